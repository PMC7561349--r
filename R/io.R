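## documented CSV schemas; unknown extra columns are preserved on read
.trial_schema <- c("trial_id", "participant_id", "start_posture",
                   "end_posture", "soa_ms", "first_hand", "t1_ms", "t2_ms",
                   "response_hand", "reported_x_mm", "reported_y_mm")
.traj_schema <- c("trial_id", "hand", "t_ms", "x_mm", "y_mm")

#' Read and write trial tables
#'
#' Comma-separated UTF-8 files with a header; the required columns are
#' `r paste0('\x60', .trial_schema, '\x60', collapse = ", ")`. Additional
#' columns (e.g. the generator's kinematic annotations) are preserved.
#' Rows violating the stimulus-pair invariant `t2 - t1 == soa`, rows with an
#' invalid response hand, and duplicated trial ids are rejected with the
#' offending line numbers.
#'
#' @param path CSV file path.
#' @param trials Trial tibble to write.
#' @return `read_trials()` returns a tibble; `write_trials()` returns
#'   `path`, invisibly.
#' @export
read_trials <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  missing <- setdiff(.trial_schema, names(df))
  if (length(missing)) {
    stop_tojshift(paste0("trial table is missing columns: ",
                         paste(missing, collapse = ", ")),
                  "tojshift_schema_error")
  }
  dup <- duplicated(df$trial_id)
  if (any(dup)) {
    stop_tojshift(paste0("duplicate trial_id at rows: ",
                         paste(head(which(dup), 5), collapse = ", ")),
                  "tojshift_schema_error")
  }
  bad_soa <- which(abs(df$t2_ms - df$t1_ms - df$soa_ms) > 1e-6)
  if (length(bad_soa)) {
    stop_tojshift(paste0("t2 - t1 differs from soa at rows: ",
                         paste(head(bad_soa, 5), collapse = ", ")),
                  "tojshift_schema_error")
  }
  bad_hand <- which(!df$response_hand %in% c("left", "right") |
                      !df$first_hand %in% c("left", "right"))
  if (length(bad_hand)) {
    stop_tojshift(paste0("invalid hand labels at rows: ",
                         paste(head(bad_hand, 5), collapse = ", ")),
                  "tojshift_schema_error")
  }
  df
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(.trial_schema, names(trials))
  if (length(missing)) {
    stop_tojshift(paste0("trial table is missing columns: ",
                         paste(missing, collapse = ", ")),
                  "tojshift_schema_error")
  }
  write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Read and write trajectory tables
#'
#' Long-format marker tables with columns
#' `r paste0('\x60', .traj_schema, '\x60', collapse = ", ")` (optionally
#' `z_mm`); missing samples are `NA`.
#'
#' @param path CSV file path.
#' @param trajectories Trajectory tibble to write.
#' @return `read_trajectories()` returns a tibble; `write_trajectories()`
#'   returns `path`, invisibly.
#' @export
read_trajectories <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  missing <- setdiff(.traj_schema, names(df))
  if (length(missing)) {
    stop_tojshift(paste0("trajectory table is missing columns: ",
                         paste(missing, collapse = ", ")),
                  "tojshift_schema_error")
  }
  if (!all(df$hand %in% c("left", "right"))) {
    stop_tojshift("hand must be 'left' or 'right'", "tojshift_schema_error")
  }
  df
}

#' @rdname read_trajectories
#' @export
write_trajectories <- function(trajectories, path) {
  missing <- setdiff(.traj_schema, names(trajectories))
  if (length(missing)) {
    stop_tojshift(paste0("trajectory table is missing columns: ",
                         paste(missing, collapse = ", ")),
                  "tojshift_schema_error")
  }
  write.csv(trajectories, path, row.names = FALSE)
  invisible(path)
}
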