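#' Plot localization-error curves
#'
#' Simple diagnostic plot of the correct-trial (time-1 and time-2) and
#' incorrect-trial curves produced by [run_pipeline()], faceted by analysis
#' cell. Requires ggplot2.
#'
#' @param curves Curve tibble (`t`, `value`, `class`, plus cell columns).
#' @return A ggplot object.
#' @export
plot_localization_curves <- function(curves) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_tojshift("ggplot2 is required for plotting", "tojshift_config_error")
  }
  cell_cols <- intersect(c("start_posture", "end_posture", "soa_ms"),
                         names(curves))
  curves$cell <- do.call(paste, c(curves[cell_cols], sep = " / "))
  ggplot2::ggplot(curves[curves$defined, ],
                  ggplot2::aes(x = .data$t, y = .data$value,
                               colour = .data$class)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~cell) +
    ggplot2::labs(x = "stimulus time re movement onset (ms)",
                  y = "localization error (mm)",
                  colour = "trial class / reference") +
    ggplot2::theme_minimal()
}
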