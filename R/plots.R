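#' Per-miRNA expression levels by group
#'
#' Jittered points on a log10 scale with the group mean marked, one facet
#' per miRNA — the usual case-vs-control level plot for validation cohorts.
#'
#' @param data Concentration tibble (`group` + miRNA columns).
#' @param mirnas Columns to plot; default all non-metadata columns.
#' @param group_col Grouping column.
#' @return A ggplot object.
#' @export
plot_expression <- function(data, mirnas = NULL, group_col = "group") {
  mirnas <- measure_cols(data, mirnas)
  long <- tidyr::pivot_longer(
    data[c(group_col, mirnas)],
    cols = dplyr::all_of(mirnas), names_to = "mirna", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data[[group_col]], .data$value)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4, linewidth = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~mirna, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "concentration (fmol/L, log scale)")
}

#' Risk-score distribution by group
#'
#' @param scored Output of [score_subjects()].
#' @param panel The panel, to mark the frozen RSF cutoff.
#' @param group_col Grouping column.
#' @return A ggplot object.
#' @export
plot_rsf <- function(scored, panel = NULL, group_col = "group") {
  p <- ggplot2::ggplot(scored, ggplot2::aes(.data[[group_col]], .data$rsf)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "risk score (RSF)")
  if (!is.null(panel)) {
    p <- p + ggplot2::geom_hline(
      yintercept = panel$rsf_cutoff, linetype = "dashed"
    )
  }
  p
}
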