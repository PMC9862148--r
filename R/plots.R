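#' Plot asymmetry indices per ROI and sibling
#'
#' Bar chart of asymmetry indices (positive = leftward) with the symmetric
#' band marked.
#'
#' @param asym Output of [asymmetry_table()] (one phenotype or several).
#' @param epsilon Symmetric band half-width drawn as dashed lines.
#' @return A ggplot object.
#' @export
plot_asymmetry <- function(asym, epsilon = 0.01) {
  ggplot2::ggplot(asym,
                  ggplot2::aes(x = .data$roi, y = .data$index,
                               fill = .data$subject_id)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = c(-epsilon, epsilon),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::facet_wrap(~phenotype, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "asymmetry index (L - R) / ((L + R)/2)",
                  fill = "sibling") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a Q-Q curve
#'
#' Matched quantiles of two luminosity distributions against the identity
#' line; departure from the diagonal is dissimilarity.
#'
#' @param curve A `qq_curve`.
#' @return A ggplot object.
#' @export
plot_qq <- function(curve) {
  df <- tibble::tibble(qx = curve$qx, qy = curve$qy)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$qx, y = .data$qy)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 255), ylim = c(0, 255)) +
    ggplot2::labs(x = curve$labels[1], y = curve$labels[2],
                  subtitle = sprintf("divergence = %.4f", curve$divergence)) +
    ggplot2::theme_minimal()
}

# best-effort plot rendering for pipeline outputs; device failures are
# reported, not fatal
write_report_plots <- function(report, out_dir) {
  pdir <- file.path(out_dir, "plots")
  dir.create(pdir, showWarnings = FALSE)
  try_save <- function(p, file) {
    tryCatch(ggplot2::ggsave(file.path(pdir, file), p, width = 8,
                             height = 5, dpi = 150),
             error = function(e) message("plot skipped: ",
                                         conditionMessage(e)))
  }
  try_save(plot_asymmetry(report$asymmetry), "asymmetry.png")
  icc <- report$icc
  p <- ggplot2::ggplot(icc, ggplot2::aes(x = .data$pair, y = .data$icc,
                                         fill = .data$region_set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~phenotype) +
    ggplot2::ylim(0, 1) + ggplot2::theme_minimal()
  try_save(p, "icc.png")
  invisible(NULL)
}
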