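#' Line plot of a metagene profile
#'
#' @param profile A `MetageneProfile`.
#' @return A ggplot object (bins on x, density on y, regions separated by
#'   dashed boundaries).
#' @export
plot_metagene <- function(profile) {
  df <- profile$profile
  bounds <- cumsum(rep(profile$bins_per_region,
                       length(profile$region_labels)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$density)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::geom_vline(xintercept = utils::head(bounds, -1) - 0.5,
                        linetype = "dashed", color = "grey50") +
    ggplot2::labs(x = paste(profile$region_labels, collapse = " | "),
                  y = "sites per transcript per bin",
                  title = sprintf("Metagene (%d transcripts)",
                                  profile$n_transcripts_used)) +
    ggplot2::theme_minimal()
}

#' Coverage plot around a boundary anchor, with 95% CI ribbon
#'
#' @param profile A `BoundaryProfile`.
#' @return A ggplot object.
#' @export
plot_boundary <- function(profile) {
  df <- profile$profile
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$mean_cov)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "#a6bddb", alpha = 0.6) +
    ggplot2::geom_line(color = "#045a8d") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        color = "grey50") +
    ggplot2::labs(x = sprintf("offset from %s (nt)", profile$anchor),
                  y = "mean site coverage",
                  title = sprintf("%s coverage (n = %d)", profile$anchor,
                                  profile$n_units)) +
    ggplot2::theme_minimal()
}
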