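#' Scatter plot of lab versus field epigenetic aging rates
#'
#' Slope pairs of the age-associated set colored by octant, with the axes
#' and the 45-degree diagonals drawn as guides; the analogue of the
#' two-environment rate-comparison panel.
#'
#' @param categories output of [categorizeSites()].
#' @param mask probes to draw; defaults to the age-associated
#'   (not `not_significant`) set.
#' @return a ggplot object.
#' @export
plotRateComparison <- function(categories,
                               mask = categories$category !=
                                   "not_significant") {
    df <- data.frame(lab = categories$slope_lab[mask],
                     field = categories$slope_field[mask])
    df$octant <- factor(octantOf(df$lab, df$field), levels = 1:8)
    df <- df[!is.na(df$octant), , drop = FALSE]
    lim <- max(abs(c(df$lab, df$field)))
    ggplot2::ggplot(df, ggplot2::aes(x = lab, y = field, color = octant)) +
        ggplot2::geom_hline(yintercept = 0, linewidth = 0.3,
                            color = "grey50") +
        ggplot2::geom_vline(xintercept = 0, linewidth = 0.3,
                            color = "grey50") +
        ggplot2::geom_abline(slope = c(1, -1), intercept = 0,
                             linetype = "dashed", color = "grey70") +
        ggplot2::geom_point(size = 0.6, alpha = 0.6) +
        ggplot2::coord_equal(xlim = c(-lim, lim), ylim = c(-lim, lim)) +
        ggplot2::labs(x = "lab aging rate (fraction/year)",
                      y = "field aging rate (fraction/year)",
                      color = "octant") +
        ggplot2::theme_minimal()
}
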