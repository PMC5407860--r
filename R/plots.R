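## Figure-style plot helpers.

#' Plot a permutation enrichment result
#'
#' Observed overlap count against the permuted distribution with its 95%
#' interval, in the style of PIR feature-enrichment bar plots.
#'
#' @param x a `permutation_result` (see [feature_enrichment()]).
#' @param label feature-set label.
#' @return a ggplot object.
#' @export
plot_enrichment <- function(x, label = "feature") {
  df <- data.frame(
    set = factor(c("observed", "permuted"), c("observed", "permuted")),
    value = c(x$observed, x$permuted_mean),
    lo = c(NA, x$ci95[1]), hi = c(NA, x$ci95[2])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = set, y = value, fill = set)) +
    ggplot2::geom_col(width = 0.6, show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = lo, ymax = hi), width = 0.2,
                           na.rm = TRUE) +
    ggplot2::scale_fill_manual(values = c(observed = "#2c5aa0",
                                          permuted = "grey60")) +
    ggplot2::labs(x = NULL, y = "fragments overlapping feature",
                  title = sprintf("%s (z = %.1f, p = %.3g)", label,
                                  x$z_score, x$empirical_p)) +
    ggplot2::theme_minimal()
}

#' Plot a CRU containment profile
#'
#' Observed per-bin fractions against the permuted mean and 95% interval,
#' over the 12 containment bins (exactly 0%, ten 10% intervals, exactly
#' 100%).
#'
#' @param x a `containment_profile` (see [containment_test()]).
#' @return a ggplot object.
#' @export
plot_containment <- function(x) {
  bins <- c("0%", paste0("(", seq(0, 90, 10), ",", seq(10, 100, 10), "]%")[1:10],
            "100%")
  bins[12] <- "100%"
  df <- data.frame(
    bin = factor(rep(bins, 2), levels = bins),
    frac = c(x$observed, colMeans(x$permuted)),
    which = rep(c("observed", "permuted"), each = 12),
    lo = c(rep(NA, 12), x$ci95[1, ]),
    hi = c(rep(NA, 12), x$ci95[2, ])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = bin, y = frac, colour = which,
                                   group = which)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = lo, ymax = hi), width = 0.2,
                           na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c(observed = "#6a3d9a",
                                            permuted = "grey50")) +
    ggplot2::labs(x = "fraction of interactions inside the promoter's domain",
                  y = "fraction of CRUs", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
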