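#' Flexibility plot of a correlation profile
#'
#' `ln c` against contour distance `s` with block-SEM error bars, plus the
#' least-squares fit (solid) and the secant through the first and last
#' points (dashed) — the standard visual for persistence-length estimation.
#'
#' @param object A [correlation_profile()].
#' @param temperature_K Used only for the fits drawn on top.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot correlation_profile
#' @export
autoplot.correlation_profile <- function(object, temperature_K = 300, ...) {
  dat <- as_tibble(object)
  dat$ln_c <- log(dat$c)
  dat$ln_lo <- log(pmax(dat$c - dat$sem, .Machine$double.eps))
  dat$ln_hi <- log(dat$c + dat$sem)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$s_nm, y = .data$ln_c)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ln_lo,
                                        ymax = .data$ln_hi), width = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "s (nm)", y = "ln c(s)",
                  title = "Tangent-correlation flexibility plot") +
    ggplot2::theme_minimal()
  ok <- all(dat$c > 0)
  if (ok) {
    ls <- fit_lp(object, temperature_K, "least_squares")
    sec <- fit_lp(object, temperature_K, "secant")
    if (is.finite(ls$lp_nm)) {
      p <- p + ggplot2::geom_abline(slope = ls$slope_per_nm,
                                    intercept = ls$intercept,
                                    linetype = "solid")
    }
    if (is.finite(sec$lp_nm)) {
      p <- p + ggplot2::geom_abline(slope = sec$slope_per_nm,
                                    intercept = sec$intercept,
                                    linetype = "dashed")
    }
  }
  p
}

#' Local flexibility plot
#'
#' Local slope of `ln c` versus `s` at interior positions; the most
#' flexible (steepest) position is highlighted.
#'
#' @param object A [flexibility_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot flexibility_profile
#' @export
autoplot.flexibility_profile <- function(object, ...) {
  dat <- as_tibble(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$s_nm,
                                    y = .data$local_slope_per_nm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$most_flexible),
                        size = 2, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "s (nm)", y = "local slope of ln c (1/nm)",
                  title = "Local flexibility along the coiled-coil") +
    ggplot2::theme_minimal()
}

#' Inter-helix distance plot
#'
#' Mean +/- SD of the distance between the two chains' segment centroids
#' along the molecule.
#'
#' @param distances Output of [helix_distance_profile()].
#' @return A ggplot object.
#' @export
plot_helix_distances <- function(distances) {
  ggplot2::ggplot(distances,
                  ggplot2::aes(x = (.data$res_first + .data$res_last) / 2,
                               y = .data$d_mean_nm)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$d_mean_nm - .data$d_sd_nm,
                                        ymax = .data$d_mean_nm + .data$d_sd_nm),
                           width = 1) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "residue (segment midpoint)",
                  y = "inter-helix distance (nm)",
                  title = "Distance between the two helices") +
    ggplot2::theme_minimal()
}
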