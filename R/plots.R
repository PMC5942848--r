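#' Plot an emergent kinetic curve
#'
#' Growth rate against substrate concentration, in the bulk medium (`S_inf`,
#' solid) and at the membrane surface (`S0`, dashed); the horizontal
#' reference line marks half-maximal growth, whose intersection with the
#' bulk curve is the emergent `K_G`.
#'
#' @param object a [kinetic_curve()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot nutrikin_curve
#' @export
autoplot.nutrikin_curve <- function(object, ...) {
  org <- attr(object, "organism")
  long <- tidyr::pivot_longer(object, c("S_inf", "S0"),
                              names_to = "where", values_to = "S")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$S, y = .data$G,
                                     linetype = .data$where)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = org$quota$G_max / 2,
                        colour = "grey60", linetype = "dotted") +
    ggplot2::scale_linetype_manual(
      values = c(S_inf = "solid", S0 = "dashed"),
      labels = c(S_inf = "bulk medium", S0 = "membrane surface")) +
    ggplot2::labs(x = "substrate concentration (uM)",
                  y = expression(G ~ (d^-1)),
                  linetype = NULL,
                  title = sprintf("Emergent growth kinetics, ESD %g um (%s, %s)",
                                  org$ESD, org$carbon$label, org$motion)) +
    ggplot2::theme_minimal()
}

#' Plot an ESD scan of emergent half-saturation
#'
#' `K_G` against cell diameter on log-log axes, with the membrane (`S0`) and
#' diffusive (`S_diff`) components.
#'
#' @param object an [esd_scan()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot nutrikin_scan
#' @export
autoplot.nutrikin_scan <- function(object, ...) {
  cfg <- attr(object, "config")
  long <- tidyr::pivot_longer(
    dplyr::filter(object, .data$feasible),
    c("K_G", "S0", "S_diff"), names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ESD, y = .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "ESD (um)", y = "concentration (uM)",
                  colour = NULL,
                  title = sprintf("Emergent K_G vs cell size (%s, %s)",
                                  cfg$carbon, cfg$motion)) +
    ggplot2::theme_minimal()
}

#' Plot a rectangular-hyperbola fit over its data
#'
#' @param object a [fit_rht2()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot nutrikin_rht2
#' @export
autoplot.nutrikin_rht2 <- function(object, ...) {
  d <- object$data
  grid <- tibble(S = seq(0, max(d$S), length.out = 200))
  grid$v <- object$Vmax * grid$S / (grid$S + object$K)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$S, y = .data$v)) +
    ggplot2::geom_point(size = 0.8, colour = "grey30") +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::labs(x = "substrate concentration", y = "rate",
                  title = sprintf("RHt2 fit: Vmax %.3g, K %.3g, R^2 %.4f%s",
                                  object$Vmax, object$K, object$r.squared,
                                  if (object$fixed_max) " (max fixed)" else "")) +
    ggplot2::theme_minimal()
}
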