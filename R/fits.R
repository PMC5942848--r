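#' Power-law fit on the log-log scale
#'
#' Fits `y = a * x^b` by ordinary least squares on log10-transformed values,
#' the standard way scaling exponents of trait-allometry relations (such as
#' affinity `G_max / K_G` against cell diameter) are estimated.
#'
#' @param data a data frame; rows with missing or non-positive values in the
#'   chosen columns are dropped (infeasible scan points carry `NA`).
#' @param x,y column names (strings) holding predictor and response; defaults
#'   match the output of [esd_scan()].
#' @return An object of class `nutrikin_powerfit` with elements `a`, `b`,
#'   `r.squared` (of the log-log regression) and the underlying `lm` fit.
#'   Supports [tidy()], [glance()], `predict()` and `autoplot()`.
#' @examples
#' scan <- esd_scan(carbon = "C150")
#' power_fit(scan)
#' @export
power_fit <- function(data, x = "ESD", y = "affinity") {
  d <- data[, c(x, y)]
  names(d) <- c("x", "y")
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (any(d$x <= 0) || any(d$y <= 0)) {
    abort("power_fit: x and y must be strictly positive for a log-log fit.")
  }
  if (nrow(d) < 5) abort("power_fit: need at least 5 usable points.")
  fit <- lm(log10(y) ~ log10(x), data = d)
  structure(list(
    a = unname(10^coef(fit)[1]),
    b = unname(coef(fit)[2]),
    r.squared = summary(fit)$r.squared,
    lm = fit, data = d, vars = c(x = x, y = y)
  ), class = "nutrikin_powerfit")
}

#' @export
print.nutrikin_powerfit <- function(x, ...) {
  cat(sprintf("<power fit> %s = a * %s^b\n", x$vars["y"], x$vars["x"]))
  cat(sprintf("  a = %.6g, b = %.4f, R^2 = %.4f (n = %d)\n",
              x$a, x$b, x$r.squared, nrow(x$data)))
  invisible(x)
}

#' @export
predict.nutrikin_powerfit <- function(object, newdata = NULL, ...) {
  xv <- if (is.null(newdata)) object$data$x else newdata[[object$vars["x"]]]
  object$a * xv^object$b
}

#' @rdname power_fit
#' @param x a `nutrikin_powerfit` object (for the methods).
#' @param ... unused.
#' @method tidy nutrikin_powerfit
#' @export
tidy.nutrikin_powerfit <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  tibble(term = c("a", "b"),
         estimate = c(x$a, x$b),
         std.error = c(log(10) * x$a * s[1, 2], s[2, 2]),
         statistic = s[, 3],
         p.value = s[, 4])
}

#' @rdname power_fit
#' @method glance nutrikin_powerfit
#' @export
glance.nutrikin_powerfit <- function(x, ...) {
  tibble(r.squared = x$r.squared, sigma = summary(x$lm)$sigma,
         nobs = nrow(x$data))
}

#' Rectangular-hyperbola (Monod / Michaelis-Menten) fit
#'
#' Fits the type-2 rectangular hyperbola `v = Vmax * S / (S + K)` to a
#' rate-versus-substrate relation by Levenberg-Marquardt nonlinear least
#' squares, initialized from a double-reciprocal (Lineweaver-Burk) linear
#' estimate on the positive points. Either both parameters are free, or the
#' maximum is fixed (e.g. at a known `G_max`) and only `K` is fitted —
#' the two variants used when asking how well this curve form describes
#' emergent growth kinetics that are not truly hyperbolic.
#'
#' @param data a data frame holding the curve. By default the substrate and
#'   rate columns are auto-detected: `S_inf`/`G` (a [kinetic_curve()]) or
#'   `S`/`rate` (a [gen_uptake_experiment()] table).
#' @param s,rate optional column names overriding the auto-detection.
#' @param fix_max if non-`NULL`, the maximum rate is fixed at this value and
#'   only `K` is estimated.
#' @return An object of class `nutrikin_rht2` with elements `Vmax`, `K`,
#'   `r.squared`, `fixed_max`, and the underlying `nls` fit. Supports
#'   [tidy()], [glance()], [augment()], `predict()` and `autoplot()`.
#' @examples
#' kc <- kinetic_curve(organism(20), n = 100)
#' fit_rht2(kc)
#' fit_rht2(kc, fix_max = 0.693)
#' @export
fit_rht2 <- function(data, s = NULL, rate = NULL, fix_max = NULL) {
  if (is.null(s)) s <- if ("S_inf" %in% names(data)) "S_inf" else "S"
  if (is.null(rate)) rate <- if ("G" %in% names(data)) "G" else "rate"
  if (!all(c(s, rate) %in% names(data))) {
    abort(sprintf("fit_rht2: columns '%s' and '%s' not found.", s, rate))
  }
  d <- tibble(S = data[[s]], v = data[[rate]])
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 5) abort("fit_rht2: need at least 5 points.")

  # double-reciprocal start on strictly positive points
  pos <- d$S > 0 & d$v > 0
  if (sum(pos) < 3) abort("fit_rht2: too few positive points to initialize.")
  lb <- lm(I(1 / v) ~ I(1 / S), data = d[pos, ])
  v0 <- unname(1 / coef(lb)[1])
  k0 <- unname(coef(lb)[2] * v0)
  if (!is.finite(v0) || v0 <= 0) v0 <- max(d$v)
  if (!is.finite(k0) || k0 <= 0) k0 <- stats::median(d$S)

  fit <- tryCatch({
    if (is.null(fix_max)) {
      minpack.lm::nlsLM(v ~ Vmax * S / (S + K), data = d,
                        start = list(Vmax = v0, K = k0),
                        lower = c(Vmax = 1e-12, K = 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(v ~ fix_max * S / (S + K), data = d,
                        start = list(K = k0), lower = c(K = 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) {
    abort(paste0("fit_rht2: nonlinear fit failed to converge: ",
                 conditionMessage(e)), class = "nutrikin_fit_error")
  })

  est <- coef(fit)
  Vmax <- if (is.null(fix_max)) unname(est["Vmax"]) else fix_max
  K <- unname(est["K"])
  ss_res <- sum(resid(fit)^2)
  ss_tot <- sum((d$v - mean(d$v))^2)
  structure(list(
    Vmax = Vmax, K = K, r.squared = 1 - ss_res / ss_tot,
    fixed_max = !is.null(fix_max), nls = fit, data = d,
    vars = c(s = s, rate = rate)
  ), class = "nutrikin_rht2")
}

#' @export
print.nutrikin_rht2 <- function(x, ...) {
  cat(sprintf("<RHt2 fit> %s ~ Vmax * %s / (%s + K)%s\n",
              x$vars["rate"], x$vars["s"], x$vars["s"],
              if (x$fixed_max) "  [maximum fixed]" else ""))
  cat(sprintf("  Vmax = %.5g, K = %.5g, R^2 = %.4f (n = %d)\n",
              x$Vmax, x$K, x$r.squared, nrow(x$data)))
  invisible(x)
}

#' @export
predict.nutrikin_rht2 <- function(object, newdata = NULL, ...) {
  S <- if (is.null(newdata)) {
    object$data$S
  } else if (is.data.frame(newdata)) {
    newdata[[object$vars["s"]]]
  } else {
    newdata
  }
  object$Vmax * S / (S + object$K)
}

#' @rdname fit_rht2
#' @param x a `nutrikin_rht2` object (for the methods).
#' @param ... unused.
#' @method tidy nutrikin_rht2
#' @export
tidy.nutrikin_rht2 <- function(x, ...) {
  s <- summary(x$nls)$coefficients
  out <- tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                statistic = s[, 3], p.value = s[, 4])
  if (x$fixed_max) {
    out <- dplyr::bind_rows(
      tibble(term = "Vmax", estimate = x$Vmax, std.error = NA_real_,
             statistic = NA_real_, p.value = NA_real_), out)
  }
  out
}

#' @rdname fit_rht2
#' @method glance nutrikin_rht2
#' @export
glance.nutrikin_rht2 <- function(x, ...) {
  tibble(r.squared = x$r.squared, sigma = summary(x$nls)$sigma,
         nobs = nrow(x$data), fixed_max = x$fixed_max,
         converged = x$nls$convInfo$isConv)
}

#' @rdname fit_rht2
#' @method augment nutrikin_rht2
#' @export
augment.nutrikin_rht2 <- function(x, ...) {
  dplyr::mutate(x$data, .fitted = predict(x), .resid = .data$v - .data$.fitted)
}
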