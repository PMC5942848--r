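#' Synthetic short-incubation uptake experiment
#'
#' Generates a noisy uptake-rate dataset of the kind short-incubation
#' experiments produce: a true rectangular hyperbola
#' `v = Vmax * S / (S + K)` evaluated on a substrate grid, perturbed by
#' multiplicative lognormal noise of a stated coefficient of variation
#' (measurement error in rate data scales with magnitude). The noise is
#' mean-one, and the generator is bit-reproducible for a given seed: the
#' seed is applied locally without touching the global RNG state.
#'
#' @param true_Vmax,true_K true hyperbola parameters (rate and concentration
#'   units of your choosing).
#' @param grid strictly increasing substrate concentrations; the default is
#'   log-spaced, the usual design for kinetics assays (even leverage across
#'   the rising limb and the plateau).
#' @param noise_cv coefficient of variation of the multiplicative noise;
#'   0 returns the exact curve.
#' @param seed integer seed (required when `noise_cv > 0`).
#' @return A tibble with columns `S`, `rate` (observed) and `true_rate`,
#'   carrying `true_Vmax`, `true_K`, `noise_cv` and `seed` as attributes.
#' @examples
#' gen_uptake_experiment(1, 0.5, noise_cv = 0.1, seed = 42)
#' @export
gen_uptake_experiment <- function(true_Vmax, true_K,
                                  grid = exp(seq(log(0.05), log(5),
                                                 length.out = 20)),
                                  noise_cv = 0.1, seed = NULL) {
  if (noise_cv < 0) abort("gen_uptake_experiment: noise_cv must be >= 0.")
  if (any(diff(grid) <= 0)) {
    abort("gen_uptake_experiment: substrate grid must be strictly increasing.")
  }
  true_rate <- true_Vmax * grid / (grid + true_K)
  if (noise_cv == 0) {
    rate <- true_rate
  } else {
    if (is.null(seed)) {
      abort("gen_uptake_experiment: a seed is required when noise_cv > 0.")
    }
    sdlog <- sqrt(log(1 + noise_cv^2))
    mult <- withr::with_seed(seed,
      rlnorm(length(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog))
    rate <- true_rate * mult
  }
  out <- tibble(S = grid, rate = rate, true_rate = true_rate)
  attr(out, "true_Vmax") <- true_Vmax
  attr(out, "true_K") <- true_K
  attr(out, "noise_cv") <- noise_cv
  attr(out, "seed") <- seed
  out
}

#' Synthetic nutrient-status-dependent transport capacity table
#'
#' Generates a tabulated (N:C, Tmax) curve with the shape empirical
#' transport-capacity data show: capacity rises from a replete floor as
#' moderate N stress de-represses transporter expression, peaks at
#' intermediate stress, and collapses again under extreme stress when the
#' machinery itself degrades. Optionally the replete end can be repressed
#' below the floor (nitrate-style repression near full quota).
#'
#' The curve is built from two smooth half-waves joined at the peak
#' (continuously differentiable, single interior maximum):
#' on the stressed side it climbs from `collapse_fraction * peak` at
#' `NC_min` to the peak; on the replete side it relaxes to the floor
#' (or below it, under repression) at `NC_max`.
#'
#' @param quota a [quota_params()]; sets the N:C range and, via
#'   `G_max * NC_max`, the default floor (the capacity just sufficient for
#'   maximal growth).
#' @param floor replete-end capacity, gN gC^-1 d^-1.
#' @param peak_multiplier peak capacity as a multiple of `floor`; > 1.
#' @param collapse_fraction capacity at `NC_min` as a fraction of the peak;
#'   in `[0, 1)`.
#' @param peak_position location of the peak on the normalized quota scale
#'   (0 = NC_min, 1 = NC_max); interior.
#' @param repress fraction by which the value at `NC_max` is pushed below the
#'   floor (0 = none; nitrate-style repression uses, e.g., 0.5).
#' @param n_knots number of tabulated knots.
#' @param jitter_cv coefficient of variation of optional multiplicative
#'   knot jitter (0 = smooth table).
#' @param seed integer seed, required when `jitter_cv > 0`.
#' @return A tibble of class `nutrikin_tmax_table` with columns `NC` and
#'   `Tmax_specific`, ready for [empirical_tmax_curve()] or
#'   [organism()]`(tmax_mode = "empirical")`.
#' @examples
#' gen_tmax_table()
#' @export
gen_tmax_table <- function(quota = quota_params(),
                           floor = quota$G_max * quota$NC_max,
                           peak_multiplier = 8,
                           collapse_fraction = 0.3,
                           peak_position = 0.3,
                           repress = 0,
                           n_knots = 25,
                           jitter_cv = 0,
                           seed = NULL) {
  if (peak_multiplier <= 1) {
    abort("gen_tmax_table: peak_multiplier must exceed 1 (unimodal curve).")
  }
  if (collapse_fraction < 0 || collapse_fraction >= 1) {
    abort("gen_tmax_table: collapse_fraction must lie in [0, 1).")
  }
  if (peak_position <= 0 || peak_position >= 1) {
    abort("gen_tmax_table: peak_position must be interior to (0, 1).")
  }
  if (repress < 0 || repress >= 1) {
    abort("gen_tmax_table: repress must lie in [0, 1).")
  }
  peak <- floor * peak_multiplier
  right_end <- floor * (1 - repress)
  if (collapse_fraction * peak >= peak || right_end >= peak) {
    abort("gen_tmax_table: parameters violate unimodality.")
  }
  q <- seq(0, 1, length.out = n_knots)
  left <- collapse_fraction * peak +
    (peak - collapse_fraction * peak) * sin(pi / 2 * q / peak_position)^2
  right <- right_end + (peak - right_end) *
    cos(pi / 2 * (q - peak_position) / (1 - peak_position))^2
  val <- ifelse(q <= peak_position, left, right)
  if (jitter_cv > 0) {
    if (is.null(seed)) {
      abort("gen_tmax_table: a seed is required when jitter_cv > 0.")
    }
    sdlog <- sqrt(log(1 + jitter_cv^2))
    val <- val * withr::with_seed(seed,
      rlnorm(n_knots, meanlog = -sdlog^2 / 2, sdlog = sdlog))
  }
  NC <- quota$NC_min + q * (quota$NC_max - quota$NC_min)
  out <- tibble(NC = NC, Tmax_specific = val)
  attr(out, "shape") <- list(floor = floor, peak = peak,
                             peak_position = peak_position,
                             collapse_fraction = collapse_fraction,
                             repress = repress, jitter_cv = jitter_cv,
                             seed = seed)
  class(out) <- c("nutrikin_tmax_table", class(out))
  out
}

# generating function of the smooth synthetic capacity curve, used by tests
# to bound interpolation error against the table's own source
tmax_shape_fun <- function(shape, quota) {
  force(shape); force(quota)
  function(NC) {
    q <- (NC - quota$NC_min) / (quota$NC_max - quota$NC_min)
    peak <- shape$peak
    right_end <- shape$floor * (1 - shape$repress)
    ifelse(q <= shape$peak_position,
           shape$collapse_fraction * peak +
             (peak - shape$collapse_fraction * peak) *
             sin(pi / 2 * q / shape$peak_position)^2,
           right_end + (peak - right_end) *
             cos(pi / 2 * (q - shape$peak_position) /
                   (1 - shape$peak_position))^2)
  }
}
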