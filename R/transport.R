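#' Transporter parameters
#'
#' Parameters of the membrane nutrient transporter system: the transporter
#' half-saturation `K_T` (defined at the membrane surface, i.e. on the S_0
#' scale), the absolute ceiling on transporter rate density `TRD_max`
#' (pgN um^-2 d^-1; the membrane can only hold so many transporter proteins
#' per unit area), and the shape constant `KT_con` of the hypothetical
#' N-status response of maximum transport capacity
#' ([tmax_hypothetical()]; smaller values give a steeper rise of capacity
#' with N stress).
#'
#' @param K_T transporter half-saturation, uM.
#' @param TRD_max maximum transporter rate density, pgN um^-2 d^-1.
#' @param KT_con dimensionless curve-shape constant.
#' @return An object of class `nutrikin_transporter`.
#' @export
transporter_params <- function(K_T = 1, TRD_max = 0.4, KT_con = 0.1) {
  if (K_T <= 0 || TRD_max <= 0 || KT_con <= 0) {
    abort("transporter_params: K_T, TRD_max and KT_con must all be > 0.")
  }
  structure(list(K_T = K_T, TRD_max = TRD_max, KT_con = KT_con),
            class = "nutrikin_transporter")
}

#' @export
print.nutrikin_transporter <- function(x, ...) {
  cat(sprintf("<transporter> K_T %g uM, TRD_max %g pgN um^-2 d^-1, KT_con %g\n",
              x$K_T, x$TRD_max, x$KT_con))
  invisible(x)
}

#' Transporter rate density required for maximal growth
#'
#' `TRD_Gmax = G_max * NC_max * C_cell / SA`: the transport rate per unit
#' membrane area needed to keep a replete cell growing at `G_max`.
#'
#' @param G_max maximum growth rate, d^-1.
#' @param NC_max maximum N:C quota, gN gC^-1.
#' @param C_cell cellular carbon, pgC.
#' @param SA cell surface area, um^2.
#' @return TRD_Gmax, pgN um^-2 d^-1.
#' @examples
#' trd_gmax(1.4, 0.18, 462, 605.21)  # ~0.1924
#' @export
trd_gmax <- function(G_max, NC_max, C_cell, SA) {
  if (any(c(G_max, NC_max, C_cell, SA) <= 0)) {
    abort("trd_gmax: all inputs must be positive.")
  }
  G_max * NC_max * C_cell / SA
}

#' Transport over-capacity multiplier
#'
#' `T_add = (TRD_max - TRD_Gmax) / TRD_Gmax`: the headroom between the
#' membrane's maximum possible transporter rate density and what maximal
#' growth requires, expressed as a multiplier. `T_add = 0` means no
#' up-regulation of transport under N stress is possible; configurations
#' with `TRD_Gmax > TRD_max` cannot reach `G_max` at all.
#'
#' @param TRD_max ceiling transporter rate density, pgN um^-2 d^-1.
#' @param TRD_Gmax density required at maximal growth, pgN um^-2 d^-1.
#' @return Dimensionless multiplier, >= 0.
#' @export
t_add <- function(TRD_max, TRD_Gmax) {
  if (any(TRD_Gmax <= 0)) abort("t_add: TRD_Gmax must be positive.")
  if (any(TRD_Gmax > TRD_max)) {
    abort(paste0("t_add: TRD_Gmax exceeds TRD_max; the requested G_max is ",
                 "unattainable for this cell size and carbon density."),
          class = "nutrikin_infeasible")
  }
  (TRD_max - TRD_Gmax) / TRD_Gmax
}

#' Hypothetical N-status response of maximum transport capacity
#'
#' The C-specific maximum transport rate as a function of N status:
#' `Tmax = G_max NC_max (1 + T_add (1 + KT_con)(1 - NCu) / ((1 - NCu) + KT_con))`.
#' At `NCu = 1` (replete) capacity sits at the floor `G_max * NC_max`, just
#' enough to sustain maximal growth; as stress deepens (`NCu -> 0`) capacity
#' rises towards `(1 + T_add)` times the floor. The normalized-hyperbola
#' bracket runs 0 to 1 for any `KT_con`. Multiply by `C_cell` for the
#' per-cell capacity.
#'
#' @param NCu normalized quota(s) in `[0, 1]`.
#' @param quota a [quota_params()] (supplies G_max and NC_max).
#' @param T_add over-capacity multiplier from [t_add()].
#' @param KT_con curve-shape constant.
#' @return C-specific maximum transport rate(s), gN gC^-1 d^-1.
#' @export
tmax_hypothetical <- function(NCu, quota = quota_params(), T_add = 0,
                              KT_con = 0.1) {
  if (any(NCu < 0) || any(NCu > 1)) {
    abort("tmax_hypothetical: NCu must lie in [0, 1].")
  }
  s <- 1 - NCu
  quota$G_max * quota$NC_max *
    (1 + T_add * (1 + KT_con) * s / (s + KT_con))
}

#' Michaelis-Menten transport at the membrane
#'
#' `T = Tmax_cell * S0 / (S0 + K_T)`: saturating transport as a function of
#' the substrate concentration at the membrane surface.
#'
#' @param S0 substrate concentration at the membrane, uM.
#' @param Tmax_cell per-cell maximum transport rate, pgN cell^-1 d^-1.
#' @param K_T transporter half-saturation, uM.
#' @return Transport rate(s), pgN cell^-1 d^-1.
#' @export
transport_rate <- function(S0, Tmax_cell, K_T = 1) {
  if (any(S0 < 0)) abort("transport_rate: S0 must be non-negative.")
  Tmax_cell * S0 / (S0 + K_T)
}

#' Membrane substrate concentration sustaining a transport rate
#'
#' Inverse of [transport_rate()]: `S0 = T K_T / (Tmax_cell - T)`. A demand at
#' or above capacity has no finite solution.
#'
#' @param T transport rate(s), pgN cell^-1 d^-1, with `0 <= T < Tmax_cell`.
#' @param Tmax_cell per-cell maximum transport rate, pgN cell^-1 d^-1.
#' @param K_T transporter half-saturation, uM.
#' @return Membrane substrate concentration(s), uM.
#' @export
substrate_at_membrane <- function(T, Tmax_cell, K_T = 1) {
  if (any(T < 0)) abort("substrate_at_membrane: T must be non-negative.")
  if (any(T >= Tmax_cell)) {
    abort(paste0("substrate_at_membrane: demand T >= capacity Tmax_cell; ",
                 "no finite membrane concentration can sustain it."),
          class = "nutrikin_saturated")
  }
  T * K_T / (Tmax_cell - T)
}

#' Interpolate an empirical transport-capacity table
#'
#' Builds a monotone-preserving piecewise-cubic interpolator (Fritsch-Carlson
#' Hermite, no overshoot between knots) through tabulated
#' (N:C, C-specific Tmax) pairs, for use in place of the hypothetical
#' response curve when experimentally derived capacity curves are available.
#' Queries outside the tabulated N:C range are clamped to the end values with
#' a warning.
#'
#' @param table a data frame with numeric columns `NC` (strictly increasing)
#'   and `Tmax_specific` (gN gC^-1 d^-1, non-negative), at least 3 rows.
#' @return A function `f(NC)` returning interpolated Tmax_specific.
#' @examples
#' tab <- gen_tmax_table(seed = 1)
#' f <- empirical_tmax_curve(tab)
#' f(0.1)
#' @export
empirical_tmax_curve <- function(table) {
  if (!all(c("NC", "Tmax_specific") %in% names(table))) {
    abort("empirical_tmax_curve: table needs columns NC and Tmax_specific.")
  }
  nc <- table$NC
  tm <- table$Tmax_specific
  if (length(nc) < 3) abort("empirical_tmax_curve: need at least 3 knots.")
  if (any(diff(nc) <= 0)) {
    abort("empirical_tmax_curve: NC knots must be strictly increasing.")
  }
  if (any(tm < 0)) abort("empirical_tmax_curve: Tmax values must be >= 0.")
  f <- splinefun(nc, tm, method = "monoH.FC")
  rng <- range(nc)
  function(NC) {
    out <- any(NC < rng[1] | NC > rng[2])
    if (out) {
      warn(sprintf("empirical Tmax query outside tabulated N:C range [%g, %g]; clamping.",
                   rng[1], rng[2]))
    }
    f(pmin(pmax(NC, rng[1]), rng[2]))
  }
}

#' Apparent half-saturation of a multi-transporter membrane
#'
#' With `n` identical transporters of turnover `k_cat` and half-saturation
#' `K_T` working in parallel, the substrate concentration at which the pooled
#' transport meets half the demand at maximal growth solves
#' `n k_cat S / (S + K_T) = d / 2`, i.e.
#' `S = K_T (d/2) / (n k_cat - d/2)`. As transporter number grows the
#' apparent half-saturation for growth falls ever further below K_T.
#'
#' @param n_transporters number of transporter proteins.
#' @param k_cat per-transporter turnover rate.
#' @param K_T transporter half-saturation (any concentration unit).
#' @param demand_at_Gmax transport rate required at maximal growth, same rate
#'   units as `n_transporters * k_cat`.
#' @return Substrate concentration, in the units of `K_T`.
#' @examples
#' multi_transporter_halfsat(4, 1, 1, 2)   # 1/3
#' multi_transporter_halfsat(16, 1, 1, 2)  # 1/15
#' @export
multi_transporter_halfsat <- function(n_transporters, k_cat, K_T,
                                      demand_at_Gmax) {
  cap <- n_transporters * k_cat
  half <- demand_at_Gmax / 2
  if (any(cap <= half)) {
    abort("multi_transporter_halfsat: pooled capacity must exceed half the demand.",
          class = "nutrikin_saturated")
  }
  K_T * half / (cap - half)
}
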