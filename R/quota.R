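#' Quota parameters for N-limited growth
#'
#' Parameters of the normalized (Droop-type) N:C quota control of growth:
#' growth stops at `NC_min`, reaches `G_max` at `NC_max`, and in between is
#' set by the normalized quota [normalized_quota()] whose curvature is
#' controlled by `KQ` (KQ = 10 gives a near-linear N:C-to-growth map).
#'
#' @param NC_max maximum N:C quota (gN gC^-1), at which G = G_max.
#' @param NC_min minimum N:C quota (gN gC^-1), at which G = 0.
#' @param KQ dimensionless curve-shape constant, > 0.
#' @param G_max maximum growth rate, d^-1.
#' @return An object of class `nutrikin_quota`.
#' @examples
#' quota_params()
#' @export
quota_params <- function(NC_max = 0.18, NC_min = 0.05, KQ = 10, G_max = 0.693) {
  if (!(NC_min > 0 && NC_max > NC_min)) {
    abort("quota_params: need 0 < NC_min < NC_max.")
  }
  if (KQ <= 0 || G_max <= 0) abort("quota_params: KQ and G_max must be > 0.")
  structure(list(NC_max = NC_max, NC_min = NC_min, KQ = KQ, G_max = G_max),
            class = "nutrikin_quota")
}

#' @export
print.nutrikin_quota <- function(x, ...) {
  cat(sprintf("<quota> N:C %.3g-%.3g gN gC^-1, KQ %g, G_max %g d^-1\n",
              x$NC_min, x$NC_max, x$KQ, x$G_max))
  invisible(x)
}

#' Normalized N:C quota
#'
#' Maps the cellular N:C mass ratio onto the normalized quota
#' `NCu = (1 + KQ) (NC - NC_min) / ((NC - NC_min) + KQ (NC_max - NC_min))`,
#' which runs from 0 (maximum N stress, G = 0) to 1 (replete, G = G_max).
#'
#' @param NC cellular N:C quota(s), gN gC^-1, within `[NC_min, NC_max]`.
#' @param quota a [quota_params()].
#' @return Normalized quota(s) in `[0, 1]`.
#' @examples
#' normalized_quota(0.125, quota_params(NC_max = 0.2))
#' @export
normalized_quota <- function(NC, quota = quota_params()) {
  tol <- 1e-12
  if (any(NC < quota$NC_min - tol) || any(NC > quota$NC_max + tol)) {
    abort("normalized_quota: NC outside [NC_min, NC_max].")
  }
  NC <- pmin(pmax(NC, quota$NC_min), quota$NC_max)
  d <- NC - quota$NC_min
  (1 + quota$KQ) * d / (d + quota$KQ * (quota$NC_max - quota$NC_min))
}

#' N:C quota from a target N status
#'
#' Algebraic inverse of [normalized_quota()]:
#' `NC = NC_min + NCu KQ (NC_max - NC_min) / (1 + KQ - NCu)`.
#'
#' @param NCu normalized quota(s) in `[0, 1]`.
#' @param quota a [quota_params()].
#' @return N:C quota(s), gN gC^-1.
#' @examples
#' quota_from_nstatus(0.5, quota_params(NC_max = 0.2))  # ~0.1214
#' @export
quota_from_nstatus <- function(NCu, quota = quota_params()) {
  if (any(NCu < 0) || any(NCu > 1)) {
    abort("quota_from_nstatus: NCu must lie in [0, 1].")
  }
  quota$NC_min +
    NCu * quota$KQ * (quota$NC_max - quota$NC_min) / (1 + quota$KQ - NCu)
}

#' Growth rate under quota control
#'
#' `G = G_max * NCu`: growth is proportional to the normalized quota.
#'
#' @param NCu normalized quota(s) in `[0, 1]`.
#' @param quota a [quota_params()].
#' @return Growth rate(s), d^-1.
#' @export
growth_rate <- function(NCu, quota = quota_params()) {
  if (any(NCu < 0) || any(NCu > 1)) abort("growth_rate: NCu must lie in [0, 1].")
  quota$G_max * NCu
}

#' Steady-state nitrogen transport demand
#'
#' The N transport rate a cell must sustain to grow at rate `G` while holding
#' quota `NC`: `T = G * NC * C_cell` (pgN cell^-1 d^-1). At `G = G_max` and
#' `NC = NC_max` this is the per-cell transport requirement underpinning the
#' transporter rate density needed for maximal growth.
#'
#' @param G growth rate(s), d^-1.
#' @param NC cellular N:C quota(s), gN gC^-1.
#' @param C_cell cellular carbon content(s), pgC.
#' @return Transport demand(s), pgN cell^-1 d^-1.
#' @examples
#' required_transport(1.4, 0.15, 12.31)  # 2.585
#' @export
required_transport <- function(G, NC, C_cell) {
  if (any(G < 0) || any(NC < 0) || any(C_cell < 0)) {
    abort("required_transport: inputs must be non-negative.")
  }
  G * NC * C_cell
}
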