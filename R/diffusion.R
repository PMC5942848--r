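#' Motion enhancement of diffusive supply
#'
#' The boundary-layer mass-transfer factor `1 + 0.5 r c / D` by which
#' swimming or sinking thins the diffusive boundary layer (a Peclet-number
#' enhancement). Equals 1 for a non-motile cell.
#'
#' @param radius cell radius, um.
#' @param speed speed of motion, um d^-1 (0 if non-motile).
#' @param env a [marine_environment()].
#' @return Dimensionless enhancement factor(s), >= 1.
#' @export
motion_enhancement <- function(radius, speed, env = marine_environment()) {
  if (any(speed < 0)) abort("motion_enhancement: speed must be >= 0.")
  1 + 0.5 * radius * speed / D_um2_d(env)
}

#' Diffusive transport from a concentration gradient
#'
#' Transport sustained by molecular diffusion across the boundary layer:
#' `T = (D / r) (1 + 0.5 r c / D) * 4 pi r^2 (S_inf - S0)`, with
#' concentrations converted internally from uM to pg um^-3.
#'
#' @param S_inf bulk substrate concentration, uM.
#' @param S0 substrate concentration at the membrane, uM; `S0 <= S_inf`
#'   (efflux is not modelled).
#' @param radius cell radius, um.
#' @param speed motion speed, um d^-1.
#' @param env a [marine_environment()].
#' @return Transport rate(s), pgN cell^-1 d^-1.
#' @export
transport_from_gradient <- function(S_inf, S0, radius, speed = 0,
                                    env = marine_environment()) {
  if (any(S0 < 0)) abort("transport_from_gradient: S0 must be >= 0.")
  if (any(S_inf < S0)) {
    abort("transport_from_gradient: S_inf < S0 implies efflux, which is not modelled.")
  }
  D <- D_um2_d(env)
  grad <- pg_per_um3(S_inf - S0, env$molar_mass_N)
  4 * pi * D * radius * motion_enhancement(radius, speed, env) * grad
}

#' Bulk substrate concentration sustaining a transport rate
#'
#' Inverse of [transport_from_gradient()] at fixed membrane concentration:
#' `S_inf = T / (4 pi D r (1 + 0.5 r c / D)) + S0`. This is the step that
#' turns a per-cell demand into the bulk-water concentration an observer
#' would measure.
#'
#' @param T transport rate(s), pgN cell^-1 d^-1, >= 0.
#' @param S0 membrane substrate concentration, uM.
#' @param radius cell radius, um.
#' @param speed motion speed, um d^-1.
#' @param env a [marine_environment()].
#' @return Bulk concentration(s), uM.
#' @export
bulk_substrate <- function(T, S0, radius, speed = 0,
                           env = marine_environment()) {
  if (any(T < 0)) abort("bulk_substrate: T must be >= 0.")
  D <- D_um2_d(env)
  grad_pg <- T / (4 * pi * D * radius * motion_enhancement(radius, speed, env))
  S0 + uM(grad_pg, env$molar_mass_N)
}
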