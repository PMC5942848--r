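#' Physical environment for transport calculations
#'
#' Bundles the physical constants of the seawater medium that the diffusion
#' and sedimentation calculations need: molecular diffusivity of the dissolved
#' nutrient, dynamic viscosity, organism and seawater densities, gravitational
#' acceleration, and the molar mass used to convert molar concentrations to
#' mass densities.
#'
#' Internally the package works in micrometres, days and picograms; `D` and
#' the speeds from [swimming_speed()] / [sinking_speed()] are converted on
#' entry (see [D_um2_d()]).
#'
#' @param D molecular diffusivity of the nutrient, m^2 s^-1. The default
#'   1.5e-9 is typical for small inorganic nitrogen ions near 20 degrees C.
#' @param eta dynamic viscosity of seawater, Pa s.
#' @param rho_org organism density, kg L^-1. Must exceed `rho_w` for sinking.
#' @param rho_w seawater density, kg L^-1.
#' @param g gravitational acceleration, m s^-2.
#' @param molar_mass_N molar mass of the transported element, g mol^-1
#'   (14 for nitrogen).
#'
#' @return An object of class `nutrikin_env`: a validated list of the six
#'   constants.
#' @examples
#' env <- marine_environment()
#' env$D
#' @export
marine_environment <- function(D = 1.5e-9,
                               eta = 1.0846e-3,
                               rho_org = 1.0634,
                               rho_w = 1.033,
                               g = 9.8,
                               molar_mass_N = 14) {
  vals <- list(D = D, eta = eta, rho_org = rho_org, rho_w = rho_w,
               g = g, molar_mass_N = molar_mass_N)
  bad <- names(vals)[!vapply(vals, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("marine_environment: all constants must be single positive ",
                 "numbers; offending: ", paste(bad, collapse = ", ")))
  }
  structure(vals, class = "nutrikin_env")
}

#' @export
print.nutrikin_env <- function(x, ...) {
  cat("<marine environment>\n")
  cat(sprintf("  D        %.3g m^2 s^-1  (%.4g um^2 d^-1)\n", x$D, D_um2_d(x)))
  cat(sprintf("  eta      %.4g Pa s\n", x$eta))
  cat(sprintf("  rho_org  %.4f kg L^-1    rho_w %.4f kg L^-1\n", x$rho_org, x$rho_w))
  cat(sprintf("  g        %.2f m s^-2     molar mass %g g mol^-1\n", x$g, x$molar_mass_N))
  invisible(x)
}

#' Diffusivity in internal units
#'
#' Converts the environment's diffusivity from m^2 s^-1 to the package's
#' internal um^2 d^-1 (factor 1e12 x 86400).
#'
#' @param env a [marine_environment()].
#' @return Diffusivity in um^2 d^-1.
#' @export
D_um2_d <- function(env) env$D * 1e12 * 86400

#' Concentration unit conversions
#'
#' The user-facing concentration unit is umol L^-1 (uM); the diffusion
#' equations work in mass density, pg um^-3. For nitrogen,
#' 1 uM = 14 ug L^-1 = 1.4e-8 pg um^-3 (1 um^3 = 1e-15 L).
#'
#' @param x concentration to convert.
#' @param molar_mass molar mass of the element, g mol^-1.
#' @return The converted concentration.
#' @examples
#' pg_per_um3(1)          # 1.4e-8
#' uM(pg_per_um3(2.5))    # 2.5, round trip
#' @export
pg_per_um3 <- function(x, molar_mass = 14) x * molar_mass * 1e-9

#' @rdname pg_per_um3
#' @export
uM <- function(x, molar_mass = 14) x / (molar_mass * 1e-9)
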