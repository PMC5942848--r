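#' Sphere geometry of a cell
#'
#' Computes radius, volume and surface area of the volume-equivalent sphere
#' for one or more equivalent spherical diameters (ESD).
#'
#' @param ESD equivalent spherical diameter(s), um. Strictly positive.
#' @return A tibble with columns `ESD`, `radius` (um), `volume` (um^3) and
#'   `SA` (um^2), one row per input diameter.
#' @examples
#' sphere_geometry(c(4.5, 11.5, 13.9))
#' @export
sphere_geometry <- function(ESD) {
  if (!is.numeric(ESD) || any(!is.finite(ESD)) || any(ESD <= 0)) {
    abort("sphere_geometry: ESD must be finite and strictly positive (um).")
  }
  r <- ESD / 2
  tibble(ESD = ESD,
         radius = r,
         volume = 4 / 3 * pi * r^3,
         SA = 4 * pi * r^2)
}

#' Cellular carbon models
#'
#' A carbon model maps cell volume to cellular carbon content `C_cell` (pgC)
#' and thence carbon density (gC per litre of cell volume). Two kinds are
#' supported:
#'
#' * `fixed_density`: `C_cell = density * volume * 1e-3` (density in gC L^-1,
#'   volume in um^3; 1 um^3 = 1e-15 L).
#' * `allometric`: piecewise power law `C_cell = a * volume^b` with one or
#'   more volume segments, following the standard carbon-to-volume
#'   regressions for protist plankton in which coefficients differ between
#'   small (< 3000 um^3) and large cells.
#'
#' Three named presets cover the configurations used throughout the package:
#' `"C150"` (fixed density of 150 gC L^-1), `"Cprot"` (generic protist
#' allometry: a = 0.261, b = 0.86 below 3000 um^3; a = 10^-0.665, b = 0.939
#' above) and `"Cdiat"` (diatom allometry, reflecting increasing vacuolation
#' with size: a = 0.288, b = 0.811 below 3000 um^3; a = 10^-0.933, b = 0.881
#' above).
#'
#' @param kind `"C150"`, `"Cprot"`, `"Cdiat"`, `"fixed_density"` or
#'   `"allometric"`.
#' @param density carbon density for `fixed_density`, gC L^-1.
#' @param a,b coefficients for a single-segment `allometric` model
#'   (`C_cell = a * volume^b`, volume in um^3, result in pgC); `0 < b <= 1`.
#' @return An object of class `nutrikin_carbon`.
#' @examples
#' carbon_model("Cdiat")
#' carbon_model("allometric", a = 0.3, b = 0.8)
#' @export
carbon_model <- function(kind = c("C150", "Cprot", "Cdiat",
                                  "fixed_density", "allometric"),
                         density = 150, a = NULL, b = NULL) {
  kind <- match.arg(kind)
  m <- switch(kind,
    C150 = list(kind = "fixed_density", label = "C150", density = 150),
    fixed_density = {
      if (!is.numeric(density) || density <= 0) {
        abort("carbon_model: density must be positive (gC L^-1).")
      }
      list(kind = "fixed_density", label = sprintf("C%g", density),
           density = density)
    },
    Cprot = list(kind = "allometric", label = "Cprot",
                 segments = data.frame(vmax = c(3000, Inf),
                                       a = c(0.261, 10^-0.665),
                                       b = c(0.86, 0.939))),
    Cdiat = list(kind = "allometric", label = "Cdiat",
                 segments = data.frame(vmax = c(3000, Inf),
                                       a = c(0.288, 10^-0.933),
                                       b = c(0.811, 0.881))),
    allometric = {
      if (is.null(a) || is.null(b)) {
        abort("carbon_model: allometric model needs coefficients a and b.")
      }
      if (a <= 0 || b <= 0 || b > 1) {
        abort("carbon_model: require a > 0 and 0 < b <= 1.")
      }
      list(kind = "allometric", label = sprintf("allom(a=%g,b=%g)", a, b),
           segments = data.frame(vmax = Inf, a = a, b = b))
    })
  structure(m, class = "nutrikin_carbon")
}

#' @export
print.nutrikin_carbon <- function(x, ...) {
  cat("<carbon model>", x$label, "\n")
  if (x$kind == "fixed_density") {
    cat(sprintf("  fixed density %g gC L^-1\n", x$density))
  } else {
    for (i in seq_len(nrow(x$segments))) {
      s <- x$segments[i, ]
      cat(sprintf("  volume <= %g um^3: C_cell = %.4g * V^%.3g pgC\n",
                  s$vmax, s$a, s$b))
    }
  }
  invisible(x)
}

#' Cellular carbon content and density
#'
#' Applies a carbon model to cell geometry, adding carbon content `C_cell`
#' (pgC) and `carbon_density` (gC L^-1) columns.
#'
#' @param morphology a tibble from [sphere_geometry()] (needs a `volume`
#'   column in um^3).
#' @param model a [carbon_model()] or a preset name passed to it.
#' @return The input tibble with `C_cell` and `carbon_density` columns added.
#' @examples
#' sphere_geometry(13.9) |> cell_carbon("Cdiat")
#' @export
cell_carbon <- function(morphology, model = carbon_model("Cprot")) {
  if (is.character(model)) model <- carbon_model(model)
  stopifnot(inherits(model, "nutrikin_carbon"))
  if (!"volume" %in% names(morphology)) {
    abort("cell_carbon: morphology must contain a 'volume' column (um^3).")
  }
  v <- morphology$volume
  C_cell <- carbon_from_volume(v, model)
  dplyr::mutate(as_tibble(morphology),
                C_cell = C_cell,
                carbon_density = C_cell / v * 1e3)  # pg um^-3 -> gC L^-1
}

# volume (um^3) -> pgC under a carbon model; vectorized
carbon_from_volume <- function(volume, model) {
  if (model$kind == "fixed_density") return(model$density * volume * 1e-3)
  seg <- model$segments
  idx <- findInterval(volume, c(0, seg$vmax), rightmost.closed = FALSE)
  idx <- pmin(idx, nrow(seg))
  seg$a[idx] * volume^seg$b[idx]
}

#' Swimming speed allometry
#'
#' Empirical allometric swimming speed for flagellated protists,
#' `c = 38.542 * ESD^0.5424` um s^-1.
#'
#' @param ESD equivalent spherical diameter(s), um.
#' @return Swimming speed(s), um s^-1.
#' @examples
#' swimming_speed(10)  # ~134 um/s
#' @export
swimming_speed <- function(ESD) {
  if (any(!is.finite(ESD)) || any(ESD <= 0)) {
    abort("swimming_speed: ESD must be positive.")
  }
  38.542 * ESD^0.5424
}

#' Stokes sedimentation speed
#'
#' Terminal sinking speed of a small sphere by Stokes' law,
#' `c_sed = 2 g r^2 (rho_org - rho_w) / (9 eta)`, evaluated in SI units and
#' returned in um s^-1.
#'
#' @param radius cell radius (or radii), um.
#' @param env a [marine_environment()] supplying g, densities and viscosity.
#' @return Sinking speed(s), um s^-1.
#' @examples
#' sinking_speed(10)  # ~6.1 um/s with default constants
#' @export
sinking_speed <- function(radius, env = marine_environment()) {
  if (any(!is.finite(radius)) || any(radius < 0)) {
    abort("sinking_speed: radius must be non-negative.")
  }
  if (env$rho_org < env$rho_w) {
    abort("sinking_speed: rho_org < rho_w; buoyant ascent is not modelled.")
  }
  r_m <- radius * 1e-6
  drho <- (env$rho_org - env$rho_w) * 1e3    # kg L^-1 -> kg m^-3
  2 * env$g * r_m^2 * drho / (9 * env$eta) * 1e6
}
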