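#' Organism configuration
#'
#' Assembles the full trait set of a model cell: size, carbon model, motion
#' mode, quota (stoichiometry and G_max) and transporter parameters, plus the
#' mode used for the N-status response of maximum transport capacity:
#'
#' * `"eq5"` (default): the hypothetical up-regulation curve
#'   [tmax_hypothetical()] with headroom `T_add` derived from the membrane
#'   ceiling `TRD_max` via [t_add()];
#' * `"flat"`: capacity fixed at the replete floor `G_max * NC_max`
#'   (the implicit assumption of most ecosystem models);
#' * `"empirical"`: capacity interpolated from a user-supplied
#'   (NC, Tmax_specific) table via [empirical_tmax_curve()].
#'
#' Feasibility (`TRD_Gmax <= TRD_max`) is checked at construction for the
#' `"eq5"` mode: a large, carbon-dense, fast-growing cell may demand more
#' transporter density than the membrane can hold, in which case its `G_max`
#' is unattainable and construction fails.
#'
#' @param ESD equivalent spherical diameter, um.
#' @param carbon a [carbon_model()] or preset name (`"C150"`, `"Cprot"`,
#'   `"Cdiat"`).
#' @param motion `"none"`, `"swim"` (flagellate allometry,
#'   [swimming_speed()]) or `"sink"` (Stokes law, [sinking_speed()]).
#' @param quota a [quota_params()].
#' @param transporter a [transporter_params()].
#' @param tmax_mode `"eq5"`, `"flat"` or `"empirical"`.
#' @param tmax_table data frame of `NC`, `Tmax_specific` knots, required when
#'   `tmax_mode = "empirical"`.
#' @param env a [marine_environment()]; used for the feasibility check and
#'   stored as part of the configuration snapshot.
#' @return An object of class `nutrikin_organism` carrying the resolved
#'   morphology (radius, volume, SA, C_cell, carbon density), speed and
#'   transport capacity parameters.
#' @examples
#' org <- organism(10, carbon = "C150")
#' org
#' @export
organism <- function(ESD,
                     carbon = carbon_model("Cprot"),
                     motion = c("none", "swim", "sink"),
                     quota = quota_params(),
                     transporter = transporter_params(),
                     tmax_mode = c("eq5", "flat", "empirical"),
                     tmax_table = NULL,
                     env = marine_environment()) {
  motion <- match.arg(motion)
  tmax_mode <- match.arg(tmax_mode)
  if (is.character(carbon)) carbon <- carbon_model(carbon)
  stopifnot(inherits(carbon, "nutrikin_carbon"),
            inherits(quota, "nutrikin_quota"),
            inherits(transporter, "nutrikin_transporter"),
            inherits(env, "nutrikin_env"))

  morph <- cell_carbon(sphere_geometry(ESD), carbon)
  TRD_Gmax <- trd_gmax(quota$G_max, quota$NC_max, morph$C_cell, morph$SA)

  Tadd <- NA_real_
  tmax_fun <- NULL
  if (tmax_mode == "eq5") {
    Tadd <- t_add(transporter$TRD_max, TRD_Gmax)  # errors if infeasible
  } else if (tmax_mode == "empirical") {
    if (is.null(tmax_table)) {
      abort("organism: tmax_mode = 'empirical' requires a tmax_table.")
    }
    tmax_fun <- empirical_tmax_curve(tmax_table)
  }

  speed_um_s <- switch(motion,
    none = 0,
    swim = swimming_speed(ESD),
    sink = sinking_speed(morph$radius, env))

  structure(list(
    ESD = ESD, carbon = carbon, motion = motion, quota = quota,
    transporter = transporter, tmax_mode = tmax_mode,
    tmax_table = tmax_table, tmax_fun = tmax_fun, env = env,
    radius = morph$radius, volume = morph$volume, SA = morph$SA,
    C_cell = morph$C_cell, carbon_density = morph$carbon_density,
    TRD_Gmax = TRD_Gmax, T_add = Tadd,
    speed = speed_um_s * 86400   # um d^-1, internal time base
  ), class = "nutrikin_organism")
}

#' @export
print.nutrikin_organism <- function(x, ...) {
  cat(sprintf("<organism> ESD %g um (%s, %s, Tmax mode '%s')\n",
              x$ESD, x$carbon$label, x$motion, x$tmax_mode))
  cat(sprintf("  volume %.4g um^3, SA %.4g um^2, C_cell %.4g pgC (%.4g gC L^-1)\n",
              x$volume, x$SA, x$C_cell, x$carbon_density))
  cat(sprintf("  TRD_Gmax %.4g pgN um^-2 d^-1 (ceiling %.4g)",
              x$TRD_Gmax, x$transporter$TRD_max))
  if (is.finite(x$T_add)) cat(sprintf(", T_add %.3g", x$T_add))
  cat("\n")
  if (x$speed > 0) {
    cat(sprintf("  speed %.4g um s^-1 (%s)\n", x$speed / 86400, x$motion))
  }
  invisible(x)
}

# C-specific transport capacity at a given quota state, per the organism's
# tmax_mode. NC is needed for the empirical mode, NCu for eq5.
tmax_specific_at <- function(org, NCu, NC) {
  switch(org$tmax_mode,
    eq5 = tmax_hypothetical(NCu, org$quota, org$T_add, org$transporter$KT_con),
    flat = rep(org$quota$G_max * org$quota$NC_max, length(NCu)),
    empirical = org$tmax_fun(NC))
}
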