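#' Physiological state at a given growth rate
#'
#' The forward chain at the heart of the model. For each requested growth
#' rate `G` it resolves, deterministically and without iteration:
#'
#' 1. the N status `NCu = G / G_max` and quota `NC` (inverse quota curve);
#' 2. the steady-state transport demand `T = G * NC * C_cell`;
#' 3. the instantaneous capacity `Tmax_cell` at that N status (per the
#'    organism's `tmax_mode`);
#' 4. the membrane concentration `S0` that makes Michaelis-Menten transport
#'    meet the demand;
#' 5. the bulk concentration `S_inf` that drives the demand across the
#'    diffusive boundary layer, thinned by swimming or sinking.
#'
#' @param G growth rate(s), d^-1, in `[0, G_max]`; `G = G_max` is only
#'   attainable while capacity still exceeds demand there (`T_add > 0`).
#' @param org a [organism()].
#' @param env a [marine_environment()]; defaults to the one stored in `org`.
#' @return A tibble with one row per growth rate: `G`, `NCu`, `NC`,
#'   `T_demand`, `Tmax_cell` (pgN cell^-1 d^-1), `S0`, `S_inf` and the
#'   diffusive gradient `S_diff = S_inf - S0` (uM).
#' @examples
#' org <- organism(10, carbon = "C150")
#' solve_state_at_growth(org$quota$G_max / 2, org)
#' @export
solve_state_at_growth <- function(G, org, env = org$env) {
  q <- org$quota
  if (any(G < 0) || any(G > q$G_max)) {
    abort("solve_state_at_growth: G must lie in [0, G_max].")
  }
  NCu <- G / q$G_max
  NC <- quota_from_nstatus(NCu, q)
  T_demand <- required_transport(G, NC, org$C_cell)
  Tmax_cell <- tmax_specific_at(org, NCu, NC) * org$C_cell
  S0 <- substrate_at_membrane(T_demand, Tmax_cell, org$transporter$K_T)
  S_inf <- bulk_substrate(T_demand, S0, org$radius, org$speed, env)
  tibble(G = G, NCu = NCu, NC = NC, T_demand = T_demand,
         Tmax_cell = Tmax_cell, S0 = S0, S_inf = S_inf,
         S_diff = S_inf - S0)
}

#' Emergent half-saturation constant for growth
#'
#' `K_G` is the bulk substrate concentration at which growth runs at half its
#' maximum. It is evaluated directly at the half-maximal operating point
#' (`NCu = 0.5`) of [solve_state_at_growth()], and decomposes additively into
#' the membrane term `S0` (transporter kinetics) and the boundary-layer
#' gradient `S_diff` (diffusion).
#'
#' @inheritParams solve_state_at_growth
#' @return A one-row tibble: `ESD`, `K_G`, `S0`, `S_diff` (uM) and
#'   `affinity = G_max / K_G` (d^-1 uM^-1).
#' @examples
#' half_saturation_growth(organism(10, carbon = "C150"))
#' @export
half_saturation_growth <- function(org, env = org$env) {
  st <- solve_state_at_growth(org$quota$G_max / 2, org, env)
  tibble(ESD = org$ESD, K_G = st$S_inf, S0 = st$S0, S_diff = st$S_diff,
         affinity = org$quota$G_max / st$S_inf)
}

#' Emergent kinetic curve over a growth sweep
#'
#' Sweeps growth rate over a grid and records the full physiological state at
#' each point, yielding the emergent (S_inf, G) relation whose shape the
#' rectangular hyperbola is commonly (and imperfectly) fitted to. Grid points
#' whose demand reaches transport capacity are dropped with a warning.
#'
#' @param org a [organism()].
#' @param env a [marine_environment()].
#' @param n number of evenly spaced growth-rate points.
#' @param g_max_frac top of the sweep as a fraction of `G_max`; the default
#'   stops just short of saturation so that flat-capacity configurations
#'   remain solvable.
#' @param g_grid optional explicit growth-rate grid, overriding `n` and
#'   `g_max_frac`.
#' @return A tibble of class `nutrikin_curve` (columns as
#'   [solve_state_at_growth()]), with the organism stored in attribute
#'   `"organism"`.
#' @examples
#' kc <- kinetic_curve(organism(10, carbon = "C150"), n = 50)
#' head(kc)
#' @export
kinetic_curve <- function(org, env = org$env, n = 200, g_max_frac = 0.995,
                          g_grid = NULL) {
  if (is.null(g_grid)) {
    g_grid <- seq(0, g_max_frac * org$quota$G_max, length.out = n)
  }
  rows <- purrr::map(g_grid, function(g) {
    tryCatch(solve_state_at_growth(g, org, env),
             nutrikin_saturated = function(e) NULL)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0) {
    warn(sprintf("kinetic_curve: %d grid point(s) at or beyond transport saturation dropped.",
                 dropped))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "organism") <- org
  class(out) <- c("nutrikin_curve", class(out))
  out
}

#' Scan emergent K_G across cell size
#'
#' Rebuilds the organism at each ESD of a grid (all other traits held fixed)
#' and records the emergent half-saturation constant and affinity
#' `G_max / K_G`. Sizes whose `G_max` is infeasible under the transporter
#' density ceiling are flagged rather than dropped.
#'
#' @param esd vector of equivalent spherical diameters, um. Default: 25
#'   log-spaced points on `[2, 80]` um.
#' @param carbon,motion,quota,transporter,tmax_mode,env passed to
#'   [organism()].
#' @return A tibble of class `nutrikin_scan`: `ESD`, `feasible`, `K_G`, `S0`,
#'   `S_diff`, `affinity`.
#' @examples
#' esd_scan(carbon = "C150") |> head()
#' @export
esd_scan <- function(esd = esd_grid(),
                     carbon = carbon_model("Cprot"),
                     motion = c("none", "swim", "sink"),
                     quota = quota_params(),
                     transporter = transporter_params(),
                     tmax_mode = c("eq5", "flat"),
                     env = marine_environment()) {
  motion <- match.arg(motion)
  tmax_mode <- match.arg(tmax_mode)
  if (is.character(carbon)) carbon <- carbon_model(carbon)
  out <- purrr::map(esd, function(e) {
    res <- tryCatch({
      org <- organism(e, carbon = carbon, motion = motion, quota = quota,
                      transporter = transporter, tmax_mode = tmax_mode,
                      env = env)
      dplyr::mutate(half_saturation_growth(org, env), feasible = TRUE,
                    .before = 1)
    },
    nutrikin_infeasible = function(e2) {
      tibble(feasible = FALSE, ESD = e, K_G = NA_real_, S0 = NA_real_,
             S_diff = NA_real_, affinity = NA_real_)
    },
    nutrikin_saturated = function(e2) {
      tibble(feasible = FALSE, ESD = e, K_G = NA_real_, S0 = NA_real_,
             S_diff = NA_real_, affinity = NA_real_)
    })
    res
  })
  out <- dplyr::bind_rows(out)
  out <- dplyr::relocate(out, "ESD", .before = 1)
  attr(out, "config") <- list(carbon = carbon$label, motion = motion,
                              quota = quota, transporter = transporter,
                              tmax_mode = tmax_mode)
  class(out) <- c("nutrikin_scan", class(out))
  out
}

#' Default logarithmic ESD grid
#'
#' @param from,to grid end points, um.
#' @param n number of points.
#' @return Log-spaced diameters, um.
#' @export
esd_grid <- function(from = 2, to = 80, n = 25) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Sensitivity of K_G to the transporter half-saturation
#'
#' Recomputes the emergent `K_G` with the transporter `K_T` scaled by each
#' factor and reports the ratio to the unscaled value. The membrane component
#' `S0` scales exactly linearly in `K_T` while the diffusive component is
#' invariant, so the ratio is a size- and motion-dependent blend strictly
#' between the factor and 1.
#'
#' @param org a [organism()].
#' @param env a [marine_environment()].
#' @param factors multiplicative factors applied to `K_T`.
#' @return A tibble: `factor`, `K_T`, `K_G`, `ratio` (K_G relative to the
#'   factor-1 value).
#' @examples
#' kt_sensitivity(organism(10, carbon = "C150"))
#' @export
kt_sensitivity <- function(org, env = org$env, factors = c(0.5, 2)) {
  base <- half_saturation_growth(org, env)$K_G
  rows <- purrr::map(factors, function(f) {
    tr <- org$transporter
    org2 <- organism(org$ESD, carbon = org$carbon, motion = org$motion,
                     quota = org$quota,
                     transporter = transporter_params(K_T = f * tr$K_T,
                                                      TRD_max = tr$TRD_max,
                                                      KT_con = tr$KT_con),
                     tmax_mode = org$tmax_mode, tmax_table = org$tmax_table,
                     env = env)
    kg <- half_saturation_growth(org2, env)$K_G
    tibble(factor = f, K_T = f * tr$K_T, K_G = kg, ratio = kg / base)
  })
  dplyr::bind_rows(rows)
}

#' Transporter-density feasibility surface
#'
#' Evaluates the transporter rate density required for maximal growth,
#' `TRD_Gmax`, over a grid of carbon models, cell sizes and maximum growth
#' rates, flagging combinations that demand more than the membrane ceiling
#' `TRD_max` can supply. Large, fast-growing, carbon-dense protists approach
#' and cross this frontier.
#'
#' @param carbon_models character vector of carbon model presets (or a list
#'   of [carbon_model()] objects).
#' @param esd cell diameters, um.
#' @param gmax maximum growth rates, d^-1.
#' @param NC_max maximum N:C quota, gN gC^-1.
#' @param TRD_max membrane ceiling, pgN um^-2 d^-1.
#' @return A tibble: `carbon`, `ESD`, `G_max`, `TRD_Gmax`, `feasible`.
#' @examples
#' trd_feasibility_surface(c("Cprot", "Cdiat"), esd = c(10, 40),
#'                         gmax = c(0.35, 1.4))
#' @export
trd_feasibility_surface <- function(carbon_models = c("C150", "Cprot", "Cdiat"),
                                    esd = esd_grid(),
                                    gmax = seq(0.2, 1.4, by = 0.2),
                                    NC_max = 0.18, TRD_max = 0.4) {
  models <- purrr::map(carbon_models, function(m) {
    if (is.character(m)) carbon_model(m) else m
  })
  grid <- tidyr::expand_grid(model = models, ESD = esd, G_max = gmax)
  morph <- sphere_geometry(grid$ESD)
  C_cell <- purrr::map2_dbl(grid$model, morph$volume, function(m, v) {
    carbon_from_volume(v, m)
  })
  tibble(
    carbon = vapply(grid$model, function(m) m$label, character(1)),
    ESD = grid$ESD,
    G_max = grid$G_max,
    TRD_Gmax = trd_gmax(grid$G_max, NC_max, C_cell, morph$SA)
  ) |>
    dplyr::mutate(feasible = .data$TRD_Gmax <= TRD_max)
}
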