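test_that("the worked operating point of the standard cell resolves correctly", {
  org <- std_org()
  st <- solve_state_at_growth(org$quota$G_max / 2, org)
  expect_equal(st$NC, 0.1119, tolerance = 1e-3)
  expect_equal(st$T_demand, 3.045, tolerance = 1e-3)
  expect_equal(st$Tmax_cell, 116.0, tolerance = 1e-3)
  expect_equal(st$S0, 0.0270, tolerance = 2e-3)
  expect_equal(st$S_inf, 0.0537, tolerance = 2e-3)

  zero <- solve_state_at_growth(0, org)
  expect_equal(zero[c("T_demand", "S0", "S_inf")],
               tibble::tibble(T_demand = 0, S0 = 0, S_inf = 0))
  expect_error(solve_state_at_growth(2, org), "G_max")
})

test_that("flat transport capacity saturates exactly at maximal growth", {
  org <- organism(10, carbon = "C150", tmax_mode = "flat")
  expect_error(solve_state_at_growth(org$quota$G_max, org),
               class = "nutrikin_saturated")
  # just below G_max it still solves
  st <- solve_state_at_growth(0.99 * org$quota$G_max, org)
  expect_true(st$S_inf > 0)
})

test_that("emergent half-saturation decomposes into membrane and diffusion parts", {
  kg <- half_saturation_growth(std_org())
  expect_equal(kg$K_G, 0.0537, tolerance = 2e-3)
  expect_equal(kg$K_G, kg$S0 + kg$S_diff)
  expect_equal(kg$affinity, 0.693 / kg$K_G)
})

test_that("kinetic curves are monotone and pass through (K_G, G_max/2)", {
  org <- std_org()
  # a grid containing G_max/2 exactly; G_max itself is excluded because the
  # replete capacity floor equals the replete demand exactly
  kc <- kinetic_curve(org, g_grid = org$quota$G_max * seq(0, 0.99, by = 0.01))
  expect_true(all(diff(kc$S_inf) > 0))
  kg <- half_saturation_growth(org)
  expect_equal(kc$S_inf[kc$G == org$quota$G_max / 2], kg$K_G,
               tolerance = 1e-12)

  # up-regulating capacity under stress lowers the whole curve
  flat <- kinetic_curve(organism(10, carbon = "C150", tmax_mode = "flat"),
                        g_grid = kc$G[kc$G > 0])
  expect_true(all(flat$S_inf > kc$S_inf[kc$G > 0]))

  # motion lowers the whole curve
  swim <- kinetic_curve(organism(10, carbon = "C150", motion = "swim"),
                        g_grid = kc$G[kc$G > 0])
  expect_true(all(swim$S_inf < kc$S_inf[kc$G > 0]))
})

test_that("saturated sweep points are dropped with a warning", {
  org <- organism(10, carbon = "C150", tmax_mode = "flat")
  expect_warning(kc <- kinetic_curve(org, g_grid = seq(0, 0.693, length.out = 20)),
                 "saturation")
  expect_lt(nrow(kc), 20)
})

test_that("K_G rises with cell size and falls with motion and vacuolation", {
  esd <- esd_grid(n = 12)
  for (cm in c("C150", "Cprot", "Cdiat")) {
    sc <- esd_scan(esd, carbon = cm)
    expect_true(all(diff(sc$K_G) > 0))
  }
  still <- esd_scan(esd, carbon = "Cprot", motion = "none")
  moving <- esd_scan(esd, carbon = "Cprot", motion = "swim")
  expect_true(all(moving$K_G < still$K_G))

  # diatom vacuolation beats fixed density at large sizes
  c150 <- esd_scan(esd, carbon = "C150")
  cdiat <- esd_scan(esd, carbon = "Cdiat")
  big <- esd > 20
  expect_true(all(cdiat$K_G[big] < c150$K_G[big]))
})

test_that("infeasible sizes are flagged, not dropped, in scans", {
  # a very fast-growing dense cell overruns the membrane ceiling when large
  fast <- quota_params(G_max = 2.8)
  sc <- esd_scan(esd_grid(2, 200, 15), carbon = "C150", quota = fast)
  expect_true(any(!sc$feasible))
  expect_true(any(sc$feasible))
  expect_true(all(is.na(sc$K_G[!sc$feasible])))
  expect_equal(nrow(sc), 15)
  # and power_fit silently uses only the feasible points
  pf <- power_fit(sc)
  expect_equal(nrow(pf$data), sum(sc$feasible))
})

test_that("halving or doubling K_T moves K_G less than pro rata", {
  sens <- kt_sensitivity(std_org(), factors = c(0.5, 1, 2))
  expect_equal(sens$ratio[sens$factor == 1], 1)
  expect_equal(sens$ratio[sens$factor == 0.5], 0.75, tolerance = 0.02)
  expect_equal(sens$ratio[sens$factor == 2], 1.50, tolerance = 0.02)
  # strictly between the factor and 1: diffusion does not care about K_T
  expect_gt(sens$ratio[sens$factor == 0.5], 0.5)
  expect_lt(sens$ratio[sens$factor == 2], 2)
})

test_that("affinity G_max/K_G is nearly invariant in G_max", {
  for (cm in c("C150", "Cdiat")) {
    aff <- sapply(c(0.2, 0.693, 1.4), function(gm) {
      org <- organism(15, carbon = cm, quota = quota_params(G_max = gm))
      half_saturation_growth(org)$affinity
    })
    expect_lt(diff(range(aff)) / mean(aff), 0.10)
  }
})

test_that("the transporter-density surface ranks carbon models and scales linearly", {
  surf <- trd_feasibility_surface(c("Cprot", "Cdiat"),
                                  esd = c(5, 20, 60), gmax = c(0.35, 0.7, 1.4))
  wide <- tidyr::pivot_wider(surf, names_from = "carbon",
                             values_from = "TRD_Gmax",
                             id_cols = c("ESD", "G_max"))
  expect_true(all(wide$Cdiat < wide$Cprot))

  # fixed density: TRD_Gmax = G_max NC_max density ESD / 6 * 1e-3, linear in ESD
  s150 <- trd_feasibility_surface("C150", esd = c(10, 20, 40), gmax = 0.693)
  expect_equal(s150$TRD_Gmax, 0.693 * 0.18 * 150 * c(10, 20, 40) / 6 * 1e-3)

  tiny <- trd_feasibility_surface("Cprot", esd = 20, gmax = 1e-9)
  expect_lt(tiny$TRD_Gmax, 1e-9)

  # frontier flag: large fast protists overrun the ceiling
  frontier <- trd_feasibility_surface("C150", esd = 150, gmax = 1.4)
  expect_false(frontier$feasible)
})

test_that("organism construction rejects infeasible trait combinations", {
  expect_error(organism(150, carbon = "C150",
                        quota = quota_params(G_max = 1.4)),
               class = "nutrikin_infeasible")
  # the same traits are constructible under a flat capacity assumption
  org <- organism(150, carbon = "C150", quota = quota_params(G_max = 1.4),
                  tmax_mode = "flat")
  expect_s3_class(org, "nutrikin_organism")
})

test_that("scan and curve plots build without error", {
  sc <- esd_scan(esd_grid(n = 6), carbon = "C150")
  expect_s3_class(ggplot2::autoplot(sc), "ggplot")
  kc <- kinetic_curve(std_org(), n = 30)
  expect_s3_class(ggplot2::autoplot(kc), "ggplot")
})
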