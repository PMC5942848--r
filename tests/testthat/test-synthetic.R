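test_that("uptake generator is exact without noise and reproducible with it", {
  up0 <- gen_uptake_experiment(2, 0.8, noise_cv = 0)
  expect_equal(up0$rate, 2 * up0$S / (up0$S + 0.8))
  expect_equal(up0$rate, up0$true_rate)

  a <- gen_uptake_experiment(1, 0.5, noise_cv = 0.1, seed = 99)
  b <- gen_uptake_experiment(1, 0.5, noise_cv = 0.1, seed = 99)
  c <- gen_uptake_experiment(1, 0.5, noise_cv = 0.1, seed = 100)
  expect_identical(a$rate, b$rate)
  expect_false(identical(a$rate, c$rate))
  expect_true(all(a$rate >= 0))
  expect_error(gen_uptake_experiment(1, 0.5, noise_cv = 0.1), "seed")
  expect_error(gen_uptake_experiment(1, 0.5, grid = c(1, 1, 2)), "increasing")
})

test_that("the generators leave the global random state alone", {
  set.seed(1234)
  before <- .Random.seed
  gen_uptake_experiment(1, 0.5, noise_cv = 0.2, seed = 5)
  gen_tmax_table(jitter_cv = 0.05, seed = 6)
  expect_identical(.Random.seed, before)
})

test_that("synthetic capacity tables have the stressed-peak shape", {
  q <- quota_params()
  tab <- gen_tmax_table(q, peak_multiplier = 8, collapse_fraction = 0.3,
                        n_knots = 41)
  sh <- attr(tab, "shape")
  expect_equal(range(tab$NC), c(q$NC_min, q$NC_max))
  expect_equal(max(tab$Tmax_specific), sh$floor * 8, tolerance = 1e-6)
  # collapses under extreme stress, relaxes to the floor when replete
  expect_equal(tab$Tmax_specific[1], 0.3 * sh$floor * 8)
  expect_equal(tab$Tmax_specific[41], sh$floor)
  # single interior maximum: rises then falls
  dd <- diff(tab$Tmax_specific)
  turn <- which(dd < 0)[1]
  expect_true(all(dd[seq_len(turn - 1)] > 0))
  expect_true(all(dd[turn:length(dd)] < 0))
  # replete value covers the demand of maximal growth
  expect_gte(tab$Tmax_specific[41], q$G_max * q$NC_max)

  # nitrate-style repression pushes the replete end below the floor
  rep_tab <- gen_tmax_table(q, repress = 0.5)
  expect_equal(rep_tab$Tmax_specific[nrow(rep_tab)], sh$floor * 0.5)

  # degenerate limit: peak barely above the floor gives a near-flat curve
  flatish <- gen_tmax_table(q, peak_multiplier = 1 + 1e-6,
                            collapse_fraction = 0.999)
  expect_lt(diff(range(flatish$Tmax_specific)) / sh$floor, 2e-3)

  expect_error(gen_tmax_table(q, peak_multiplier = 0.9), "exceed 1")
  expect_error(gen_tmax_table(q, collapse_fraction = 1), "collapse_fraction")
})

test_that("interpolating a default table stays within 2% of its generator", {
  q <- quota_params()
  tab <- gen_tmax_table(q)
  f <- empirical_tmax_curve(tab)
  g <- nutrikin:::tmax_shape_fun(attr(tab, "shape"), q)
  nc <- seq(q$NC_min, q$NC_max, length.out = 10 * nrow(tab))
  expect_lt(max(abs(f(nc) - g(nc))) / attr(tab, "shape")$peak, 0.02)
})

test_that("an empirical capacity curve drives the full pipeline to a biased hyperbola", {
  q <- quota_params()
  tab <- gen_tmax_table(q)
  org <- organism(6, carbon = "Cprot", tmax_mode = "empirical",
                  tmax_table = tab, quota = q)
  kc <- kinetic_curve(org, n = 120)
  f <- fit_rht2(kc)
  expect_gt(f$r.squared, 0.95)
  # the apparent half-saturation sits far below the transporter's K_T
  expect_lt(f$K, 0.5 * org$transporter$K_T)
})
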