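test_that("required transporter density matches the reference cell budgets", {
  expect_equal(trd_gmax(1.4, 0.15, 12.31, 63.62), 0.0406, tolerance = 2e-3)
  expect_equal(trd_gmax(1.4, 0.18, 462, 605.21), 0.1924, tolerance = 2e-3)
  expect_equal(trd_gmax(1.4, 0.15, 7.25, 63.62), 0.0239, tolerance = 2e-3)
  expect_error(trd_gmax(0, 0.18, 100, 300), "positive")
})

test_that("over-capacity multiplier and its infeasibility frontier", {
  expect_equal(t_add(0.4, 0.0406), (0.4 - 0.0406) / 0.0406)
  expect_equal(t_add(0.4, 0.0406), 8.852, tolerance = 1e-3)
  expect_equal(t_add(0.25, 0.25), 0)
  expect_error(t_add(0.4, 0.5), class = "nutrikin_infeasible")
})

test_that("capacity response to N status has the stated floor, ceiling and shape", {
  q <- quota_params()
  # replete floor: exactly the demand of maximal growth
  expect_equal(tmax_hypothetical(1, q, T_add = 5), q$G_max * q$NC_max)
  # full stress ceiling is (1 + T_add) x floor for any shape constant
  for (ktc in c(0.01, 0.1, 1, 10)) {
    expect_equal(tmax_hypothetical(0, q, T_add = 7, KT_con = ktc),
                 q$G_max * q$NC_max * 8)
  }
  # worked mid-stress value
  qh <- quota_params(NC_max = 0.18, G_max = 0.693)
  expect_equal(tmax_hypothetical(0.5, qh, T_add = 11.83, KT_con = 0.1),
               1.477, tolerance = 1e-3)
  # monotone: capacity never rises with improving N status
  ncu <- seq(0, 1, length.out = 50)
  v <- tmax_hypothetical(ncu, q, T_add = 3)
  expect_true(all(diff(v) < 0))
  # T_add = 0 collapses to a flat capacity
  expect_equal(tmax_hypothetical(ncu, q, T_add = 0),
               rep(q$G_max * q$NC_max, 50))
})

test_that("membrane transport and its inversion are exact inverses", {
  expect_equal(transport_rate(1, 10, K_T = 1), 5)       # half-saturation
  expect_equal(transport_rate(0, 10, K_T = 1), 0)
  expect_equal(transport_rate(1e6, 10, K_T = 1), 10, tolerance = 1e-5)

  expect_equal(substrate_at_membrane(5, 10, K_T = 1), 1)
  # worked half-growth operating point of the standard cell
  expect_equal(substrate_at_membrane(3.045, 116.03, K_T = 1), 0.02695,
               tolerance = 1e-3)

  set.seed(11)
  S0 <- runif(100, 0, 50)
  Tm <- runif(100, 1, 200)
  expect_equal(substrate_at_membrane(transport_rate(S0, Tm, 0.7), Tm, 0.7),
               S0, tolerance = 1e-10)
  expect_error(substrate_at_membrane(12, 10, 1), class = "nutrikin_saturated")
})

test_that("empirical capacity tables interpolate monotonically without overshoot", {
  q <- quota_params()
  flat <- tibble::tibble(NC = seq(0.05, 0.18, length.out = 5),
                         Tmax_specific = rep(2, 5))
  f <- empirical_tmax_curve(flat)
  expect_equal(f(seq(0.06, 0.17, by = 0.01)), rep(2, 12))

  tab <- gen_tmax_table(q, seed = 3)
  f <- empirical_tmax_curve(tab)
  expect_equal(f(tab$NC), tab$Tmax_specific)   # exact at the knots
  # the interpolated maximum lies between the two highest knots
  nc_fine <- seq(0.05, 0.18, length.out = 2000)
  peak_nc <- nc_fine[which.max(f(nc_fine))]
  top2 <- sort(tab$NC[order(-tab$Tmax_specific)][1:2])
  expect_gte(peak_nc, top2[1])
  expect_lte(peak_nc, top2[2])
  # queries beyond the table clamp with a warning
  expect_warning(v <- f(0.3), "clamp")
  expect_equal(v, tab$Tmax_specific[nrow(tab)])

  expect_error(empirical_tmax_curve(flat[1:2, ]), "3 knots")
  expect_error(empirical_tmax_curve(flat[c(1, 1, 2), ]), "increasing")
})

test_that("pooled transporters push the apparent half-saturation below K_T", {
  expect_equal(multi_transporter_halfsat(4, 1, 1, 2), 1 / 3)
  expect_equal(multi_transporter_halfsat(8, 1, 1, 2), 1 / 7)
  expect_equal(multi_transporter_halfsat(16, 1, 1, 2), 1 / 15)
  expect_lt(multi_transporter_halfsat(1e6, 1, 1, 2), 1e-5)  # n -> infinity
  expect_error(multi_transporter_halfsat(1, 1, 1, 2),
               class = "nutrikin_saturated")
})
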