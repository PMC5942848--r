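test_that("sphere geometry matches measured reference cells and closed forms", {
  g <- sphere_geometry(c(4.5, 11.5, 13.9, 2))

  # reference biovolumes/areas were measured; ESD round-trip agrees to < 0.5%
  expect_equal(g$volume[1:3], c(47.7, 800, 1400), tolerance = 5e-3)
  expect_equal(g$SA[1:3], c(63.62, 416.75, 605.21), tolerance = 5e-3)

  expect_equal(g$volume[4], pi / 6 * 8)   # exact closed form
  expect_equal(g$radius, c(4.5, 11.5, 13.9, 2) / 2)

  expect_error(sphere_geometry(0), "positive")
  expect_error(sphere_geometry(-3), "positive")
})

test_that("sphere surface and volume are self-consistent: SA^3 = 36 pi V^2", {
  esd <- exp(seq(log(0.5), log(500), length.out = 40))
  g <- sphere_geometry(esd)
  expect_equal(g$SA^3, 36 * pi * g$volume^2, tolerance = 1e-12)
})

test_that("carbon models reproduce reference carbon contents and densities", {
  # protist allometry at the coccolithophore's size
  m <- sphere_geometry(4.5) |> cell_carbon("Cprot")
  expect_equal(m$C_cell, 7.25, tolerance = 2e-3)

  # diatom allometry at the diatom's size: vacuolation lowers density
  m <- sphere_geometry(13.9) |> cell_carbon("Cdiat")
  expect_equal(m$C_cell, 102.54, tolerance = 5e-3)
  expect_equal(m$carbon_density, 73.24, tolerance = 5e-3)

  # fixed density: C_cell = density * volume, density constant by construction
  m <- sphere_geometry(c(5, 10, 40)) |> cell_carbon("C150")
  expect_equal(m$C_cell[2], 150 * (pi / 6 * 1000) * 1e-3)
  expect_equal(m$carbon_density, rep(150, 3))
})

test_that("single-segment allometric density decreases with size when b < 1", {
  cm <- carbon_model("allometric", a = 0.261, b = 0.86)
  m <- sphere_geometry(seq(2, 80, by = 2)) |> cell_carbon(cm)
  expect_true(all(diff(m$carbon_density) < 0))
  expect_error(carbon_model("allometric", a = 0.3, b = 1.2), "b <= 1")
  expect_error(carbon_model("allometric", a = -1, b = 0.8), "a > 0")
})

test_that("preset allometries use the small-cell coefficients below 3000 um^3", {
  # below the size-class boundary both presets equal their printed power laws
  v <- c(100, 1000, 2500)
  cp <- cell_carbon(tibble::tibble(volume = v), "Cprot")
  expect_equal(cp$C_cell, 0.261 * v^0.86)
  cd <- cell_carbon(tibble::tibble(volume = v), "Cdiat")
  expect_equal(cd$C_cell, 0.288 * v^0.811)
  # above it the large-cell relations take over
  cp2 <- cell_carbon(tibble::tibble(volume = 1e5), "Cprot")
  expect_equal(cp2$C_cell, 10^-0.665 * 1e5^0.939)
})

test_that("swimming allometry follows the empirical power law", {
  expect_equal(swimming_speed(1), 38.542)
  expect_equal(swimming_speed(10), 38.542 * 10^0.5424)
  expect_equal(swimming_speed(10), 134.4, tolerance = 1e-3)
  esd <- seq(1, 100, by = 1)
  expect_true(all(diff(swimming_speed(esd)) > 0))
  expect_error(swimming_speed(-1), "positive")
})

test_that("Stokes sedimentation speed is quadratic in radius", {
  expect_equal(sinking_speed(10), 6.10, tolerance = 1e-3)
  expect_equal(sinking_speed(0), 0)
  expect_equal(sinking_speed(20) / sinking_speed(10), 4)
  r <- seq(1, 60, by = 1)
  expect_true(all(diff(sinking_speed(r)) > 0))
  # buoyant cells are out of scope
  light <- marine_environment(rho_org = 1.0, rho_w = 1.033)
  expect_error(sinking_speed(10, light), "buoyant")
})

test_that("concentration unit conversion round-trips at machine precision", {
  x <- c(1e-4, 0.037, 1, 250)
  expect_equal(uM(pg_per_um3(x)), x, tolerance = 1e-14)
  expect_equal(pg_per_um3(1), 1.4e-8)   # 1 uM N = 14 ug/L
  expect_equal(pg_per_um3(1, molar_mass = 31), 3.1e-8)  # phosphorus
})
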