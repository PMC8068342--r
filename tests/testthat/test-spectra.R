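test_that("dose-weighted spectral average reduces to the discrete weighted mean", {
  sp <- fluence_spectrum(c(1, 2), c(1, 1))
  lt <- stopping_power_table(c(1, 2), c(1, 3))
  ## hand quadrature: (2*1 + 6*3) / (1 + 3)
  expect_equal(spectrum_average(energy_resolved_yield(c(1, 2), c(2, 6)), sp, lt), 5)
})

test_that("constant curves average to the constant for any spectrum", {
  fx <- make_synthetic_spectrum(seed = 2)
  e <- fx$spectrum$energy
  const <- energy_resolved_yield(e, rep(8.29, length(e)))
  expect_equal(spectrum_average(const, fx$spectrum, fx$let), 8.29)
  expect_equal(spectrum_average(8.29, fx$spectrum, fx$let), 8.29)
})

test_that("a delta-like spectrum evaluates the curve at its support", {
  e <- c(0.01, 0.1, 0.1001, 0.5)
  sp <- fluence_spectrum(e, c(0, 1, 1, 0))
  lt <- stopping_power_table(e, c(5, 2, 2, 1))
  y <- energy_resolved_yield(e, c(10, 4, 4, 7))
  expect_equal(spectrum_average(y, sp, lt), 4, tolerance = 1e-3)
})

test_that("spectrum averaging is linear in the curve and fluence-scale invariant", {
  fx <- make_synthetic_spectrum(n_grid = 24, jitter = 0.2, seed = 5)
  e <- fx$spectrum$energy
  y1 <- energy_resolved_yield(e, e^0.5)
  y2 <- energy_resolved_yield(e, 2 + cos(e))
  a1 <- spectrum_average(y1, fx$spectrum, fx$let)
  a2 <- spectrum_average(y2, fx$spectrum, fx$let)
  ycomb <- energy_resolved_yield(e, 3 * e^0.5 + 0.5 * (2 + cos(e)))
  expect_equal(spectrum_average(ycomb, fx$spectrum, fx$let), 3 * a1 + 0.5 * a2)
  scaled <- fluence_spectrum(e, fx$spectrum$fluence * 137)
  expect_equal(spectrum_average(y1, scaled, fx$let), a1)
})

test_that("disjoint supports and degenerate inputs are rejected", {
  sp <- fluence_spectrum(c(1, 2), c(1, 1))
  lt <- stopping_power_table(c(1, 2), c(1, 3))
  y <- energy_resolved_yield(c(5, 6), c(1, 1))
  expect_error(spectrum_average(y, sp, lt), "disjoint")
  expect_error(fluence_spectrum(c(1, 1), c(1, 1)), "strictly increasing")
  expect_error(fluence_spectrum(c(1, 2), c(0, 0)), "identically zero")
  expect_error(stopping_power_table(c(1, 2), c(0, 3)), "positive")
  expect_error(make_synthetic_spectrum(n_grid = 4), ">= 8")
})

test_that("synthetic spectra are reproducible and hit a requested mean LET", {
  a <- make_synthetic_spectrum(jitter = 0.1, seed = 11)
  b <- make_synthetic_spectrum(jitter = 0.1, seed = 11)
  expect_identical(a$spectrum$fluence, b$spectrum$fluence)
  d <- make_synthetic_spectrum(jitter = 0.1, seed = 12)
  expect_false(identical(a$spectrum$fluence, d$spectrum$fluence))
  ## dose-weighted mean LET pinned to the gamma-ray nominal 2.4 keV/um
  g <- make_synthetic_spectrum(mean_let = 2.4, seed = 11)
  e <- g$spectrum$energy
  realised <- spectrum_average(energy_resolved_yield(e, let_at(g$let, e)),
                               g$spectrum, g$let)
  expect_equal(realised, 2.4, tolerance = 1e-10)
})

test_that("two-column CSV round-trips spectra and stopping-power tables", {
  fx <- make_synthetic_spectrum(n_grid = 12, seed = 3)
  f <- tempfile(fileext = ".csv")
  writeLines(c("# energy: MeV, value: arbitrary fluence",
               "energy,value",
               paste(fx$spectrum$energy, fx$spectrum$fluence, sep = ",")), f)
  sp <- read_spectrum_csv(f, "spectrum")
  expect_equal(sp$energy, fx$spectrum$energy)
  expect_equal(sp$fluence, fx$spectrum$fluence)
  unlink(f)
})
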