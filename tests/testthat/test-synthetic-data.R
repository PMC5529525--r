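test_that("peak shapes evaluate as specified", {
  g <- seq(600, 800, by = 0.5)
  p <- make_component_profile("x", list(peak_spec(700, 20, 1)), g,
                              unit_concentration = 20)
  y <- p$reference$intensities
  expect_equal(max(y), 1)
  expect_equal(g[which.max(y)], 700)
  # half maximum at center +/- fwhm/2
  expect_equal(y[g == 710], 0.5, tolerance = 1e-9)

  # two non-overlapping peaks: integral additivity
  p1 <- list(peak_spec(650, 10, 1))
  p2 <- list(peak_spec(760, 10, 1))
  int <- function(peaks) {
    prof <- make_component_profile("x", peaks, g, unit_concentration = 20)
    sum(prof$reference$intensities) * 0.5
  }
  expect_equal(int(c(p1, p2)), int(p1) + int(p2), tolerance = 1e-6)

  expect_error(make_component_profile("x", list(peak_spec(900, 10, 1)), g),
               "outside")
  expect_error(peak_spec(700, -1, 1), "fwhm")
  expect_error(peak_spec(700, 10, -1), "amplitude")
})

test_that("pseudo-Voigt interpolates between Gaussian and Lorentzian", {
  g <- seq(600, 800, by = 1)
  mk <- function(shape, eta = 0.5) {
    make_component_profile("x", list(peak_spec(700, 20, 1, shape, eta = eta)),
                           g, unit_concentration = 20)$reference$intensities
  }
  gauss <- mk("gaussian"); lor <- mk("lorentzian")
  pv <- mk("pseudo_voigt", eta = 0.3)
  expect_equal(pv, 0.3 * lor + 0.7 * gauss, tolerance = 1e-9)
  # Lorentzian has the heavier tails
  expect_gt(lor[g == 640], gauss[g == 640])
})

test_that("default library components are mutually well separated", {
  lib <- default_component_library()
  M <- vapply(lib$components, function(cp) cp$reference$intensities,
              numeric(length(lib$grid)))
  nms <- colnames(M)
  for (i in 1:(length(nms) - 1)) for (j in (i + 1):length(nms)) {
    cs <- sum(M[, i] * M[, j]) /
      sqrt(sum(M[, i]^2) * sum(M[, j]^2))
    expect_lt(cs, 0.8)
  }
})

test_that("spectrum simulation is seeded and closes the loop with the fit", {
  lib <- default_component_library()
  a <- simulate_spectrum(lib, c(protein = 0.5), noise_sd = 0.1, seed = 42)
  b <- simulate_spectrum(lib, c(protein = 0.5), noise_sd = 0.1, seed = 42)
  expect_identical(a$spectrum$intensities, b$spectrum$intensities)

  clean <- simulate_spectrum(lib, c(protein = 0.6, lipid = 0.9))
  f <- fit_lcm(clean$spectrum, lib)
  expect_equal(unname(f$weights[c("protein", "lipid")]), c(0.6, 0.9),
               tolerance = 1e-6)
  expect_error(simulate_spectrum(lib, c(protein = 0.5), noise_sd = -1),
               "noise_sd")
  expect_error(simulate_spectrum(lib, c(saccharide = 0.5)), "unknown")
})

test_that("residual noise of the fit tracks the generating noise level", {
  lib <- default_component_library()
  noise_sd <- max(vapply(lib$components,
                         function(cp) max(cp$reference$intensities),
                         numeric(1))) / 20
  ratio <- replicate(100, {
    i <- sample.int(1e6, 1)
    sim <- simulate_spectrum(lib, c(protein = 0.85, RNA = 1.3, lipid = 1.1),
                             noise_sd = noise_sd, seed = i)
    f <- fit_lcm(sim$spectrum, lib, fit_options(allow_shift = FALSE))
    f$rms_residual / noise_sd
  })
  expect_lt(abs(mean(ratio) - 1), 0.15)
})

test_that("independent population variables stay uncorrelated", {
  v <- c("nucleolus.protein", "nucleolus.RNA", "nucleolus.lipid")
  spec <- population_spec(1000, "L",
                          means = c(nucleolus.protein = 85,
                                    nucleolus.RNA = 27.5,
                                    nucleolus.lipid = 22.5),
                          sds = c(nucleolus.protein = 17.5,
                                  nucleolus.RNA = 8.75,
                                  nucleolus.lipid = 6.25),
                          seed = 314)
  pop <- simulate_population(spec)
  wide <- sapply(c("protein", "RNA", "lipid"), function(a) {
    pop$concentration_mgml[pop$analyte == a]
  })
  cm <- cor(wide)
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.1)
  expect_true(all(pop$concentration_mgml > 0))
})

test_that("a specified protein-RNA correlation of 0.8 is realized", {
  vn <- c("nucleolus.protein", "nucleolus.RNA")
  R <- matrix(c(1, 0.8, 0.8, 1), 2, dimnames = list(vn, vn))
  spec <- population_spec(200, "L",
                          means = c(nucleolus.protein = 85,
                                    nucleolus.RNA = 27.5),
                          sds = c(nucleolus.protein = 17.5,
                                  nucleolus.RNA = 8.75),
                          correlation = R, seed = 2718)
  pop <- simulate_population(spec)
  r <- correlate_within(pop, "nucleolus", c("protein", "RNA"))$r
  # Fisher-z 99% interval around 0.8 at n = 200
  z <- atanh(0.8); hw <- qnorm(0.995) / sqrt(200 - 3)
  expect_gt(r, tanh(z - hw))
  expect_lt(r, tanh(z + hw))
})

test_that("population specs validate their covariance and reproduce", {
  vn <- c("a.x", "a.y")
  bad <- matrix(c(1, 1.2, 1.2, 1), 2, dimnames = list(vn, vn))
  expect_error(population_spec(10, "L", means = c(a.x = 1, a.y = 1),
                               sds = c(a.x = 1, a.y = 1), correlation = bad),
               "eigenvalue")
  expect_error(population_spec(2, "L", means = c(a.x = 1),
                               sds = c(a.x = 1)), "n_cells")
  sp <- population_spec(3, "L", means = c(a.x = 10, a.y = 20),
                        sds = c(a.x = 1, a.y = 2), seed = 5)
  p1 <- simulate_population(sp)
  p2 <- simulate_population(sp)
  expect_identical(p1$concentration_mgml, p2$concentration_mgml)
  expect_equal(nrow(p1), 3L * 2L)
})

test_that("the lognormal population matches moments and stays positive", {
  sp <- population_spec(4000, "L", means = c(a.x = 20), sds = c(a.x = 8),
                        distribution = "lognormal", seed = 99)
  pop <- simulate_population(sp)
  expect_true(all(pop$concentration_mgml > 0))
  expect_equal(mean(pop$concentration_mgml), 20, tolerance = 0.05)
  expect_equal(sd(pop$concentration_mgml), 8, tolerance = 0.1)
})

test_that("time-series generator honours its spec", {
  # zero amplitude, zero noise: constant
  s0 <- simulate_timeseries(timeseries_spec(amplitude = 0, noise_sd = 0,
                                            baseline_level = 25, seed = 1))
  expect_true(all(s0$series$values == 25))
  # 2 cycles/h, noiseless, 10-min sampling: 4 sign changes of first diffs
  s2 <- simulate_timeseries(timeseries_spec(frequency = 2, amplitude = 5,
                                            noise_sd = 0, phase = 0))
  d <- diff(s2$series$values)
  expect_equal(sum(diff(sign(d)) != 0), 4L)
  # determinism under seed
  a <- simulate_timeseries(timeseries_spec(noise_sd = 2, seed = 7))
  b <- simulate_timeseries(timeseries_spec(noise_sd = 2, seed = 7))
  expect_identical(a$series$values, b$series$values)
  expect_equal(a$truth$phase, b$truth$phase)
  expect_error(timeseries_spec(interval_min = 120, duration_min = 60),
               "interval")
})
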