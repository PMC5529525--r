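test_that("fitting a pure component returns weight 1 for it, 0 elsewhere", {
  lib <- default_component_library()
  for (nm in component_names(lib)) {
    s <- raman_spectrum(lib$grid, lib$components[[nm]]$reference$intensities)
    f <- fit_lcm(s, lib)
    expect_equal(unname(f$weights[nm]), 1, tolerance = 1e-6)
    expect_lt(max(abs(f$weights[setdiff(names(f$weights), nm)])), 1e-6)
  }
})

test_that("a noiseless two-component mixture is recovered exactly", {
  lib <- default_component_library()
  sim <- simulate_spectrum(lib, c(protein = 0.8, RNA = 0.3))
  f <- fit_lcm(sim$spectrum, lib)
  expect_equal(unname(f$weights["protein"]), 0.8, tolerance = 1e-6)
  expect_equal(unname(f$weights["RNA"]), 0.3, tolerance = 1e-6)
  expect_lt(max(abs(f$weights[c("lipid", "DNA")])), 1e-6)
  expect_equal(unname(f$concentrations["protein"]), 80, tolerance = 1e-4)
  expect_equal(unname(f$concentrations["RNA"]), 6, tolerance = 1e-4)
})

test_that("an all-zero spectrum fits to all-zero weights with R^2 = 0", {
  lib <- default_component_library()
  f <- fit_lcm(raman_spectrum(lib$grid, rep(0, length(lib$grid))), lib)
  expect_true(all(f$weights == 0))
  expect_equal(f$r_squared, 0)
  expect_equal(max(abs(f$residual$intensities)), 0)
})

test_that("a true wavenumber shift of 1.5 cm^-1 is recovered", {
  lib <- default_component_library()
  sim <- simulate_spectrum(lib, c(protein = 0.8, RNA = 0.3), shift = 1.5)
  f <- fit_lcm(sim$spectrum, lib)
  expect_lt(abs(f$shift - 1.5), 0.1)
  expect_lt(abs(f$weights["protein"] - 0.8) / 0.8, 0.01)
  expect_lt(abs(f$weights["RNA"] - 0.3) / 0.3, 0.01)
})

test_that("the optimizer matches a brute-force grid search oracle", {
  lib <- small_library()
  opts <- fit_options(allow_shift = FALSE, residual_poly_degree = -1)
  # no shift: optimizer objective must not exceed the grid minimum
  sim <- simulate_spectrum(lib, c(alpha = 0.8, beta = 0.3))
  y <- sim$spectrum$intensities
  f <- fit_lcm(sim$spectrum, lib, opts)
  gs <- grid_search_lcm(y, lib, seq(0.7, 0.9, by = 0.001),
                        seq(0.2, 0.4, by = 0.001))
  obj_fit <- sum(f$residual$intensities^2)
  expect_lte(obj_fit, gs$obj + 1e-9)
  expect_lt(abs(f$weights["alpha"] - gs$c1), 0.001)
  expect_lt(abs(f$weights["beta"] - gs$c2), 0.001)

  # with a true shift of +1.5 cm^-1 the 3-parameter grid agrees too
  sims <- simulate_spectrum(lib, c(alpha = 0.8, beta = 0.3), shift = 1.5)
  fs <- fit_lcm(sims$spectrum, lib,
                fit_options(allow_shift = TRUE, residual_poly_degree = -1))
  gs3 <- grid_search_lcm(sims$spectrum$intensities, lib,
                         seq(0.7, 0.9, by = 0.001), seq(0.2, 0.4, by = 0.001),
                         delta_grid = seq(0.5, 2.5, by = 0.05))
  expect_lte(sum(fs$residual$intensities^2), gs3$obj + 1e-9)
  expect_lt(abs(fs$shift - gs3$delta), 0.05 + 1e-6)
  expect_lt(abs(fs$weights["alpha"] - gs3$c1), 0.002)
  expect_lt(abs(fs$weights["beta"] - gs3$c2), 0.002)
})

test_that("fitted plus residual reconstructs the input exactly", {
  lib <- default_component_library()
  for (seed in 1:5) {
    sim <- simulate_spectrum(lib, c(protein = 0.85, RNA = 1.3, lipid = 1.1),
                             baseline = list(amplitude = 0.5, center = 1200,
                                             width = 400),
                             noise_sd = 0.07, seed = seed)
    f <- fit_lcm(sim$spectrum, lib)
    expect_equal(f$fitted$intensities + f$residual$intensities,
                 sim$spectrum$intensities, tolerance = 1e-9)
    expect_true(all(f$weights >= 0))
  }
})

test_that("scaling the input scales weights, polynomial and residual", {
  lib <- default_component_library()
  sim <- simulate_spectrum(lib, c(protein = 0.7, RNA = 1.1, lipid = 0.8),
                           baseline = list(amplitude = 0.3, center = 1200,
                                           width = 400),
                           noise_sd = 0.05, seed = 17)
  f1 <- fit_lcm(sim$spectrum, lib)
  for (k in c(0.25, 7.3)) {
    f2 <- fit_lcm(raman_spectrum(sim$spectrum$wavenumbers,
                                 k * sim$spectrum$intensities), lib)
    expect_equal(f2$weights, k * f1$weights, tolerance = 1e-6)
    expect_equal(f2$residual$intensities, k * f1$residual$intensities,
                 tolerance = 1e-6)
    expect_equal(f2$residual_poly, k * f1$residual_poly, tolerance = 1e-6)
  }
})

test_that("component order in the library does not change the result", {
  lib <- default_component_library()
  perm <- component_library(unname(lib$components)[c(3, 1, 4, 2)])
  sim <- simulate_spectrum(lib, c(protein = 0.85, RNA = 1.3, lipid = 1.1),
                           baseline = list(amplitude = 0.4, center = 1150,
                                           width = 380),
                           noise_sd = 0.06, seed = 23)
  f1 <- fit_lcm(sim$spectrum, lib)
  f2 <- fit_lcm(sim$spectrum, perm)
  expect_equal(f2$weights[names(f1$weights)], f1$weights, tolerance = 1e-9)
})

test_that("detection threshold flags without altering weights", {
  lib <- default_component_library()
  sim <- simulate_spectrum(lib, c(protein = 0.9, DNA = 0.04))
  f <- fit_lcm(sim$spectrum, lib)
  expect_true(f$detected[["protein"]])
  expect_false(f$detected[["DNA"]])
  w_before <- f$weights
  f0 <- apply_detection_threshold(f, 0)
  expect_true(all(f0$detected[f0$weights > 0]))
  fbig <- apply_detection_threshold(f, 10)
  expect_false(any(fbig$detected))
  expect_identical(fbig$weights, w_before)
  expect_error(apply_detection_threshold(f, -0.1), "non-negative")
  expect_error(fit_options(detection_threshold = -1), ">= 0")
})

test_that("batch fitting assembles and orders the profiles table", {
  lib <- small_library()
  mk <- function(cell, org, wa, wb) {
    simulate_spectrum(lib, c(alpha = wa, beta = wb),
                      meta = list(cell_id = cell, cell_line = "L1",
                                  organelle = org))$spectrum
  }
  spectra <- list(mk("c2", "ER", 0.5, 0.2), mk("c1", "nucleolus", 0.8, 0.3),
                  mk("c1", "ER", 0.6, 0.1), mk("c2", "nucleolus", 0.7, 0.4),
                  mk("c3", "ER", 0.4, 0.2), mk("c3", "nucleolus", 0.9, 0.5))
  prof <- batch_fit(spectra, lib,
                    fit_options(allow_shift = FALSE,
                                residual_poly_degree = -1))
  expect_equal(nrow(prof), 6L * 2L)  # 6 spectra x 2 analytes
  expect_equal(attr(prof, "n_skipped"), 0L)
  expect_false(is.unsorted(prof$cell_id))
  got <- prof$weight[prof$cell_id == "c1" & prof$organelle == "nucleolus"]
  expect_equal(sort(got), c(0.3, 0.8), tolerance = 1e-6)

  incomplete <- c(spectra[1:5],
                  list(simulate_spectrum(lib, c(alpha = 1),
                                         meta = list(cell_line = "L1",
                                                     organelle = "ER")
                  )$spectrum))
  expect_warning(prof2 <- batch_fit(incomplete, lib,
                                    fit_options(allow_shift = FALSE,
                                                residual_poly_degree = -1)),
                 "cell_id")
  expect_equal(nrow(prof2), 5L * 2L)
  expect_equal(attr(prof2, "n_skipped"), 1L)
})
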