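test_that("truncated-normal targets respect bounds and degenerate cases", {
  x <- generate_targets(357, 6.90, 1.41, 4.20, 10.20, seed = 1)
  expect_length(x, 357)
  expect_true(all(x >= 4.20 & x <= 10.20))
  expect_identical(x, generate_targets(357, 6.90, 1.41, 4.20, 10.20,
                                       seed = 1))
  expect_false(identical(x, generate_targets(357, 6.90, 1.41, 4.20,
                                             10.20, seed = 2)))
  expect_equal(generate_targets(5, 4.20, 0, 3, 5), rep(4.20, 5))
  expect_error(generate_targets(5, 5, 1, lo = 2, hi = 2), "lo")
})

test_that("target sample moments match integrated truncated-normal moments", {
  mo <- truncnorm_moments(6.90, 1.41, 4.20, 10.20)
  x <- generate_targets(10000, 6.90, 1.41, 4.20, 10.20, seed = 99)
  se <- mo$sd / sqrt(10000)
  expect_lt(abs(mean(x) - mo$mean), 3 * se)
  # sd within 5% of the truncation-adjusted sd
  expect_lt(abs(sd(x) - mo$sd) / mo$sd, 0.05)
})

test_that("null forward model returns the baseline exactly", {
  cfg <- synthetic_config(n_samples = 4,
                          bands = list(component_band(1450, 40, 0, 0)),
                          scatter_slope_range = c(1, 1),
                          scatter_offset_range = c(0, 0), noise_sd = 0)
  gen <- generate_spectra(rep(6, 4), rep(4.2, 4), cfg)
  for (i in 1:4)
    expect_equal(unname(gen$spectra$values[i, ]), cfg$baseline)
})

test_that("scatter enters as an exact affine transform of the clean spectra", {
  cfg <- synthetic_config(n_samples = 6, noise_sd = 0,
                          scatter_slope_range = c(0.8, 0.8),
                          scatter_offset_range = c(0.03, 0.03), seed = 5)
  gen <- generate_spectra(generate_targets(6, seed = 1),
                          generate_targets(6, 4.2, 0.2, 3.77, 4.78,
                                           seed = 2), cfg)
  expect_equal(gen$spectra$values,
               0.03 + 0.8 * gen$truth$clean_spectra)
  expect_equal(gen$truth$slope, rep(0.8, 6))
  expect_equal(gen$truth$offset, rep(0.03, 6))
})

test_that("band coefficients are recoverable by regression at the centre", {
  wl <- seq(900, 1700, length.out = 224)
  cfg <- synthetic_config(n_samples = 50,
                          bands = list(component_band(1450, 40,
                                                      coeff_ssc = 0.02)),
                          scatter_slope_range = c(1, 1),
                          scatter_offset_range = c(0, 0), noise_sd = 0,
                          seed = 3)
  ssc <- generate_targets(50, seed = 4)
  gen <- generate_spectra(ssc, rep(4.2, 50), cfg)
  j <- which.min(abs(wl - 1450))
  absorb <- -log10(gen$spectra$values[, j] / cfg$baseline[j])
  fit <- lm(absorb ~ ssc)
  # the nearest grid point is a hair off 1450 nm; the recoverable slope
  # is the coefficient times the Gaussian profile at that grid point
  expected <- 0.02 * exp(-(wl[j] - 1450)^2 / (2 * 40^2))
  expect_equal(unname(coef(fit)[2]), expected, tolerance = 1e-6)
})

test_that("generation is bit-deterministic for a fixed config", {
  cfg <- synthetic_config(n_samples = 10, seed = 17)
  ssc <- generate_targets(10, seed = 18)
  ph <- generate_targets(10, 4.2, 0.2, 3.77, 4.78, seed = 19)
  g1 <- generate_spectra(ssc, ph, cfg)
  g2 <- generate_spectra(ssc, ph, cfg)
  expect_identical(g1$spectra$values, g2$spectra$values)
  expect_identical(g1$truth$clean_spectra, g2$truth$clean_spectra)
})

test_that("scene cubes paint disks exactly and keep the background flat", {
  d <- make_linear_dataset(n = 15, seed = 31)
  sp <- spectra_matrix(d$X, d$wavelengths)
  scene <- generate_scene_cube(sp, 3, 5, disk_radius = 8, seed = 44)
  expect_length(scene$masks, 15)
  # per-disk pixel mean equals the assigned spectrum exactly
  ms <- mean_spectra(scene$cube, scene$masks)
  expect_equal(ms$values, d$X, tolerance = 1e-12)
  # all non-disk pixels sit at the background level at every band
  bg <- !Reduce(`|`, scene$masks)
  flat <- matrix(scene$cube$data, ncol = dim(scene$cube$data)[3])
  expect_true(all(flat[which(bg), ] == 0.05))
  # connected components by construction: disks are disjoint
  expect_equal(sum(vapply(scene$masks, sum, 0L) > 0), 15L)
  expect_false(any(Reduce(`+`, lapply(scene$masks, `+`, 0)) > 1))
  expect_error(generate_scene_cube(sp, 2, 5, disk_radius = 8), "cells")
  expect_error(generate_scene_cube(sp, 3, 5, disk_radius = 8,
                                   cell_px = 10), "overlap")
})
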