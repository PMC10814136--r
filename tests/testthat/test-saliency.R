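zero_head_cnn <- function(seq_len = 64, const = 5) {
  m <- build_model(cnn_spec(), seq_len = seq_len, seed = 4)
  m$weights[["fc2.W"]][] <- 0
  m$weights[["fc2.b"]][] <- const
  m
}

test_that("a constant-output model yields an all-zero profile", {
  m <- zero_head_cnn()
  x <- rnorm(64)
  prof <- gradcam_profile(m, x)
  expect_equal(prof, rep(0, 64))
  # and prediction really is constant
  expect_equal(predict(m, rbind(x, rnorm(64))), rep(5, 2),
               tolerance = 1e-5)
})

test_that("profiles are rectified and max-normalised into [0, 1]", {
  set.seed(91)
  for (nm in c("cnn", "cnn_lstm", "cnn_transformer")) {
    spec <- switch(nm, cnn = cnn_spec(), cnn_lstm = cnn_lstm_spec(),
                   cnn_transformer = cnn_transformer_spec())
    m <- build_model(spec, seq_len = 64, seed = 7)
    prof <- gradcam_profile(m, rnorm(64))
    expect_true(all(prof >= 0 & prof <= 1))
    expect_equal(max(prof), 1)
  }
})

test_that("saliency is refused for models without a conv front end", {
  for (spec in list(lstm_spec(), transformer_spec())) {
    m <- build_model(spec, seq_len = 64)
    expect_error(gradcam_profile(m, rnorm(64)), "unsupported|conv")
    expect_error(aggregate_profiles(m, matrix(rnorm(64 * 3), 3), n = 3),
                 "unsupported|conv")
  }
})

test_that("aggregation bounds, variance and normalisation behave", {
  set.seed(92)
  m <- build_model(cnn_spec(), seq_len = 64, seed = 8)
  X <- matrix(rnorm(20 * 64), 20, 64)
  # n = 1: variance identically zero
  p1 <- aggregate_profiles(m, X, n = 1, seed = 3)
  expect_equal(p1$variance, rep(0, 64))
  # identical rows: variance identically zero
  Xid <- matrix(rep(X[1, ], 6), 6, byrow = TRUE)
  pid <- aggregate_profiles(m, Xid, n = 6, seed = 3)
  expect_equal(pid$variance, rep(0, 64), tolerance = 1e-12)
  # mean profile bounded by per-band min/max of individual profiles
  # (checked before the final re-normalisation, which divides by a
  # constant; recompute individual profiles as the oracle)
  pall <- aggregate_profiles(m, X, n = 20, seed = 5)
  indiv <- t(vapply(1:20, function(i) gradcam_profile(m, X[i, ]),
                    numeric(64)))
  mean_raw <- colMeans(indiv)
  expect_equal(pall$mean_weight, mean_raw / max(mean_raw),
               tolerance = 1e-6)
  expect_true(all(colMeans(indiv) <= apply(indiv, 2, max) + 1e-12))
  expect_true(all(colMeans(indiv) >= apply(indiv, 2, min) - 1e-12))
  expect_error(aggregate_profiles(m, X, n = 0), "positive")
  expect_error(aggregate_profiles(m, X, n = 21), "exceeds")
})

test_that("band mass fractions are additive window measures", {
  prof <- structure(list(wavelengths = seq(900, 1700, length.out = 64),
                         mean_weight = runif(64), variance = rep(0, 64),
                         n_samples = 1L), class = "saliency_profile")
  expect_equal(band_mass_fraction(prof, 900, 1700), 1)
  expect_equal(band_mass_fraction(prof, 100, 200), 0)
  lowhalf <- band_mass_fraction(prof, 900, 1299.9)
  highhalf <- band_mass_fraction(prof, 1299.91, 1700)
  expect_equal(lowhalf + highhalf, 1, tolerance = 1e-12)
  expect_error(band_mass_fraction(prof, 1400, 1300), "lo_nm")
  zero <- prof; zero$mean_weight <- rep(0, 64)
  expect_equal(band_mass_fraction(zero, 900, 1700), 0)
})
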