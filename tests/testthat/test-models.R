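# Deep-model unit tests use small sample counts and epoch budgets: they
# check contracts (shapes, determinism, gradient correctness, learning on
# easy targets), not predictive performance, which the acceptance suite
# measures at full study size.

all_specs <- function() list(cnn = cnn_spec(), lstm = lstm_spec(),
                             cnn_lstm = cnn_lstm_spec(),
                             transformer = transformer_spec(),
                             cnn_transformer = cnn_transformer_spec())

test_that("every architecture maps a batch of spectra to one value per row", {
  set.seed(81)
  X <- matrix(rnorm(10 * 209), 10, 209)
  for (nm in names(all_specs())) {
    m <- build_model(all_specs()[[nm]], seq_len = 209, seed = 3)
    p1 <- predict(m, X)
    expect_length(p1, 10)
    expect_true(all(is.finite(p1)), info = nm)
    # evaluation mode is deterministic (dropout inert)
    expect_identical(p1, predict(m, X), info = nm)
  }
  m <- build_model(cnn_spec(), seq_len = 209)
  expect_error(predict(m, X[, 1:100]), "width")
})

test_that("CNN-Transformer parameter count matches the closed-form sum", {
  m <- build_model(cnn_transformer_spec(), seq_len = 209)
  # conv1 (3*1*128 + 128) + conv2 (3*128*256 + 256)
  # + 6 encoder layers [4 * (256*256 + 256) attention projections
  #   + 2 LayerNorms (2 * 256) + feed-forward (256*1024 + 1024
  #   + 1024*256 + 256)] + flattened FC head (209*256 + 1)
  expect_identical(n_parameters(m), 4891137L)
  expect_identical(n_parameters(build_model(cnn_transformer_spec(),
                                            seq_len = 209, seed = 9)),
                   4891137L)
})

test_that("spec invariants are enforced", {
  expect_error(transformer_spec(n_heads = 3L), "must equal")
  expect_error(cnn_spec(dropout_p = 1.2), "dropout_p")
  expect_error(train_config(lr = -1), "positive")
  expect_error(train_config(batch_size = 0), "batch_size")
})

test_that("seeded training is reproducible and seed-sensitive", {
  d <- make_linear_dataset(n = 30, seed = 82, noise_sd = 0.005)
  m <- build_model(lstm_spec(), seq_len = 209, seed = 1)
  cfg <- train_config(max_epochs = 3, patience = 10, seed = 4)
  t1 <- train_model(m, d$X[1:20, ], d$ssc[1:20], d$X[21:30, ],
                    d$ssc[21:30], cfg)
  t2 <- train_model(m, d$X[1:20, ], d$ssc[1:20], d$X[21:30, ],
                    d$ssc[21:30], cfg)
  expect_identical(predict(t1, d$X), predict(t2, d$X))
  cfg2 <- train_config(max_epochs = 3, patience = 10, seed = 5)
  t3 <- train_model(m, d$X[1:20, ], d$ssc[1:20], d$X[21:30, ],
                    d$ssc[21:30], cfg2)
  expect_false(identical(predict(t1, d$X), predict(t3, d$X)))
})

test_that("a constant target is learned to high precision", {
  d <- make_linear_dataset(n = 30, seed = 83, noise_sd = 0.005)
  y <- rep(7.5, 30)
  m <- build_model(lstm_spec(), seq_len = 209, seed = 2)
  tm <- train_model(m, d$X[1:20, ], y[1:20], d$X[21:30, ], y[21:30],
                    train_config(max_epochs = 60, patience = 60,
                                 seed = 1))
  expect_lt(rmse(y[1:20], predict(tm, d$X[1:20, ])),
            0.01 * (1 + 7.5))
  # monotone selection: training loss at the best epoch is no worse
  # than at the first
  expect_lte(tm$history$train_mse[tm$best_epoch],
             tm$history$train_mse[1])
})

test_that("the CNN learns a single-absorption-band linear target", {
  # one informative Gaussian band; the target is the analyte itself,
  # linear in the band depth to first order
  cfg <- synthetic_config(n_samples = 120,
                          bands = list(component_band(1300, 40,
                                                      coeff_ssc = 0.02)),
                          noise_sd = 0.002, seed = 84)
  y <- generate_targets(120, seed = 85)
  gen <- generate_spectra(y, rep(4.2, 120), cfg)
  X <- crop_bands(msc_fit_apply(gen$spectra)$corrected)$values
  cal <- 1:80; val <- 81:100
  m <- build_model(cnn_spec(), seq_len = 209, seed = 1)
  tm <- train_model(m, X[cal, ], y[cal], X[val, ], y[val],
                    train_config(max_epochs = 150, patience = 40,
                                 seed = 1))
  expect_gte(r_squared(y[val], predict(tm, X[val, ])), 0.9)
})

test_that("backpropagated input gradients match central differences", {
  # directional derivative check; the networks run in single precision,
  # so agreement is bounded by the float32 noise floor when the
  # derivative itself is tiny (hence the absolute floor in the
  # tolerance)
  set.seed(85)
  x <- rnorm(64)
  h <- 3e-3
  for (nm in c("cnn", "cnn_transformer", "cnn_lstm", "lstm",
               "transformer")) {
    m <- build_model(all_specs()[[nm]], seq_len = 64, seed = 6)
    ana <- spectrareg:::cpp_nn_inputgrad(m$arch, m$weights, x)
    expect_length(ana, 64)
    expect_true(all(is.finite(ana)))
    d <- rnorm(64); d <- d / sqrt(sum(d^2))
    fd <- (spectrareg:::cpp_nn_predict(m$arch, m$weights,
                                       matrix(x + h * d, 1)) -
             spectrareg:::cpp_nn_predict(m$arch, m$weights,
                                         matrix(x - h * d, 1))) / (2 * h)
    want <- sum(ana * d)
    expect_lt(abs(fd - want), 0.05 * max(abs(want), 2e-4),
              label = paste("directional-derivative gap for", nm))
  }
})
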