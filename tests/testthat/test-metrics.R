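test_that("rmse matches direct arithmetic and the loop oracle", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 4)), sqrt(1 / 3))
  set.seed(7)
  for (rep in 1:5) {
    y <- rnorm(23); yh <- rnorm(23)
    expect_equal(rmse(y, yh), rmse_loop(y, yh), tolerance = 1e-12)
  }
  expect_error(rmse(1:3, 1:4), "equal")
  expect_error(rmse(numeric(0), numeric(0)), "nonzero")
})

test_that("r_squared follows the explained-variance definition", {
  y <- c(1, 2, 3)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, c(1, 2, 4)), 0.5)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_error(r_squared(rep(2, 5), rnorm(5)), "constant")
  # can be negative for predictions worse than the mean
  expect_lt(r_squared(y, c(3, 1, 2)), 0)
})

test_that("r_squared is invariant under a common affine transform", {
  set.seed(11)
  y <- rnorm(40); yh <- y + rnorm(40, 0, 0.3)
  base <- r_squared(y, yh)
  for (a in c(-2, 0.5, 10)) for (b in c(-1, 0, 3))
    expect_equal(r_squared(a * y + b, a * yh + b), base,
                 tolerance = 1e-12)
})

test_that("rpd is the SD-to-RMSE ratio with its boundary behaviours", {
  # constructed SD = 2, RMSE = 1
  y <- c(-2, 0, 2) / sd(c(-2, 0, 2)) * 2
  yh <- y + c(1, -1, 1)
  expect_equal(rpd(y, yh), 2)
  # null model: sample SD over population RMSE
  set.seed(3)
  y <- rnorm(31)
  expect_equal(rpd(y, rep(mean(y), 31)), sqrt(31 / 30), tolerance = 1e-12)
  # doubling all residuals halves the RPD
  yh <- y + rnorm(31, 0, 0.5)
  expect_equal(rpd(y, y + 2 * (yh - y)), rpd(y, yh) / 2,
               tolerance = 1e-12)
  expect_warning(out <- rpd(y, y), "zero RMSE")
  expect_identical(out, Inf)
})

test_that("rpd times rmse recovers the sample SD identically", {
  set.seed(5)
  for (rep in 1:5) {
    y <- rnorm(17); yh <- y + rnorm(17, 0, 0.2)
    expect_equal(rpd(y, yh) * rmse(y, yh), sd(y), tolerance = 1e-12)
  }
})

test_that("reliability classes split at 1.4 and 2.0 (boundaries inclusive)", {
  expect_equal(as.character(reliability_class(c(1.39, 1.4, 2.0, 2.45))),
               c("unreliable", "reliable", "reliable", "high"))
  expect_error(reliability_class(-1), "positive")
})

test_that("evaluate_all assembles the comparison table from the split", {
  d <- make_linear_dataset(n = 60, seed = 9)
  w <- rep(0, ncol(d$X)); w[c(10, 100)] <- c(3, -2)
  y <- drop(d$X %*% w)
  targets <- data.frame(lin = y, ssc = d$ssc)
  split <- list(cal_idx = 1:36, val_idx = 37:48, pred_idx = 49:60)
  fit <- fit_plsr(d$X[split$cal_idx, ], y[split$cal_idx],
                  plsr_spec(component_grid = 1:5))
  rep_tab <- evaluate_all(list(lin = list(plsr = fit)), d$X, targets,
                          split)
  expect_s3_class(rep_tab, "metrics_report")
  expect_equal(nrow(rep_tab), 1L)
  # noiseless linear target: essentially perfect linear recovery
  expect_gt(rep_tab$R2_P, 0.999)
  expect_lt(rep_tab$RMSEP, 1e-3 * sd(y))
  # cells agree with metrics recomputed from the serialized predictions
  scat <- attr(rep_tab, "scatter")
  pp <- scat[scat$part == "P", ]
  expect_equal(rep_tab$R2_P, r_squared(pp$measured, pp$predicted))
  expect_equal(rep_tab$RMSEP, rmse(pp$measured, pp$predicted))
  expect_equal(rep_tab$RPDP, rpd(pp$measured, pp$predicted))
  # two models x two targets -> four rows
  rep2 <- evaluate_all(list(lin = list(plsr = fit, plsr2 = fit),
                            ssc = list(plsr = fit, plsr2 = fit)),
                       d$X, targets, split)
  expect_equal(nrow(rep2), 4L)
  expect_error(evaluate_all(list(lin = list(plsr = fit)), d$X, targets,
                            list(cal_idx = 1:3)), "missing part")
})
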