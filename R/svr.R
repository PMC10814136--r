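#' SVR hyperparameter specification
#'
#' Kernel set and grids for support vector regression: gamma log-spaced
#' over `[1e-4, 1e5]`, cost grid `{0.1, 1, 10, 100}`, polynomial degree 3.
#' The gamma grid applies to the polynomial and Gaussian (radial) kernels;
#' the linear kernel is searched over cost only.
#'
#' @param kernel_set subset of `c("linear", "polynomial", "gaussian")`.
#' @param gamma_grid positive values, default `10^(-4:5)`.
#' @param cost_grid positive values, default `c(0.1, 1, 10, 100)`.
#' @param degree polynomial degree (default 3).
#' @param cv_folds folds for the grid search (default 5).
#' @return Object of class `svr_spec`.
#' @export
svr_spec <- function(kernel_set = c("linear", "polynomial", "gaussian"),
                     gamma_grid = 10^(-4:5),
                     cost_grid = c(0.1, 1, 10, 100),
                     degree = 3L, cv_folds = 5L) {
  kernel_set <- match.arg(kernel_set, several.ok = TRUE)
  if (length(gamma_grid) == 0 || length(cost_grid) == 0)
    stop("svr_spec: grids must be non-empty")
  structure(list(kernel_set = kernel_set, gamma_grid = gamma_grid,
                 cost_grid = cost_grid, degree = as.integer(degree),
                 cv_folds = as.integer(cv_folds)),
            class = "svr_spec")
}

#' Fit a support vector regression
#'
#' Epsilon-SVR with kernel, gamma and cost chosen by k-fold cross-validated
#' grid search on the calibration data only, refit on all calibration rows.
#' Kernel machinery is delegated to [e1071::svm()].
#'
#' @param X predictor matrix or [spectra_matrix].
#' @param y numeric response vector.
#' @param spec an [svr_spec].
#' @param seed seed for the fold assignment.
#' @return Object of class `svr_model`.
#' @export
fit_svr <- function(X, y, spec = svr_spec(), seed = 1L) {
  Xv <- spectra_values(X)
  N <- nrow(Xv)
  if (length(y) != N) stop("fit_svr: `y` length does not match rows of X")
  folds <- min(spec$cv_folds, N - 1L)
  fold_id <- with_seed(seed, sample(rep(seq_len(folds), length.out = N)))
  kern_map <- c(linear = "linear", polynomial = "polynomial",
                gaussian = "radial")
  configs <- list()
  for (kn in spec$kernel_set) {
    gammas <- if (kn == "linear") NA_real_ else spec$gamma_grid
    for (g in gammas) for (co in spec$cost_grid)
      configs[[length(configs) + 1L]] <- list(kernel = kn, gamma = g,
                                              cost = co)
  }
  cv_rmse <- vapply(configs, function(cf) {
    se <- 0
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- svm_call(Xv[tr, , drop = FALSE], y[tr], cf, spec)
      pred <- predict(fit, Xv[!tr, , drop = FALSE])
      se <- se + sum((y[!tr] - pred)^2)
    }
    sqrt(se / N)
  }, 0)
  best <- configs[[which.min(cv_rmse)]]
  fit <- svm_call(Xv, y, best, spec)
  structure(list(fit = fit, kernel = best$kernel, gamma = best$gamma,
                 cost = best$cost, cv_rmse = min(cv_rmse), spec = spec),
            class = "svr_model")
}

svm_call <- function(X, y, cf, spec) {
  args <- list(x = X, y = y, type = "eps-regression",
               kernel = c(linear = "linear", polynomial = "polynomial",
                          gaussian = "radial")[[cf$kernel]],
               cost = cf$cost, scale = FALSE)
  if (cf$kernel != "linear") args$gamma <- cf$gamma
  if (cf$kernel == "polynomial") args$degree <- spec$degree
  do.call(e1071::svm, args)
}

#' Predict from a fitted SVR model
#'
#' @param object an `svr_model`.
#' @param newdata matrix or [spectra_matrix].
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.svr_model <- function(object, newdata, ...) {
  as.numeric(predict(object$fit, spectra_values(newdata)))
}

#' @export
print.svr_model <- function(x, ...) {
  cat(sprintf("<svr_model> kernel %s, cost %g%s (CV RMSE %.4f)\n",
              x$kernel, x$cost,
              if (is.na(x$gamma)) "" else sprintf(", gamma %g", x$gamma),
              x$cv_rmse))
  invisible(x)
}
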