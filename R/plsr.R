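#' PLSR hyperparameter specification
#'
#' @param component_grid candidate numbers of latent variables (default
#'   1-21), each `>= 1`.
#' @param cv_folds folds for the cross-validated grid search (default 5).
#' @return Object of class `plsr_spec`.
#' @export
plsr_spec <- function(component_grid = 1:21, cv_folds = 5L) {
  if (length(component_grid) == 0 || any(component_grid < 1))
    stop("plsr_spec: `component_grid` must be non-empty, all >= 1")
  structure(list(component_grid = as.integer(sort(unique(component_grid))),
                 cv_folds = as.integer(cv_folds)),
            class = "plsr_spec")
}

# Orthogonal-scores PLS1 decomposition on centred data. Returns loading
# and weight matrices for up to `ncomp` latent variables; models for
# k < ncomp components are nested, so one decomposition serves the whole
# component grid.
pls1_decompose <- function(X0, y0, ncomp) {
  B <- ncol(X0)
  Wm <- matrix(0, B, ncomp); Pm <- matrix(0, B, ncomp)
  qv <- numeric(ncomp)
  Xd <- X0; yd <- y0
  for (k in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- k - 1L; break }
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) { ncomp <- k - 1L; break }
    p <- crossprod(Xd, t) / tt
    q <- sum(yd * t) / tt
    Xd <- Xd - t %*% t(p)
    yd <- yd - q * t
    Wm[, k] <- w; Pm[, k] <- p; qv[k] <- q
  }
  if (ncomp == 0) stop("fit_plsr: singular fit (y orthogonal to X)")
  list(W = Wm[, seq_len(ncomp), drop = FALSE],
       P = Pm[, seq_len(ncomp), drop = FALSE],
       q = qv[seq_len(ncomp)], ncomp = ncomp)
}

# Regression coefficients of the k-component nested model.
pls1_coef <- function(dec, k) {
  Wk <- dec$W[, seq_len(k), drop = FALSE]
  Pk <- dec$P[, seq_len(k), drop = FALSE]
  Wk %*% solve(crossprod(Pk, Wk), dec$q[seq_len(k)])
}

#' Fit a partial least squares regression
#'
#' PLS1 with mean centring, the latent-variable count chosen by k-fold
#' cross-validated grid search on the calibration data only, then refit on
#' all calibration rows.
#'
#' @param X predictor matrix or [spectra_matrix] (calibration rows).
#' @param y numeric response vector.
#' @param spec a [plsr_spec].
#' @param seed seed for the fold assignment (deterministic CV).
#' @return Object of class `plsr_model` with the chosen component count,
#'   coefficients and per-candidate CV RMSE.
#' @export
fit_plsr <- function(X, y, spec = plsr_spec(), seed = 1L) {
  Xv <- spectra_values(X)
  N <- nrow(Xv)
  if (length(y) != N) stop("fit_plsr: `y` length does not match rows of X")
  folds <- min(spec$cv_folds, N)
  if (N <= folds) stop("fit_plsr: need more samples than CV folds")
  grid <- spec$component_grid
  grid <- grid[grid < min(N - ceiling(N / folds), ncol(Xv))]
  if (length(grid) == 0) grid <- 1L
  fold_id <- with_seed(seed, sample(rep(seq_len(folds), length.out = N)))
  press <- matrix(0, folds, length(grid))
  counts <- integer(folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f; te <- !tr
    xm <- colMeans(Xv[tr, , drop = FALSE]); ym <- mean(y[tr])
    dec <- pls1_decompose(sweep(Xv[tr, , drop = FALSE], 2, xm), y[tr] - ym,
                          max(grid))
    Xc <- sweep(Xv[te, , drop = FALSE], 2, xm)
    for (j in seq_along(grid)) {
      k <- min(grid[j], dec$ncomp)
      pred <- ym + Xc %*% pls1_coef(dec, k)
      press[f, j] <- sum((y[te] - pred)^2)
    }
    counts[f] <- sum(te)
  }
  cv_rmse <- sqrt(colSums(press) / N)
  best <- grid[which.min(cv_rmse)]
  xm <- colMeans(Xv); ym <- mean(y)
  dec <- pls1_decompose(sweep(Xv, 2, xm), y - ym, best)
  structure(list(ncomp = dec$ncomp, coef = pls1_coef(dec, dec$ncomp),
                 x_center = xm, y_center = ym, spec = spec,
                 component_grid = grid, cv_rmse = cv_rmse),
            class = "plsr_model")
}

#' Predict from a fitted PLSR model
#'
#' @param object a `plsr_model`.
#' @param newdata matrix or [spectra_matrix] with the training band count.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  Xv <- spectra_values(newdata)
  if (ncol(Xv) != length(object$x_center))
    stop("predict.plsr_model: band count mismatch")
  as.numeric(object$y_center +
               sweep(Xv, 2, object$x_center) %*% object$coef)
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d latent variables (CV over %d candidates)\n",
              x$ncomp, length(x$component_grid)))
  invisible(x)
}
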