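# Independent oracles used across the suite. These deliberately take the
# slow, literal route (explicit loops, textbook algorithm statements) and
# share no code with the package implementation.

# two-loop positional encoding
pe_loops <- function(seq_len, d_model) {
  pe <- matrix(0, seq_len, d_model)
  for (pos in 0:(seq_len - 1))
    for (i in 0:(d_model / 2 - 1)) {
      ang <- pos / 10000^(2 * i / d_model)
      pe[pos + 1, 2 * i + 1] <- sin(ang)
      pe[pos + 1, 2 * i + 2] <- cos(ang)
    }
  pe
}

# exp/normalise/weighted-sum attention, one query row at a time
attention_loops <- function(Q, K, V) {
  n <- nrow(Q); m <- nrow(K)
  out <- matrix(0, n, ncol(V))
  for (i in seq_len(n)) {
    s <- numeric(m)
    for (j in seq_len(m)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(ncol(K))
    e <- exp(s - max(s))
    w <- e / sum(e)
    for (j in seq_len(m)) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

# loop-accumulated error metrics
rmse_loop <- function(y, y_hat) {
  acc <- 0
  for (i in seq_along(y)) acc <- acc + (y[i] - y_hat[i])^2
  sqrt(acc / length(y))
}

# textbook NIPALS PLS1: score/loading extraction with explicit deflation,
# prediction by sequential score computation on new data (no coefficient
# vector is ever formed)
nipals_pls1 <- function(X, y, ncomp) {
  xm <- colMeans(X); ym <- mean(y)
  Xd <- sweep(X, 2, xm); yd <- y - ym
  Ws <- list(); Ps <- list(); qs <- numeric(ncomp)
  for (k in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd))
    w <- w / sqrt(sum(w^2))
    t <- drop(Xd %*% w)
    p <- drop(crossprod(Xd, t)) / sum(t^2)
    q <- sum(yd * t) / sum(t^2)
    Xd <- Xd - outer(t, p)
    yd <- yd - q * t
    Ws[[k]] <- w; Ps[[k]] <- p; qs[k] <- q
  }
  list(predict = function(Xnew) {
    out <- numeric(nrow(Xnew))
    for (i in seq_len(nrow(Xnew))) {
      xd <- Xnew[i, ] - xm
      yhat <- ym
      for (k in seq_len(ncomp)) {
        t <- sum(xd * Ws[[k]])
        yhat <- yhat + t * qs[k]
        xd <- xd - t * Ps[[k]]
      }
      out[i] <- yhat
    }
    out
  })
}

# numerically integrated moments of a truncated normal
truncnorm_moments <- function(mean, sd, lo, hi) {
  z <- integrate(function(x) dnorm(x, mean, sd), lo, hi)$value
  m1 <- integrate(function(x) x * dnorm(x, mean, sd), lo, hi)$value / z
  m2 <- integrate(function(x) x^2 * dnorm(x, mean, sd), lo, hi)$value / z
  list(mean = m1, sd = sqrt(m2 - m1^2))
}

# small MSC-corrected synthetic dataset shared by several model tests
make_linear_dataset <- function(n = 150, seed = 42, noise_sd = 0,
                                bands = 209) {
  ssc <- generate_targets(n, seed = seed)
  ph <- generate_targets(n, 4.20, 0.20, 3.77, 4.78, seed = seed + 1)
  cfg <- synthetic_config(n_samples = n, noise_sd = noise_sd,
                          scatter_slope_range = c(1, 1),
                          scatter_offset_range = c(0, 0), seed = seed + 2)
  gen <- generate_spectra(ssc, ph, cfg)
  sp <- crop_bands(gen$spectra)
  stopifnot(ncol(sp$values) == bands)
  list(X = sp$values, wavelengths = sp$wavelengths, ssc = ssc, ph = ph,
       truth = gen$truth)
}
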