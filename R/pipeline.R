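#' Segment fruit regions in a reflectance cube
#'
#' Thresholds a single high-contrast band (matte fruit is bright against
#' the dark platform in the NIR), labels connected components, discards
#' components below `min_area` pixels, and orders the surviving regions
#' row-major (top-to-bottom, then left-to-right by centroid) to match the
#' platform layout of the acquisition.
#'
#' @param cube a [reflectance_cube].
#' @param band_nm wavelength (nm) of the thresholding band; must lie
#'   within the cube's wavelength span. Default 1100 nm.
#' @param threshold reflectance threshold (default 0.25): pixels above it
#'   are foreground.
#' @param min_area minimum component size in pixels.
#' @return List of logical `H x W` masks in row-major order; empty (with a
#'   warning) when no component reaches `min_area`.
#' @export
segment_samples <- function(cube, band_nm = 1100, threshold = 0.25,
                            min_area = 20L) {
  if (!inherits(cube, "reflectance_cube"))
    stop("segment_samples: `cube` must be a reflectance_cube")
  wl <- cube$wavelengths
  if (band_nm < min(wl) || band_nm > max(wl))
    stop("segment_samples: `band_nm` outside the wavelength axis")
  bi <- which.min(abs(wl - band_nm))
  slice <- cube$data[, , bi]
  fg <- slice > threshold
  lab <- EBImage::bwlabel(fg)
  n_lab <- max(lab)
  if (n_lab == 0) {
    warning("segment_samples: no foreground component found")
    return(list())
  }
  areas <- tabulate(lab[lab > 0], nbins = n_lab)
  keep <- which(areas >= min_area)
  if (length(keep) == 0) {
    warning("segment_samples: no component reaches min_area = ", min_area)
    return(list())
  }
  cy <- vapply(keep, function(l) mean(row(lab)[lab == l]), 0)
  cx <- vapply(keep, function(l) mean(col(lab)[lab == l]), 0)
  # group into platform rows: a new row starts when the centroid drops
  # more than ~1.5 disk radii below the running row mean
  ord <- order(cy)
  tol <- 1.5 * sqrt(mean(areas[keep]) / pi)
  row_id <- integer(length(keep))
  current <- 1L; row_mean <- cy[ord[1]]; row_n <- 1L
  row_id[ord[1]] <- 1L
  for (j in seq_along(ord)[-1]) {
    i <- ord[j]
    if (cy[i] > row_mean + tol) {
      current <- current + 1L; row_mean <- cy[i]; row_n <- 1L
    } else {
      row_mean <- (row_mean * row_n + cy[i]) / (row_n + 1L)
      row_n <- row_n + 1L
    }
    row_id[i] <- current
  }
  final <- keep[order(row_id, cx)]
  lapply(final, function(l) lab == l)
}

#' Mean spectrum of each region of interest
#'
#' Averages all pixel spectra within each mask (the whole fruit region is
#' the ROI), producing one representative spectrum per sample.
#'
#' @param cube a [reflectance_cube].
#' @param masks list of logical `H x W` masks, e.g. from
#'   [segment_samples()] or [generate_scene_cube()].
#' @return A [spectra_matrix] with one row per mask.
#' @export
mean_spectra <- function(cube, masks) {
  if (!inherits(cube, "reflectance_cube"))
    stop("mean_spectra: `cube` must be a reflectance_cube")
  if (length(masks) == 0) stop("mean_spectra: `masks` is empty")
  d <- dim(cube$data)
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  out <- matrix(0, length(masks), d[3])
  for (k in seq_along(masks)) {
    m <- masks[[k]]
    if (!identical(dim(m), d[1:2]))
      stop("mean_spectra: mask ", k, " does not match the cube extent")
    idx <- which(m)
    if (length(idx) == 0)
      stop("mean_spectra: mask ", k, " is empty")
    out[k, ] <- colMeans(flat[idx, , drop = FALSE])
  }
  spectra_matrix(out, cube$wavelengths)
}

#' Multiplicative scatter correction
#'
#' Fits each spectrum to a reference spectrum by simple linear regression
#' (`x ~ a + b * reference`) and inverts the fit
#' (`corrected = (x - a) / b`), removing per-sample baseline offset and
#' multiplicative scatter. The reference defaults to the column mean of
#' the input set.
#'
#' @param X [spectra_matrix] (or bare matrix) of spectra.
#' @param reference optional numeric reference spectrum of length `B`;
#'   when omitted, `X` must have at least two rows.
#' @return List with `corrected` (same class as the input spectra) and
#'   `model` (class `msc_model`: fields `reference`, `intercept`, `slope`).
#' @export
msc_fit_apply <- function(X, reference = NULL) {
  vals <- spectra_values(X)
  n <- nrow(vals)
  if (is.null(reference)) {
    if (n < 2)
      stop("msc_fit_apply: need >= 2 spectra to default the reference")
    reference <- colMeans(vals)
  }
  if (length(reference) != ncol(vals))
    stop("msc_fit_apply: reference length does not match band count")
  rc <- reference - mean(reference)
  vr <- sum(rc^2)
  if (vr == 0) stop("msc_fit_apply: constant reference spectrum")
  slope <- as.numeric(vals %*% rc) / vr   # cov(x, ref)/var(ref) per sample
  intercept <- rowMeans(vals) - slope * mean(reference)
  bad <- abs(slope) < 1e-10
  if (any(bad)) {
    ids <- if (inherits(X, "spectra_matrix")) X$sample_ids[bad] else
      which(bad)
    stop("msc_fit_apply: degenerate (flat) samples: ",
         paste(ids, collapse = ", "))
  }
  corrected <- (vals - intercept) / slope
  model <- structure(list(reference = as.numeric(reference),
                          intercept = intercept, slope = slope),
                     class = "msc_model")
  if (inherits(X, "spectra_matrix"))
    corrected <- spectra_matrix(corrected, X$wavelengths, X$sample_ids)
  list(corrected = corrected, model = model)
}

#' Box-plot outlier screening of reference values
#'
#' Applies Tukey fences (`[Q1 - k*IQR, Q3 + k*IQR]`, quartiles by linear
#' interpolation) independently to each target variable; a sample is
#' removed when either its soluble-solids or its pH value falls outside
#' its fences.
#'
#' @param targets a [target_table] (or data.frame with numeric target
#'   columns `ssc` and `ph`), at least 4 rows.
#' @param k fence multiplier (default 1.5).
#' @param on which variables to screen; `c("ssc", "ph")` by default.
#' @return Integer vector of retained row indices.
#' @export
boxplot_outlier_filter <- function(targets, k = 1.5,
                                   on = c("ssc", "ph")) {
  n <- nrow(targets)
  if (is.null(n) || n < 4)
    stop("boxplot_outlier_filter: need at least 4 samples")
  keep <- rep(TRUE, n)
  for (v in on) {
    x <- targets[[v]]
    if (is.null(x)) stop("boxplot_outlier_filter: no column `", v, "`")
    q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    keep <- keep & x >= q[1] - k * iqr & x <= q[2] + k * iqr
  }
  which(keep)
}

#' PLSR-screened 3:1:1 dataset partition
#'
#' Draws `n_trials` seeded random calibration/validation/prediction splits
#' (sizes `floor(N/5)` for validation and prediction, remainder to
#' calibration), fits a cross-validated PLSR on each candidate calibration
#' set, and scores each split by its worst calibration-to-holdout R2 gap,
#' `max(R2_C - R2_V, R2_C - R2_P, 0)`, over the screened targets. The
#' minimum-score split is returned (ties to the lowest trial index): a
#' split on which a linear baseline generalizes is unlikely to provoke
#' overfitting in the heavier models.
#'
#' @param X [spectra_matrix] (or matrix) of predictor spectra.
#' @param targets [target_table] aligned with the rows of `X`.
#' @param ratio split ratio, default `c(3, 1, 1)`.
#' @param n_trials number of candidate splits, `>= 1`.
#' @param seed integer; trial `t` uses seed `seed + t`, so any candidate
#'   can be reproduced independently.
#' @param screen_on target columns entering the screening score.
#' @param spec [plsr_spec] for the screening fits.
#' @return Object of class `dataset_split` with fields `cal_idx`,
#'   `val_idx`, `pred_idx`, `seed`, `n_trials`, `trial` (selected),
#'   `screening_score` and `scores` (all trials).
#' @export
partition_screened <- function(X, targets, ratio = c(3, 1, 1),
                               n_trials = 20L, seed = 1L,
                               screen_on = c("ssc", "ph"),
                               spec = plsr_spec()) {
  vals <- spectra_values(X)
  N <- nrow(vals)
  if (N < 10) stop("partition_screened: need at least 10 samples")
  if (n_trials < 1) stop("partition_screened: `n_trials` must be >= 1")
  units <- sum(ratio)
  n_val <- floor(N * ratio[2] / units)
  n_pred <- floor(N * ratio[3] / units)
  n_cal <- N - n_val - n_pred
  if (min(n_cal, n_val, n_pred) < 1)
    stop("partition_screened: a split part would be empty")
  scores <- numeric(n_trials)
  parts <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    perm <- with_seed(seed + t, sample.int(N))
    val <- sort(perm[seq_len(n_val)])
    pred <- sort(perm[n_val + seq_len(n_pred)])
    cal <- sort(perm[n_val + n_pred + seq_len(n_cal)])
    parts[[t]] <- list(cal = cal, val = val, pred = pred)
    sc <- 0
    for (v in screen_on) {
      y <- targets[[v]]
      fit <- fit_plsr(vals[cal, , drop = FALSE], y[cal], spec,
                      seed = seed + t)
      gap <- function(idx) {
        r_squared(y[cal], predict(fit, vals[cal, , drop = FALSE])) -
          r_squared(y[idx], predict(fit, vals[idx, , drop = FALSE]))
      }
      sc <- max(sc, gap(val), gap(pred), 0)
    }
    scores[t] <- sc
  }
  best <- which.min(scores)
  structure(list(cal_idx = parts[[best]]$cal,
                 val_idx = parts[[best]]$val,
                 pred_idx = parts[[best]]$pred,
                 seed = seed, n_trials = as.integer(n_trials),
                 trial = as.integer(best),
                 screening_score = scores[best], scores = scores),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf(
    "<dataset_split> cal %d / val %d / pred %d (trial %d of %d, score %.4f)\n",
    length(x$cal_idx), length(x$val_idx), length(x$pred_idx),
    x$trial, x$n_trials, x$screening_score))
  invisible(x)
}
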