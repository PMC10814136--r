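#' Grad-CAM wavelength-importance profile of one spectrum
#'
#' Gradient-weighted class activation mapping adapted to 1-D regression:
#' with `A` the final convolutional feature map (`L` positions x `C`
#' channels; `L` equals the band count thanks to same-padding) and `g`
#' the gradient of the scalar output with respect to `A`, the channel
#' weights are `alpha_c = mean_l g[l, c]`, the raw map is
#' `M[l] = sum_c alpha_c * A[l, c]`, negative contributions are
#' rectified to zero, and the map is max-normalised to `[0, 1]` (an
#' all-zero map stays zero). Only models with a convolutional front end
#' (CNN, CNN-LSTM, CNN-Transformer) support this; for the others the
#' feature map does not exist and the call is an error.
#'
#' @param model a trained `nn_model` with a convolutional front end.
#' @param x a single spectrum (numeric vector of length `seq_len`).
#' @return Numeric vector of length `seq_len` with values in `[0, 1]`.
#' @export
gradcam_profile <- function(model, x, rectify = c("abs", "relu")) {
  rectify <- match.arg(rectify)
  if (!inherits(model, "nn_model"))
    stop("gradcam_profile: `model` must be an nn_model")
  if (!model$arch %in% c(1L, 3L, 5L))
    stop("gradcam_profile: unsupported model (no convolutional layer); ",
         "saliency is defined only for conv front-end architectures")
  x <- as.numeric(x)
  if (length(x) != model$seq_len)
    stop("gradcam_profile: spectrum length does not match model seq_len")
  res <- cpp_nn_gradcam(model$arch, model$weights,
                        nn_input_scale(model, matrix(x, nrow = 1)))
  gradcam_map(res$A[[1]], res$G[[1]], rectify)
}

gradcam_map <- function(A, G, rectify = "abs") {
  alpha <- colMeans(G)
  m <- as.numeric(A %*% alpha)
  m <- if (rectify == "relu") pmax(m, 0) else abs(m)
  mx <- max(m)
  if (mx > 0) m <- m / mx
  m
}

#' Aggregate Grad-CAM profiles over a sample set
#'
#' Draws a seeded random subset of spectra (50 by default), computes the
#' per-sample Grad-CAM profile of each, and summarises them as a
#' per-wavelength mean weight (re-normalised to maximum 1) with an
#' across-sample variance envelope.
#'
#' @param model a trained `nn_model` with a convolutional front end.
#' @param X [spectra_matrix] (or matrix) of spectra to draw from.
#' @param n number of samples to aggregate (default 50, at most the
#'   number of rows).
#' @param seed seed for the subset draw.
#' @param wavelengths optional wavelength axis; defaults to the axis of
#'   `X` when it is a [spectra_matrix].
#' @param rectify rectification mode passed to the per-sample maps; see
#'   [gradcam_profile()].
#' @return Object of class `saliency_profile` with fields `wavelengths`,
#'   `mean_weight`, `variance` and `n_samples`.
#' @export
aggregate_profiles <- function(model, X, n = 50L, seed = 1L,
                               wavelengths = NULL,
                               rectify = c("abs", "relu")) {
  rectify <- match.arg(rectify)
  if (!inherits(model, "nn_model") || !model$arch %in% c(1L, 3L, 5L))
    stop("aggregate_profiles: unsupported model (no convolutional ",
         "layer); saliency needs a conv front-end architecture")
  Xv <- spectra_values(X)
  if (n <= 0) stop("aggregate_profiles: `n` must be positive")
  if (n > nrow(Xv))
    stop("aggregate_profiles: `n` exceeds the number of spectra")
  if (is.null(wavelengths) && inherits(X, "spectra_matrix"))
    wavelengths <- X$wavelengths
  if (is.null(wavelengths)) wavelengths <- seq_len(ncol(Xv))
  pick <- with_seed(seed, sample.int(nrow(Xv), n))
  res <- cpp_nn_gradcam(model$arch, model$weights,
                        nn_input_scale(model, Xv[pick, , drop = FALSE]))
  prof <- t(vapply(seq_len(n),
                   function(i) gradcam_map(res$A[[i]], res$G[[i]],
                                           rectify),
                   numeric(model$seq_len)))
  mean_w <- colMeans(prof)
  v <- if (n > 1) apply(prof, 2, var) else rep(0, ncol(prof))
  mx <- max(mean_w)
  if (mx > 0) mean_w <- mean_w / mx
  structure(list(wavelengths = as.numeric(wavelengths),
                 mean_weight = mean_w, variance = v,
                 n_samples = as.integer(n)),
            class = "saliency_profile")
}

#' Fraction of saliency mass inside a wavelength window
#'
#' Quantifies how strongly a profile localises to a spectral window:
#' the sum of mean weights at bands inside `[lo_nm, hi_nm]` divided by
#' the sum over all bands (0 when the total is 0). Under a flat profile
#' this equals the window's share of bands, so a ratio well above that
#' share indicates localisation.
#'
#' @param profile a `saliency_profile`.
#' @param lo_nm,hi_nm window bounds in nm, `lo_nm < hi_nm`.
#' @return Fraction in `[0, 1]`.
#' @export
band_mass_fraction <- function(profile, lo_nm, hi_nm) {
  if (lo_nm >= hi_nm) stop("band_mass_fraction: `lo_nm` must be < `hi_nm`")
  tot <- sum(profile$mean_weight)
  if (tot == 0) return(0)
  inside <- profile$wavelengths >= lo_nm & profile$wavelengths <= hi_nm
  sum(profile$mean_weight[inside]) / tot
}

#' @export
print.saliency_profile <- function(x, ...) {
  cat(sprintf(
    "<saliency_profile> %d bands (%.0f-%.0f nm), aggregated over %d samples\n",
    length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
    x$n_samples))
  invisible(x)
}

#' Plot a saliency profile
#'
#' Mean Grad-CAM weight against wavelength with a +/- 1 sd envelope
#' shaded around the (pre-normalisation) mean.
#'
#' @param x a `saliency_profile`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.saliency_profile <- function(x, ...) {
  s <- sqrt(x$variance)
  graphics::plot(x$wavelengths, x$mean_weight, type = "n",
                 xlab = "wavelength (nm)", ylab = "mean Grad-CAM weight",
                 ylim = range(0, 1, x$mean_weight + s), ...)
  graphics::polygon(c(x$wavelengths, rev(x$wavelengths)),
                    c(pmax(x$mean_weight - s, 0),
                      rev(x$mean_weight + s)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(x$wavelengths, x$mean_weight, col = "steelblue4")
  invisible(x)
}
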