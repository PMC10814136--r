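#' Gaussian absorption band of one analyte
#'
#' Describes one informative spectral window of the synthetic forward
#' model: a Gaussian absorbance feature whose depth scales linearly with
#' the analyte concentration (Beer-Lambert behaviour).
#'
#' @param center_nm band centre (nm).
#' @param width_nm Gaussian sigma (nm), positive.
#' @param coeff_ssc absorbance depth per degree Brix of soluble solids.
#' @param coeff_ph absorbance depth per pH unit.
#' @return Object of class `component_band`.
#' @export
component_band <- function(center_nm, width_nm, coeff_ssc = 0,
                           coeff_ph = 0) {
  if (width_nm <= 0) stop("component_band: `width_nm` must be positive")
  structure(list(center_nm = center_nm, width_nm = width_nm,
                 coeff_ssc = coeff_ssc, coeff_ph = coeff_ph),
            class = "component_band")
}

default_bands <- function() {
  list(
    # sugar-related overtone bands in the 1380-1650 nm window
    component_band(1450, 40, coeff_ssc = 0.015),
    component_band(1550, 40, coeff_ssc = 0.015),
    # acidity-related O-H / N-H bands in the 945-1280 nm window
    component_band(1000, 35, coeff_ph = 0.12),
    component_band(1200, 35, coeff_ph = 0.12))
}

default_baseline <- function(wavelengths) {
  0.7 - 0.1 * ((wavelengths - 1300) / 400)^2
}

#' Configuration of the synthetic hyperspectral generator
#'
#' Defines the study conditions the generator emulates: a 224-band
#' 900-1700 nm reflectance axis, a smooth matte-fruit baseline, Gaussian
#' analyte absorption bands (soluble solids informative at 1450/1550 nm,
#' pH at 1000/1200 nm), per-sample multiplicative/additive scatter and
#' additive detector noise.
#'
#' @param n_samples number of fruit samples.
#' @param wavelengths strictly increasing wavelength grid (nm).
#' @param baseline per-band clean reflectance in (0, 1); default a gentle
#'   parabola between 0.6 and 0.7.
#' @param bands list of [component_band] objects; centres must lie within
#'   the wavelength span.
#' @param scatter_slope_range interval for the per-sample multiplicative
#'   scatter slope; must not contain 0.
#' @param scatter_offset_range interval for the additive scatter offset
#'   (reflectance units).
#' @param noise_sd standard deviation of additive detector noise
#'   (reflectance units), `>= 0`.
#' @param seed integer seed driving all of the generator's randomness.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 357L,
                             wavelengths = seq(900, 1700,
                                               length.out = 224),
                             baseline = NULL,
                             bands = default_bands(),
                             scatter_slope_range = c(0.7, 1.3),
                             scatter_offset_range = c(-0.05, 0.05),
                             noise_sd = 0.005,
                             seed = 1L) {
  if (n_samples < 1) stop("synthetic_config: `n_samples` must be >= 1")
  if (any(diff(wavelengths) <= 0))
    stop("synthetic_config: wavelengths must be strictly increasing")
  if (is.null(baseline)) baseline <- default_baseline(wavelengths)
  if (length(baseline) != length(wavelengths))
    stop("synthetic_config: baseline length must match wavelengths")
  if (any(baseline <= 0 | baseline >= 1))
    stop("synthetic_config: baseline must lie in (0, 1)")
  if (noise_sd < 0) stop("synthetic_config: `noise_sd` must be >= 0")
  if (scatter_slope_range[1] <= 0 && scatter_slope_range[2] >= 0)
    stop("synthetic_config: `scatter_slope_range` must exclude 0")
  for (b in bands) {
    if (!inherits(b, "component_band"))
      stop("synthetic_config: `bands` must be component_band objects")
    if (b$center_nm < min(wavelengths) || b$center_nm > max(wavelengths))
      stop("synthetic_config: band centre ", b$center_nm,
           " nm outside the wavelength span")
  }
  structure(list(n_samples = as.integer(n_samples),
                 wavelengths = as.numeric(wavelengths),
                 baseline = as.numeric(baseline), bands = bands,
                 scatter_slope_range = scatter_slope_range,
                 scatter_offset_range = scatter_offset_range,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Draw reference target values from a truncated normal
#'
#' Samples analyte reference values (e.g. soluble solids in degrees Brix,
#' or pH) from a normal distribution truncated to the observed range, by
#' rejection sampling. The defaults reproduce the soluble-solids summary
#' statistics of a 357-fruit cherry-tomato study (mean 6.90, sd 1.41,
#' range 4.20-10.20 degrees Brix).
#'
#' @param n number of samples, `>= 1`.
#' @param mean,sd parent normal parameters; `sd = 0` returns `rep(mean, n)`
#'   (the mean must then lie inside `[lo, hi]`).
#' @param lo,hi truncation bounds, `lo < hi`.
#' @param seed integer seed; the draw is deterministic for a fixed seed.
#' @return Numeric vector of length `n`, all values in `[lo, hi]`.
#' @export
generate_targets <- function(n, mean = 6.90, sd = 1.41, lo = 4.20,
                             hi = 10.20, seed = 1L) {
  if (n < 1) stop("generate_targets: `n` must be >= 1")
  if (lo >= hi) stop("generate_targets: `lo` must be < `hi`")
  if (sd < 0) stop("generate_targets: `sd` must be >= 0")
  if (sd == 0) {
    if (mean < lo || mean > hi)
      stop("generate_targets: `mean` outside [lo, hi] with sd = 0")
    return(rep(mean, n))
  }
  with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      draw <- rnorm(max(n, 100L), mean, sd)
      out <- c(out, draw[draw >= lo & draw <= hi])
    }
    out[seq_len(n)]
  })
}

#' Generate synthetic fruit spectra with known ground truth
#'
#' Forward model: the clean absorbance at wavelength `l` is the sum over
#' configured bands of `(coeff_ssc * ssc + coeff_ph * ph) *
#' exp(-(l - center)^2 / (2 * width^2))`; clean reflectance is
#' `baseline * 10^(-A)`; the observed spectrum is
#' `offset + slope * clean + noise` with per-sample scatter slope/offset
#' drawn uniformly from the configured intervals.
#'
#' @param ssc,ph numeric target vectors of equal length (one value per
#'   sample).
#' @param config a [synthetic_config]; its `seed` drives the scatter and
#'   noise draws.
#' @return List with `spectra` (observed [spectra_matrix]) and `truth`
#'   (class `ground_truth`: fields `ssc`, `ph`, `slope`, `offset`,
#'   `clean_spectra`).
#' @export
generate_spectra <- function(ssc, ph, config = synthetic_config()) {
  if (length(ssc) != length(ph))
    stop("generate_spectra: `ssc` and `ph` lengths differ")
  n <- length(ssc)
  wl <- config$wavelengths
  B <- length(wl)
  nb <- length(config$bands)
  depth <- matrix(0, n, max(nb, 1L))   # per-sample absorbance depth per band
  shape <- matrix(0, max(nb, 1L), B)   # Gaussian profile per band
  for (j in seq_len(nb)) {
    b <- config$bands[[j]]
    depth[, j] <- b$coeff_ssc * ssc + b$coeff_ph * ph
    shape[j, ] <- exp(-(wl - b$center_nm)^2 / (2 * b$width_nm^2))
  }
  A <- depth %*% shape
  clean <- sweep(10^(-A), 2, config$baseline, "*")
  if (any(clean <= 0 | clean >= 1.2))
    stop("generate_spectra: clean reflectance left (0, 1.2); check config")
  with_seed(config$seed, {
    slope <- runif(n, config$scatter_slope_range[1],
                   config$scatter_slope_range[2])
    offset <- runif(n, config$scatter_offset_range[1],
                    config$scatter_offset_range[2])
    noise <- matrix(rnorm(n * B, 0, config$noise_sd), n, B)
  })
  observed <- offset + clean * slope + noise
  truth <- structure(list(ssc = ssc, ph = ph, slope = slope,
                          offset = offset, clean_spectra = clean),
                     class = "ground_truth")
  list(spectra = spectra_matrix(observed, wl), truth = truth)
}

#' Paint spectra into a synthetic scene cube
#'
#' Lays the samples out as filled disks on a uniform dark background in a
#' row-major grid (the platform layout of a line-scan acquisition, by
#' default 3 rows x 5 columns), each disk carrying its assigned spectrum
#' at every pixel. Ground-truth pixel masks are returned in the same
#' row-major order, so segmentation can be validated exactly.
#'
#' @param spectra [spectra_matrix] of the samples to place (at most
#'   `layout_rows * layout_cols` rows).
#' @param layout_rows,layout_cols grid layout (default 3 x 5).
#' @param disk_radius disk radius in pixels.
#' @param background_level uniform background reflectance at every band.
#' @param seed optional seed for small in-cell jitter of the disk centres;
#'   jitter is bounded so disks can never overlap or touch cell borders.
#' @param cell_px grid cell side in pixels; the default leaves a 4-pixel
#'   margin around each disk. A cell too small for the disks is a
#'   geometry error.
#' @return List with `cube` (a [reflectance_cube]) and `masks` (list of
#'   logical H x W matrices, row-major order).
#' @export
generate_scene_cube <- function(spectra, layout_rows = 3L,
                                layout_cols = 5L, disk_radius = 10L,
                                background_level = 0.05, seed = NULL,
                                cell_px = NULL) {
  if (!inherits(spectra, "spectra_matrix"))
    stop("generate_scene_cube: `spectra` must be a spectra_matrix")
  vals <- spectra_values(spectra)
  n <- nrow(vals)
  if (layout_rows * layout_cols < n)
    stop("generate_scene_cube: layout has fewer cells than spectra")
  cell <- if (is.null(cell_px)) 2L * disk_radius + 9L else as.integer(cell_px)
  if (cell < 2L * disk_radius + 3L)
    stop("generate_scene_cube: disks would overlap or touch cell borders")
  H <- layout_rows * cell; W <- layout_cols * cell
  B <- ncol(vals)
  max_jit <- (cell - 2L * disk_radius - 1L) %/% 2L - 1L
  jit <- matrix(0L, n, 2)
  if (!is.null(seed) && max_jit > 0)
    jit <- with_seed(seed,
      matrix(sample.int(2L * max_jit + 1L, 2L * n, replace = TRUE) -
               max_jit - 1L, n, 2))
  cube <- array(background_level, dim = c(H, W, B))
  masks <- vector("list", n)
  rowcoord <- matrix(seq_len(H), H, W)
  colcoord <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (k in seq_len(n)) {
    r <- (k - 1L) %/% layout_cols
    c <- (k - 1L) %% layout_cols
    cy <- r * cell + (cell + 1L) %/% 2L + jit[k, 1]
    cx <- c * cell + (cell + 1L) %/% 2L + jit[k, 2]
    mask <- (rowcoord - cy)^2 + (colcoord - cx)^2 <= disk_radius^2
    masks[[k]] <- mask
    idx <- which(mask)
    for (b in seq_len(B))
      cube[idx + (b - 1L) * H * W] <- vals[k, b]
  }
  list(cube = reflectance_cube(cube, spectra$wavelengths), masks = masks)
}
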