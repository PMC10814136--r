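#' Spectra matrix
#'
#' The modelling currency of the package: an `N x B` matrix of per-sample
#' mean reflectance spectra tied to a strictly increasing wavelength axis.
#'
#' @param values numeric `N x B` matrix of reflectance values (finite).
#' @param wavelengths numeric vector of length `B`, strictly increasing, nm.
#' @param sample_ids character vector of length `N`; defaults to
#'   `"S001", "S002", ...`.
#' @return An object of class `spectra_matrix` with fields `values`,
#'   `wavelengths` and `sample_ids`.
#' @export
spectra_matrix <- function(values, wavelengths, sample_ids = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values)))
    stop("spectra_matrix: non-finite entries in `values`")
  check_wavelengths(wavelengths, ncol(values))
  if (is.null(sample_ids))
    sample_ids <- sprintf("S%03d", seq_len(nrow(values)))
  if (length(sample_ids) != nrow(values))
    stop("spectra_matrix: `sample_ids` length must match rows of `values`")
  structure(
    list(values = values, wavelengths = as.numeric(wavelengths),
         sample_ids = as.character(sample_ids)),
    class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf("<spectra_matrix> %d samples x %d bands (%.1f-%.1f nm)\n",
              nrow(x$values), ncol(x$values),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
dim.spectra_matrix <- function(x) dim(x$values)

#' Raw hyperspectral cube
#'
#' An `H x W x B` array of non-negative detector counts with its wavelength
#' axis, as acquired by a push-broom camera. The same container serves the
#' white-reference and dark-reference roles in reflectance calibration.
#'
#' @param data numeric `H x W x B` array, non-negative.
#' @param wavelengths numeric vector of length `B`, strictly increasing, nm.
#' @return Object of class `raw_cube`.
#' @export
raw_cube <- function(data, wavelengths) {
  if (length(dim(data)) != 3L) stop("raw_cube: `data` must be H x W x B")
  if (any(data < 0)) stop("raw_cube: negative intensities")
  check_wavelengths(wavelengths, dim(data)[3])
  structure(list(data = data, wavelengths = as.numeric(wavelengths)),
            class = "raw_cube")
}

#' Calibrated reflectance cube
#'
#' An `H x W x B` array of unitless reflectance values (finite everywhere)
#' with its wavelength axis.
#'
#' @param data numeric `H x W x B` array, finite.
#' @param wavelengths numeric vector of length `B`, strictly increasing, nm.
#' @return Object of class `reflectance_cube`.
#' @export
reflectance_cube <- function(data, wavelengths) {
  if (length(dim(data)) != 3L)
    stop("reflectance_cube: `data` must be H x W x B")
  if (!all(is.finite(data))) stop("reflectance_cube: non-finite values")
  check_wavelengths(wavelengths, dim(data)[3])
  structure(list(data = data, wavelengths = as.numeric(wavelengths)),
            class = "reflectance_cube")
}

#' @export
print.raw_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<raw_cube> %d x %d pixels, %d bands\n", d[1], d[2], d[3]))
  invisible(x)
}

#' @export
print.reflectance_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<reflectance_cube> %d x %d pixels, %d bands\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Per-sample reference values of the two quality targets
#'
#' @param ssc numeric vector of soluble solid content values (degrees Brix,
#'   positive).
#' @param ph numeric vector of pH values in (0, 14), same length as `ssc`.
#' @param sample_ids optional character labels.
#' @return Object of class `target_table` (also a data.frame with columns
#'   `sample_id`, `ssc`, `ph`).
#' @export
target_table <- function(ssc, ph, sample_ids = NULL) {
  if (length(ssc) != length(ph))
    stop("target_table: `ssc` and `ph` lengths differ")
  if (any(ssc <= 0)) stop("target_table: ssc must be positive")
  if (any(ph <= 0 | ph >= 14)) stop("target_table: ph must lie in (0, 14)")
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_along(ssc))
  out <- data.frame(sample_id = as.character(sample_ids),
                    ssc = as.numeric(ssc), ph = as.numeric(ph),
                    stringsAsFactors = FALSE)
  class(out) <- c("target_table", "data.frame")
  out
}

check_wavelengths <- function(wl, b) {
  if (length(wl) != b)
    stop("wavelength axis length does not match the number of bands")
  if (b > 1 && any(diff(wl) <= 0))
    stop("wavelengths must be strictly increasing")
  invisible(TRUE)
}

# Accept either a spectra_matrix or a bare matrix where only values matter.
spectra_values <- function(x) {
  if (inherits(x, "spectra_matrix")) x$values else as.matrix(x)
}
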