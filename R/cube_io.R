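#' Read an ENVI hyperspectral cube
#'
#' Reads the text header and the companion binary file of an ENVI image
#' (the standard container written by push-broom hyperspectral cameras)
#' and returns the cube reordered to `H x W x B` (lines x samples x bands)
#' regardless of the stored interleave.
#'
#' @param header_path path to the `.hdr` text header. The binary file is
#'   located by stripping the `.hdr` suffix, or by appending `.raw`, `.dat`
#'   or `.img` to the stripped name.
#' @return A [raw_cube] with the wavelength axis parsed from the header.
#' @seealso [write_envi()], [calibrate_reflectance()]
#' @export
read_envi <- function(header_path) {
  if (!file.exists(header_path)) stop("read_envi: header not found: ",
                                      header_path)
  hdr <- parse_envi_header(header_path)
  for (f in c("samples", "lines", "bands", "interleave", "data type"))
    if (is.null(hdr[[f]])) stop("read_envi: header missing field `", f, "`")
  if (is.null(hdr$wavelength))
    stop("read_envi: header missing `wavelength` field")
  W <- as.integer(hdr$samples); H <- as.integer(hdr$lines)
  B <- as.integer(hdr$bands)
  wl <- as.numeric(strsplit(hdr$wavelength, ",")[[1]])
  if (length(wl) != B)
    stop("read_envi: wavelength list length does not match `bands`")
  interleave <- tolower(hdr$interleave)
  if (!interleave %in% c("bil", "bip", "bsq"))
    stop("read_envi: unsupported interleave `", interleave, "`")
  dtype <- as.integer(hdr[["data type"]])
  spec <- envi_dtype(dtype)
  bin <- envi_binary_path(header_path)
  n <- as.numeric(H) * W * B
  expect_bytes <- n * spec$size
  if (file.info(bin)$size != expect_bytes)
    stop(sprintf(
      "read_envi: binary size %d bytes does not match header dims (%d expected)",
      file.info(bin)$size, expect_bytes))
  con <- file(bin, "rb"); on.exit(close(con))
  v <- readBin(con, what = spec$what, n = n, size = spec$size,
               signed = spec$signed, endian = "little")
  data <- switch(interleave,
    bsq = aperm(array(v, dim = c(W, H, B)), c(2, 1, 3)),
    bil = aperm(array(v, dim = c(W, B, H)), c(3, 1, 2)),
    bip = aperm(array(v, dim = c(B, W, H)), c(3, 2, 1)))
  raw_cube(data, wl)
}

#' Write an ENVI hyperspectral cube
#'
#' @param cube a [raw_cube] or [reflectance_cube].
#' @param basepath output path without extension; `<basepath>.hdr` and
#'   `<basepath>.raw` are written.
#' @param interleave storage order, one of `"bil"`, `"bip"`, `"bsq"`.
#' @param data_type ENVI data type code: 4 (float32, default) or
#'   5 (float64).
#' @return Invisibly, the header path.
#' @export
write_envi <- function(cube, basepath, interleave = c("bil", "bip", "bsq"),
                       data_type = 4L) {
  interleave <- match.arg(interleave)
  if (!data_type %in% c(4L, 5L))
    stop("write_envi: only data types 4 (float32) and 5 (float64) written")
  d <- dim(cube$data); H <- d[1]; W <- d[2]; B <- d[3]
  v <- switch(interleave,
    bsq = as.vector(aperm(cube$data, c(2, 1, 3))),
    bil = as.vector(aperm(cube$data, c(2, 3, 1))),
    bip = as.vector(aperm(cube$data, c(3, 2, 1))))
  hdr_path <- paste0(basepath, ".hdr")
  writeLines(c(
    "ENVI",
    "description = { spectrareg cube }",
    paste0("samples = ", W),
    paste0("lines = ", H),
    paste0("bands = ", B),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", data_type),
    paste0("interleave = ", interleave),
    "byte order = 0",
    paste0("wavelength = { ",
           paste(format(cube$wavelengths, trim = TRUE), collapse = ", "),
           " }")), hdr_path)
  con <- file(paste0(basepath, ".raw"), "wb"); on.exit(close(con))
  writeBin(as.numeric(v), con, size = if (data_type == 4L) 4L else 8L,
           endian = "little")
  invisible(hdr_path)
}

parse_envi_header <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (length(txt) == 0L || !grepl("^ENVI", txt[1]))
    stop("read_envi: not an ENVI header (missing ENVI magic line)")
  # scan key = value entries; { ... } blocks may span lines
  out <- list()
  buf <- NULL; key <- NULL
  for (line in txt[-1]) {
    if (is.null(key)) {
      m <- regmatches(line, regexec("^([^=]+)=(.*)$", line))[[1]]
      if (length(m) == 0L) next
      key <- tolower(trimws(m[2])); val <- trimws(m[3])
      if (startsWith(val, "{") && !grepl("\\}", val)) {
        buf <- sub("^\\{", "", val)
        next
      }
      out[[key]] <- trimws(gsub("[{}]", "", val))
      key <- NULL
    } else {
      if (grepl("\\}", line)) {
        buf <- paste(buf, sub("\\}.*$", "", line))
        out[[key]] <- trimws(buf)
        key <- NULL; buf <- NULL
      } else {
        buf <- paste(buf, line)
      }
    }
  }
  out
}

envi_dtype <- function(code) {
  switch(as.character(code),
    "1"  = list(what = "integer", size = 1L, signed = FALSE),
    "2"  = list(what = "integer", size = 2L, signed = TRUE),
    "3"  = list(what = "integer", size = 4L, signed = TRUE),
    "4"  = list(what = "numeric", size = 4L, signed = TRUE),
    "5"  = list(what = "numeric", size = 8L, signed = TRUE),
    "12" = list(what = "integer", size = 2L, signed = FALSE),
    stop("read_envi: unsupported ENVI data type ", code))
}

envi_binary_path <- function(header_path) {
  base <- sub("\\.hdr$", "", header_path)
  cands <- c(base, paste0(base, c(".raw", ".dat", ".img")))
  for (p in cands) if (file.exists(p) && !identical(p, header_path)) return(p)
  stop("read_envi: no binary file found next to ", header_path)
}

#' White/dark reflectance calibration
#'
#' Converts raw counts to reflectance with the standard two-point
#' correction `R = (I - D) / (W - D)`, where `W` is the image of a white
#' reference plate and `D` the closed-shutter dark-current image. Pixels
#' where `W == D` (dead pixels) are set to 0 and counted in a warning so
#' they cannot poison downstream ROI means; reflectance above `clip_max`
#' (specular highlights) is clipped.
#'
#' @param I [raw_cube] of the scene.
#' @param W [raw_cube] of the white reference.
#' @param D [raw_cube] of the dark reference.
#' @param clip_max upper reflectance clip (default 1.5).
#' @return A [reflectance_cube] with the same wavelength axis.
#' @export
calibrate_reflectance <- function(I, W, D, clip_max = 1.5) {
  for (x in list(I, W, D))
    if (!inherits(x, "raw_cube")) stop("calibrate_reflectance: inputs must be raw_cube")
  if (!identical(dim(I$data), dim(W$data)) ||
      !identical(dim(I$data), dim(D$data)))
    stop("calibrate_reflectance: cube shapes differ")
  if (!isTRUE(all.equal(I$wavelengths, W$wavelengths)) ||
      !isTRUE(all.equal(I$wavelengths, D$wavelengths)))
    stop("calibrate_reflectance: wavelength axes differ")
  denom <- W$data - D$data
  dead <- denom == 0
  n_dead <- sum(dead)
  denom[dead] <- 1
  R <- (I$data - D$data) / denom
  R[dead] <- 0
  if (n_dead > 0)
    warning(sprintf("calibrate_reflectance: %d pixel/band cells with W == D set to 0",
                    n_dead))
  R[R > clip_max] <- clip_max
  reflectance_cube(R, I$wavelengths)
}

#' Trim noisy edge bands
#'
#' Drops a fixed count of bands from the front and/or back of the spectral
#' axis, keeping the wavelength axis consistent. The defaults drop the 15
#' noisy leading bands of a 224-band 900-1700 nm acquisition, leaving the
#' 209 bands the sequence models consume.
#'
#' @param x a [reflectance_cube], [raw_cube] or [spectra_matrix].
#' @param n_drop_front,n_drop_back number of bands removed at each end.
#' @return Object of the same class with `B - n_drop_front - n_drop_back`
#'   bands.
#' @export
crop_bands <- function(x, n_drop_front = 15L, n_drop_back = 0L) {
  UseMethod("crop_bands")
}

crop_band_index <- function(B, nf, nb) {
  if (nf < 0 || nb < 0) stop("crop_bands: drop counts must be >= 0")
  if (nf + nb >= B)
    stop("crop_bands: dropping ", nf + nb, " of ", B,
         " bands would leave none")
  seq.int(nf + 1L, B - nb)
}

#' @export
crop_bands.spectra_matrix <- function(x, n_drop_front = 15L,
                                      n_drop_back = 0L) {
  keep <- crop_band_index(ncol(x$values), n_drop_front, n_drop_back)
  spectra_matrix(x$values[, keep, drop = FALSE], x$wavelengths[keep],
                 x$sample_ids)
}

#' @export
crop_bands.reflectance_cube <- function(x, n_drop_front = 15L,
                                        n_drop_back = 0L) {
  keep <- crop_band_index(dim(x$data)[3], n_drop_front, n_drop_back)
  reflectance_cube(x$data[, , keep, drop = FALSE], x$wavelengths[keep])
}

#' @export
crop_bands.raw_cube <- function(x, n_drop_front = 15L, n_drop_back = 0L) {
  keep <- crop_band_index(dim(x$data)[3], n_drop_front, n_drop_back)
  raw_cube(x$data[, , keep, drop = FALSE], x$wavelengths[keep])
}
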