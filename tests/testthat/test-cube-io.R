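random_cube <- function(H = 5, W = 7, B = 11, lo = 0, hi = 100,
                        wl = NULL) {
  if (is.null(wl)) wl <- seq(900, 1700, length.out = B)
  raw_cube(array(runif(H * W * B, lo, hi), dim = c(H, W, B)), wl)
}

test_that("ENVI round trip is bit-identical for every interleave", {
  set.seed(21)
  cube <- random_cube()
  for (il in c("bil", "bip", "bsq")) {
    base <- file.path(tempdir(), paste0("rt_", il))
    write_envi(cube, base, interleave = il, data_type = 5L)
    got <- read_envi(paste0(base, ".hdr"))
    expect_identical(got$data, cube$data)
    expect_identical(got$wavelengths, cube$wavelengths)
  }
})

test_that("interleave is a storage detail: BIL and BSQ reads agree", {
  set.seed(22)
  cube <- random_cube(H = 4, W = 6, B = 5)
  b1 <- file.path(tempdir(), "as_bil"); b2 <- file.path(tempdir(), "as_bsq")
  write_envi(cube, b1, "bil", data_type = 5L)
  write_envi(cube, b2, "bsq", data_type = 5L)
  expect_identical(read_envi(paste0(b1, ".hdr"))$data,
                   read_envi(paste0(b2, ".hdr"))$data)
})

test_that("header/binary inconsistencies are format errors", {
  set.seed(23)
  cube <- random_cube(H = 3, W = 4, B = 6)
  base <- file.path(tempdir(), "bad")
  write_envi(cube, base, "bil", data_type = 5L)
  hdr <- readLines(paste0(base, ".hdr"))
  # advertise one band more than the binary holds
  writeLines(sub("bands = 6", "bands = 7", hdr), paste0(base, ".hdr"))
  expect_error(read_envi(paste0(base, ".hdr")), "wavelength list")
  writeLines(sub("bands = 6", "bands = 7",
                 sub("wavelength = \\{.*",
                     paste0("wavelength = { ",
                            paste(1:7, collapse = ", "), " }"), hdr)),
             paste0(base, ".hdr"))
  expect_error(read_envi(paste0(base, ".hdr")), "binary size")
  # no wavelength field at all
  writeLines(hdr[!grepl("wavelength", hdr)], paste0(base, ".hdr"))
  expect_error(read_envi(paste0(base, ".hdr")), "wavelength")
})

test_that("reflectance calibration identities hold on random cubes", {
  set.seed(24)
  for (rep in 1:3) {
    D <- random_cube(lo = 0, hi = 10)
    W <- raw_cube(D$data + array(runif(length(D$data), 5, 50),
                                 dim = dim(D$data)), D$wavelengths)
    expect_equal(calibrate_reflectance(W, W, D)$data,
                 array(1, dim = dim(D$data)))
    expect_equal(calibrate_reflectance(D, W, D)$data,
                 array(0, dim = dim(D$data)))
    mid <- raw_cube((W$data + D$data) / 2, D$wavelengths)
    expect_equal(calibrate_reflectance(mid, W, D)$data,
                 array(0.5, dim = dim(D$data)))
  }
})

test_that("calibration equals the per-element formula, with guards", {
  set.seed(25)
  D <- random_cube(lo = 0, hi = 10)
  W <- raw_cube(D$data + array(runif(length(D$data), 0.5, 50),
                               dim = dim(D$data)), D$wavelengths)
  I <- random_cube(lo = 0, hi = 60)
  R <- calibrate_reflectance(I, W, D, clip_max = Inf)
  expect_equal(R$data, (I$data - D$data) / (W$data - D$data))
  # clipping
  Rc <- calibrate_reflectance(I, W, D, clip_max = 1.5)
  expect_true(all(Rc$data <= 1.5))
  # dead pixels (W == D) map to 0 and are counted
  Wd <- W; Wd$data[1, 1, ] <- D$data[1, 1, ]
  expect_warning(Rd <- calibrate_reflectance(I, Wd, D), "set to 0")
  expect_equal(unname(Rd$data[1, 1, ]), rep(0, dim(D$data)[3]))
  # shape and axis mismatches are parameter errors
  expect_error(calibrate_reflectance(I, W, random_cube(H = 6)), "shape")
  D2 <- D; D2$wavelengths <- D2$wavelengths + 1
  expect_error(calibrate_reflectance(I, W, D2), "wavelength")
})

test_that("default band crop leaves 209 of 224 bands", {
  sm <- spectra_matrix(matrix(runif(2 * 224), 2, 224),
                       seq(900, 1700, length.out = 224))
  out <- crop_bands(sm)
  expect_equal(ncol(out$values), 209L)
  expect_equal(out$wavelengths, sm$wavelengths[-(1:15)])
  expect_equal(crop_bands(sm, 0, 0)$values, sm$values)
  expect_error(crop_bands(sm, 224, 0), "leave none")
  expect_error(crop_bands(sm, 120, 104), "leave none")
})

test_that("band cropping commutes with calibration", {
  set.seed(26)
  D <- random_cube(lo = 0, hi = 5, B = 24)
  W <- raw_cube(D$data + array(runif(length(D$data), 1, 20),
                               dim = dim(D$data)), D$wavelengths)
  I <- random_cube(lo = 0, hi = 30, B = 24)
  a <- crop_bands(calibrate_reflectance(I, W, D), 3, 2)
  b <- calibrate_reflectance(crop_bands(I, 3, 2), crop_bands(W, 3, 2),
                             crop_bands(D, 3, 2))
  expect_equal(a$data, b$data)
  expect_equal(a$wavelengths, b$wavelengths)
})
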