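# ENVI cube I/O and reflectance calibration.

test_that("cubes round-trip bit-identically through every interleave", {
  w <- 400 + (0:9) * 2.941
  set.seed(11)
  cube <- hypercube(array(round(runif(6 * 7 * 10) * 1000, 3), c(6, 7, 10)), w)
  td <- withr::local_tempdir()
  stored <- list()
  for (il in c("bsq", "bil", "bip")) {
    write_envi(cube, file.path(td, il), interleave = il, data_type = 5)
    back <- read_envi(file.path(td, paste0(il, ".hdr")))
    expect_identical(back$data, cube$data)
    expect_identical(back$wavelengths_nm, cube$wavelengths_nm)
    expect_false(back$calibrated)
    stored[[il]] <- back$data
  }
  # interleave invariance: all three readbacks agree bit for bit
  expect_identical(stored$bsq, stored$bil)
  expect_identical(stored$bsq, stored$bip)
})

test_that("a hand-laid BSQ byte stream reads back to the laid values", {
  # 2 rows x 2 cols x 3 bands, float64 little-endian; BSQ stores, band by
  # band, each line with its samples in order:
  #   band1: v[r1c1] v[r1c2] v[r2c1] v[r2c2], then band2, band3
  td <- withr::local_tempdir()
  vals <- c(11, 12, 21, 22,      # band 1, laid row-major
            110, 120, 210, 220,  # band 2
            1100, 1200, 2100, 2200)
  con <- file(file.path(td, "hand.dat"), "wb")
  writeBin(as.double(vals), con, size = 8, endian = "little")
  close(con)
  writeLines(c("ENVI", "samples = 2", "lines = 2", "bands = 3",
               "header offset = 0", "data type = 5", "interleave = bsq",
               "byte order = 0",
               "wavelength = { 500.0, 600.0, 700.0 }"),
             file.path(td, "hand.hdr"))
  cube <- read_envi(file.path(td, "hand.hdr"))
  expect_equal(cube$data[1, 1, ], c(11, 110, 1100))
  expect_equal(cube$data[1, 2, ], c(12, 120, 1200))
  expect_equal(cube$data[2, 1, ], c(21, 210, 2100))
  expect_equal(cube$data[2, 2, ], c(22, 220, 2200))
  expect_equal(cube$wavelengths_nm, c(500, 600, 700))
})

test_that("malformed headers and size mismatches are rejected", {
  td <- withr::local_tempdir()
  write_hdr <- function(lines, name) {
    writeLines(lines, file.path(td, paste0(name, ".hdr")))
    con <- file(file.path(td, paste0(name, ".dat")), "wb")
    writeBin(as.double(1:12), con, size = 8, endian = "little")
    close(con)
    file.path(td, paste0(name, ".hdr"))
  }
  base <- c("ENVI", "samples = 2", "lines = 2", "bands = 3",
            "data type = 5", "interleave = bsq", "byte order = 0")
  # wavelength count disagreeing with the band count
  expect_error(
    read_envi(write_hdr(c(base, "wavelength = { 500, 600 }"), "short")),
    class = "hs_format_error")
  # missing required field
  expect_error(
    read_envi(write_hdr(c("ENVI", "samples = 2", "lines = 2",
                          "data type = 5", "interleave = bsq",
                          "wavelength = { 1, 2, 3 }"), "nobands")),
    class = "hs_format_error")
  # data file shorter than the header implies
  hdr <- write_hdr(c("ENVI", "samples = 4", "lines = 4", "bands = 3",
                     "data type = 5", "interleave = bsq",
                     "wavelength = { 500, 600, 700 }"), "trunc")
  expect_error(read_envi(hdr), class = "hs_corruption_error")
})

test_that("a zero-band cube cannot be constructed", {
  expect_error(hypercube(array(0, c(2, 2, 0)), numeric(0)),
               class = "hs_format_error")
})

test_that("calibration follows the white/dark ratio convention", {
  w <- c(500, 600, 700)
  white <- hypercube(array(1200, c(2, 2, 3)), w)
  raw <- hypercube(array(600, c(2, 2, 3)), w)
  # direct ratio: 1023 * 600 / 1200 = 511.5 c.u.
  cal <- calibrate(raw, white)
  expect_true(cal$calibrated)
  expect_equal(unique(as.vector(cal$data)), 511.5)

  # self-reference is constant full scale; raw = dark is zero
  expect_equal(unique(as.vector(calibrate(white, white)$data)), 1023)
  dark <- hypercube(array(100, c(2, 2, 3)), w)
  expect_equal(unique(as.vector(calibrate(dark, white, dark)$data)), 0)

  # negative post-subtraction values clip to zero instead of failing
  low <- hypercube(array(50, c(2, 2, 3)), w)
  expect_equal(unique(as.vector(calibrate(low, white, dark)$data)), 0)

  # degenerate reference: white <= dark
  expect_error(calibrate(raw, dark, white),
               class = "hs_degenerate_reference_error")
})

test_that("calibration is pixelwise monotone in the raw counts", {
  w <- c(500, 600, 700)
  set.seed(3)
  a <- array(runif(2 * 2 * 3) * 500, c(2, 2, 3))
  b <- a + array(runif(2 * 2 * 3) * 300, c(2, 2, 3))
  white <- hypercube(array(900, c(2, 2, 3)), w)
  ca <- calibrate(hypercube(a, w), white)
  cb <- calibrate(hypercube(b, w), white)
  expect_true(all(ca$data <= cb$data))
})

test_that("manifests round-trip and validate their referenced paths", {
  td <- withr::local_tempdir()
  w <- c(500, 600)
  for (f in c("a_before", "a_after", "b_before", "b_after", "white")) {
    write_envi(hypercube(array(1, c(2, 2, 2)), w), file.path(td, f))
  }
  man <- data.frame(patient_id = c("a", "b"),
                    before = c("a_before.hdr", "b_before.hdr"),
                    after = c("a_after.hdr", "b_after.hdr"),
                    roi = "0:0:2:2", stringsAsFactors = FALSE)
  path <- file.path(td, "manifest.tsv")
  write_manifest(man, path, white = "white.hdr")
  back <- read_manifest(path)
  expect_equal(back$patient_id, c("a", "b"))
  expect_true(all(file.exists(back$before, back$after)))
  expect_true(file.exists(attr(back, "white")))

  man$before[1] <- "missing.hdr"
  write_manifest(man, path, white = "white.hdr")
  expect_error(read_manifest(path), "missing.hdr", class = "hs_io_error")
})
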