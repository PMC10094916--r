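# ENVI header + raw-binary I/O.
#
# The ENVI convention stores an ASCII "key = value" header (samples, lines,
# bands, data type, interleave, byte order, wavelength list) next to a raw
# binary file holding the cube in one of three interleaves:
#   BSQ  band-sequential:   sample fastest, then line, then band
#   BIL  band-interleaved-by-line:  sample, then band, then line
#   BIP  band-interleaved-by-pixel: band fastest, then sample, then line
# Push-broom cameras of the kind used for skin imaging emit exactly this
# layout, so the package reads and writes it natively.

ENVI_TYPES <- list(
  `1`  = list(what = "integer", size = 1L, signed = FALSE),
  `2`  = list(what = "integer", size = 2L, signed = TRUE),
  `3`  = list(what = "integer", size = 4L, signed = TRUE),
  `4`  = list(what = "numeric", size = 4L, signed = TRUE),
  `5`  = list(what = "numeric", size = 8L, signed = TRUE),
  `12` = list(what = "integer", size = 2L, signed = FALSE)
)

# permutation taking a (row, col, band) array to storage order for each
# interleave; the same permutation maps the read-back array home again.
interleave_perm <- function(interleave) {
  switch(interleave,
    bsq = c(2L, 1L, 3L),
    bil = c(2L, 3L, 1L),
    bip = c(3L, 2L, 1L),
    hs_stop("unknown interleave '%s'", "hs_format_error", interleave))
}

storage_dim <- function(interleave, samples, lines, bands) {
  switch(interleave,
    bsq = c(samples, lines, bands),
    bil = c(samples, bands, lines),
    bip = c(bands, samples, lines))
}

unperm <- function(interleave) {
  switch(interleave,
    bsq = c(2L, 1L, 3L),
    bil = c(3L, 1L, 2L),
    bip = c(3L, 2L, 1L))
}

#' Write a hyperspectral cube as an ENVI header + raw file pair
#'
#' Writes `<path>.hdr` (ASCII header including the wavelength list) and
#' `<path>.dat` (raw binary). Wavelengths are printed with 10 significant
#' digits and survive a read/write round trip unchanged for grids of
#' laboratory precision.
#'
#' @param cube a [hypercube()].
#' @param path output path without extension (a trailing `.hdr` is stripped).
#' @param interleave one of `"bsq"`, `"bil"`, `"bip"`.
#' @param data_type ENVI data type code: 2 (int16), 3 (int32), 4 (float32,
#'   default), 5 (float64).
#' @return Invisibly, the header path.
#' @seealso [read_envi()]
#' @export
write_envi <- function(cube, path, interleave = c("bsq", "bil", "bip"),
                       data_type = 4L) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  data_type <- as.integer(data_type)
  if (!data_type %in% c(2L, 3L, 4L, 5L)) {
    hs_stop("unsupported output data type %d", "hs_format_error", data_type)
  }
  base <- sub("\\.hdr$", "", path)
  hdr_path <- paste0(base, ".hdr")
  dat_path <- paste0(base, ".dat")

  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    sprintf("description = {hyperskin cube, %s}",
            if (cube$calibrated) "calibrated reflectance (c.u.)" else "raw counts"),
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("reflectance scale factor = %.10g", cube$scale_cu),
    "wavelength = {",
    paste0(" ", paste(sprintf("%.10g", cube$wavelengths_nm), collapse = ", ")),
    "}"
  )
  ok <- tryCatch({
    writeLines(hdr, hdr_path)
    TRUE
  }, error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) hs_stop("cannot write header '%s'", "hs_io_error", hdr_path)

  vec <- as.vector(aperm(cube$data, interleave_perm(interleave)))
  con <- tryCatch(file(dat_path, "wb"), error = function(e) NULL,
                  warning = function(e) NULL)
  if (is.null(con)) hs_stop("cannot write data file '%s'", "hs_io_error", dat_path)
  on.exit(close(con), add = TRUE)
  spec <- ENVI_TYPES[[as.character(data_type)]]
  if (spec$what == "integer") {
    writeBin(as.integer(round(vec)), con, size = spec$size, endian = "little")
  } else {
    writeBin(as.double(vec), con, size = spec$size, endian = "little")
  }
  invisible(hdr_path)
}

parse_envi_header <- function(header_path) {
  lines <- readLines(header_path, warn = FALSE)
  if (!length(lines) || !grepl("ENVI", lines[[1L]], fixed = TRUE)) {
    hs_stop("'%s' is not an ENVI header", "hs_format_error", header_path)
  }
  fields <- list()
  i <- 2L
  while (i <= length(lines)) {
    ln <- lines[[i]]
    if (grepl("=", ln, fixed = TRUE)) {
      key <- tolower(trimws(sub("=.*$", "", ln)))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (startsWith(val, "{") && !grepl("\\}", val)) {
        # brace block possibly spanning several lines
        while (i < length(lines) && !grepl("\\}", val)) {
          i <- i + 1L
          val <- paste(val, trimws(lines[[i]]))
        }
      }
      fields[[key]] <- val
    }
    i <- i + 1L
  }
  fields
}

num_field <- function(fields, key, header_path) {
  if (is.null(fields[[key]])) {
    hs_stop("header '%s' is missing required field '%s'",
            "hs_format_error", header_path, key)
  }
  out <- suppressWarnings(as.numeric(fields[[key]]))
  if (is.na(out)) {
    hs_stop("header field '%s' is not numeric", "hs_format_error", key)
  }
  out
}

brace_list <- function(val) {
  inner <- gsub("[{}]", "", val)
  out <- suppressWarnings(as.numeric(strsplit(inner, ",")[[1L]]))
  out[!is.na(out)]
}

#' Read an ENVI header + raw file pair into a hypercube
#'
#' Accepts any of the three standard interleaves (BSQ, BIL, BIP) and returns
#' the cube reordered to `(row, col, band)` regardless of how it was stored.
#' The data file is located next to the header (same basename, with no
#' extension or one of `.dat`, `.raw`, `.img`).
#'
#' @param header_path path to the `.hdr` file.
#' @return A [hypercube()] with `calibrated = FALSE` unless the cube is later
#'   calibrated; wavelengths come from the header.
#' @export
read_envi <- function(header_path) {
  if (!file.exists(header_path)) {
    hs_stop("header '%s' does not exist", "hs_io_error", header_path)
  }
  fields <- parse_envi_header(header_path)

  samples <- as.integer(num_field(fields, "samples", header_path))
  lines_n <- as.integer(num_field(fields, "lines", header_path))
  bands <- as.integer(num_field(fields, "bands", header_path))
  dtype <- as.integer(num_field(fields, "data type", header_path))
  if (is.null(fields[["interleave"]])) {
    hs_stop("header '%s' is missing required field 'interleave'",
            "hs_format_error", header_path)
  }
  interleave <- tolower(fields[["interleave"]])
  byte_order <- if (is.null(fields[["byte order"]])) 0L else
    as.integer(num_field(fields, "byte order", header_path))
  offset <- if (is.null(fields[["header offset"]])) 0L else
    as.integer(num_field(fields, "header offset", header_path))
  if (is.null(fields[["wavelength"]])) {
    hs_stop("header '%s' is missing required field 'wavelength'",
            "hs_format_error", header_path)
  }
  wavelengths <- brace_list(fields[["wavelength"]])
  if (length(wavelengths) != bands) {
    hs_stop("header declares %d bands but %d wavelengths",
            "hs_format_error", bands, length(wavelengths))
  }
  scale_cu <- if (is.null(fields[["reflectance scale factor"]])) 1023 else
    num_field(fields, "reflectance scale factor", header_path)

  spec <- ENVI_TYPES[[as.character(dtype)]]
  if (is.null(spec)) {
    hs_stop("unsupported ENVI data type %d", "hs_format_error", dtype)
  }

  base <- sub("\\.hdr$", "", header_path)
  candidates <- paste0(base, c("", ".dat", ".raw", ".img", ".bsq", ".bil", ".bip"))
  dat_path <- candidates[file.exists(candidates)][1L]
  if (is.na(dat_path)) {
    hs_stop("no data file found for header '%s'", "hs_io_error", header_path)
  }

  n <- as.double(samples) * lines_n * bands
  expected <- n * spec$size + offset
  actual <- file.size(dat_path)
  if (!isTRUE(actual == expected)) {
    hs_stop("data file '%s' has %.0f bytes but header implies %.0f",
            "hs_corruption_error", dat_path, as.double(actual),
            as.double(expected))
  }

  con <- file(dat_path, "rb")
  on.exit(close(con), add = TRUE)
  if (offset > 0L) readBin(con, "raw", n = offset)
  endian <- if (byte_order == 0L) "little" else "big"
  vec <- readBin(con, spec$what, n = n, size = spec$size,
                 signed = spec$signed, endian = endian)
  if (length(vec) != n) {
    hs_stop("short read from '%s'", "hs_corruption_error", dat_path)
  }
  arr <- array(vec, dim = storage_dim(interleave, samples, lines_n, bands))
  data <- aperm(arr, unperm(interleave))
  hypercube(data, wavelengths, calibrated = FALSE, scale_cu = scale_cu)
}

#' Calibrate raw counts to reflectance against a white reference
#'
#' Converts raw sensor counts to reflectance in counts-units via the standard
#' flat-field convention: the white-reference cube is spatially averaged to a
#' per-band reference spectrum, and
#' `reflectance = scale_cu * (raw - dark) / (white - dark)` per band, with the
#' dark reference taken as zero when absent. Values that fall below zero after
#' dark subtraction (sensor noise) are clipped to zero rather than rejected.
#'
#' @param raw raw-counts [hypercube()].
#' @param white white-reference [hypercube()] on the same band grid; its
#'   pixels are averaged per band.
#' @param dark optional dark-reference cube (same grid) or per-band numeric
#'   vector; defaults to zero.
#' @param scale_cu counts-units scale of the result; defaults to the scale
#'   carried by `raw`.
#' @return A calibrated [hypercube()] in c.u.
#' @examples
#' w <- c(500, 600, 700)
#' raw <- hypercube(array(600, c(2, 2, 3)), w)
#' white <- hypercube(array(1200, c(2, 2, 3)), w)
#' calibrate(raw, white)$data[1, 1, 1]   # 511.5 c.u. on the 1023 scale
#' @export
calibrate <- function(raw, white, dark = NULL, scale_cu = NULL) {
  stopifnot(inherits(raw, "hypercube"), inherits(white, "hypercube"))
  scale_cu <- scale_cu %||% raw$scale_cu
  if (length(raw$wavelengths_nm) != length(white$wavelengths_nm) ||
      any(abs(raw$wavelengths_nm - white$wavelengths_nm) > 1e-6)) {
    hs_stop("raw and white cubes are on different band grids",
            "hs_format_error")
  }
  nb <- dim(raw$data)[3L]
  wd <- dim(white$data)
  wm <- colMeans(matrix(white$data, nrow = wd[1L] * wd[2L], ncol = wd[3L]))

  if (is.null(dark)) {
    dm <- rep(0, nb)
  } else if (inherits(dark, "hypercube")) {
    if (any(abs(raw$wavelengths_nm - dark$wavelengths_nm) > 1e-6)) {
      hs_stop("dark cube is on a different band grid", "hs_format_error")
    }
    dd <- dim(dark$data)
    dm <- colMeans(matrix(dark$data, nrow = dd[1L] * dd[2L], ncol = dd[3L]))
  } else {
    dm <- rep_len(as.numeric(dark), nb)
  }
  if (any(wm <= dm)) {
    hs_stop("degenerate reference: white <= dark in %d band(s)",
            "hs_degenerate_reference_error", sum(wm <= dm))
  }
  d <- dim(raw$data)
  m <- matrix(raw$data, nrow = d[1L] * d[2L], ncol = d[3L])
  refl <- scale_cu * sweep(sweep(m, 2L, dm, "-"), 2L, wm - dm, "/")
  refl[refl < 0] <- 0
  hypercube(array(refl, dim = d), raw$wavelengths_nm,
            calibrated = TRUE, scale_cu = scale_cu)
}

#' Read / write a cohort manifest
#'
#' A manifest is a tab-separated table with one patient per row and columns
#' `patient_id`, `before`, `after` (paths to ENVI headers) and `roi`
#' (`row0:col0:row1:col1`). A comment line `# white = <path>` records the
#' shared white-reference cube. Relative paths are resolved against the
#' manifest's directory.
#'
#' @param path manifest file path.
#' @return `read_manifest()`: a data.frame with attribute `"white"` holding
#'   the white-reference header path.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    hs_stop("manifest '%s' does not exist", "hs_io_error", path)
  }
  lines <- readLines(path, warn = FALSE)
  white <- NULL
  cm <- grep("^#", lines, value = TRUE)
  wl <- grep("^#\\s*white\\s*=", cm, value = TRUE)
  if (length(wl)) white <- trimws(sub("^#\\s*white\\s*=", "", wl[[1L]]))
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  need <- c("patient_id", "before", "after", "roi")
  if (!all(need %in% names(df))) {
    hs_stop("manifest must have columns %s", "hs_format_error",
            paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$patient_id)) {
    hs_stop("duplicate patient ids in manifest", "hs_format_error")
  }
  root <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(root, p))
  df$before <- resolve(df$before)
  df$after <- resolve(df$after)
  if (!is.null(white)) white <- resolve(white)
  missing <- c(df$before, df$after, white)
  missing <- missing[!file.exists(missing)]
  if (length(missing)) {
    hs_stop("manifest references missing file(s): %s", "hs_io_error",
            paste(missing, collapse = ", "))
  }
  attr(df, "white") <- white
  df
}

#' @rdname read_manifest
#' @param manifest data.frame with columns `patient_id`, `before`, `after`,
#'   `roi`.
#' @param white path to the white-reference header, stored as a comment line.
#' @export
write_manifest <- function(manifest, path, white = NULL) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  if (!is.null(white)) writeLines(sprintf("# white = %s", white), con)
  utils::write.table(manifest[, c("patient_id", "before", "after", "roi")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
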