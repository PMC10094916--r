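#' Hyperspectral cube
#'
#' Container for a hyperspectral image: a 3-D array indexed `(row, col, band)`
#' with one wavelength per band. Values are either raw sensor counts
#' (`calibrated = FALSE`) or reflectance in counts-units ("c.u.") on a scale
#' where `scale_cu` corresponds to 100% reflectance of the white reference
#' (1023, a 10-bit-like scale, by default).
#'
#' @param data numeric 3-D array, dimensions `(rows, cols, bands)`; all values
#'   must be finite and non-negative.
#' @param wavelengths_nm strictly increasing numeric vector, one wavelength
#'   (nanometres) per band.
#' @param calibrated logical; `TRUE` once the cube holds reflectance rather
#'   than raw counts.
#' @param scale_cu counts-units value that corresponds to 100% reflectance.
#' @return An object of class `"hypercube"`.
#' @examples
#' cube <- hypercube(array(500, c(4, 4, 3)), c(450, 550, 650))
#' dim(cube$data)
#' @export
hypercube <- function(data, wavelengths_nm, calibrated = FALSE,
                      scale_cu = 1023) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    hs_stop("cube data must be a 3-D array (row, col, band)", "hs_format_error")
  }
  if (any(dim(data) < 1L)) {
    hs_stop("cube must have at least one row, column and band",
            "hs_format_error")
  }
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (length(wavelengths_nm) != dim(data)[3L]) {
    hs_stop("got %d wavelengths for %d bands", "hs_format_error",
            length(wavelengths_nm), dim(data)[3L])
  }
  if (length(wavelengths_nm) > 1L && any(diff(wavelengths_nm) <= 0)) {
    hs_stop("wavelengths must be strictly increasing", "hs_format_error")
  }
  if (anyNA(data) || any(!is.finite(data)) || any(data < 0)) {
    hs_stop("cube values must be finite and >= 0", "hs_format_error")
  }
  if (!is.numeric(scale_cu) || length(scale_cu) != 1L || scale_cu <= 0) {
    hs_stop("scale_cu must be a positive scalar", "hs_format_error")
  }
  structure(
    list(data = data, wavelengths_nm = wavelengths_nm,
         calibrated = isTRUE(calibrated), scale_cu = as.numeric(scale_cu)),
    class = "hypercube"
  )
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<hypercube> %d x %d pixels, %d bands (%.1f-%.1f nm), %s, scale %g c.u.\n",
    d[1L], d[2L], d[3L], min(x$wavelengths_nm), max(x$wavelengths_nm),
    if (x$calibrated) "calibrated reflectance" else "raw counts", x$scale_cu))
  invisible(x)
}

#' Rectangular region of interest
#'
#' 0-based, half-open pixel rectangle: rows `row0 <= r < row1`, columns
#' `col0 <= c < col1`. This is the single coordinate convention used by the
#' whole package.
#'
#' @param row0,col0 inclusive upper-left corner (0-based).
#' @param row1,col1 exclusive lower-right corner.
#' @return An object of class `"roi"`.
#' @examples
#' roi(0, 0, 64, 64)     # a full 64 x 64 frame
#' @export
roi <- function(row0, col0, row1, col1) {
  v <- c(row0 = row0, col0 = col0, row1 = row1, col1 = col1)
  if (!all(vapply(v, is_count, logical(1L)))) {
    hs_stop("roi bounds must be integers", "hs_format_error")
  }
  v <- stats::setNames(as.integer(v), names(v))
  if (v[["row0"]] < 0L || v[["col0"]] < 0L ||
      v[["row0"]] >= v[["row1"]] || v[["col0"]] >= v[["col1"]]) {
    hs_stop("roi must satisfy 0 <= row0 < row1 and 0 <= col0 < col1",
            "hs_format_error")
  }
  structure(as.list(v), class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> %s\n", format_roi(x)))
  invisible(x)
}

format_roi <- function(r) {
  sprintf("%d:%d:%d:%d", r$row0, r$col0, r$row1, r$col1)
}

#' Parse a `row0:col0:row1:col1` ROI string
#'
#' @param x character scalar, e.g. `"0:0:64:64"`.
#' @return A [roi()] object.
#' @export
parse_roi <- function(x) {
  parts <- suppressWarnings(as.integer(strsplit(x, ":", fixed = TRUE)[[1L]]))
  if (length(parts) != 4L || anyNA(parts)) {
    hs_stop("cannot parse roi '%s' (expected row0:col0:row1:col1)",
            "hs_format_error", x)
  }
  roi(parts[1L], parts[2L], parts[3L], parts[4L])
}

#' Crop a cube to a region of interest
#'
#' @param cube a [hypercube()].
#' @param region a [roi()], or `NULL` for the full frame.
#' @return A `"hypercube"` restricted to the ROI pixels.
#' @export
crop_cube <- function(cube, region = NULL) {
  stopifnot(inherits(cube, "hypercube"))
  if (is.null(region)) return(cube)
  stopifnot(inherits(region, "roi"))
  d <- dim(cube$data)
  if (region$row1 > d[1L] || region$col1 > d[2L]) {
    hs_stop("roi %s exceeds cube extent %d x %d", "hs_format_error",
            format_roi(region), d[1L], d[2L])
  }
  hypercube(
    cube$data[(region$row0 + 1L):region$row1,
              (region$col0 + 1L):region$col1, , drop = FALSE],
    cube$wavelengths_nm, cube$calibrated, cube$scale_cu)
}

# Band-mean ("total") reflectance image of a cube ROI, the per-pixel quantity
# that both the gray conversion and the brightest/darkest-pixel rules use.
total_reflectance <- function(cube, region = NULL) {
  sub <- crop_cube(cube, region)
  d <- dim(sub$data)
  matrix(rowMeans(matrix(sub$data, nrow = d[1L] * d[2L], ncol = d[3L])),
         nrow = d[1L], ncol = d[2L])
}
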