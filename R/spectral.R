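# ROI spectral profiling: maximum / average / minimum reflectance curves and
# band statistics at the melanin analysis wavelength.

#' Maximum, average and minimum ROI reflectance profiles
#'
#' Because a pixel's gray level corresponds to its total (band-mean)
#' reflectance, the brightest and darkest pixels of the ROI can be identified
#' automatically; the "maximum" and "minimum" curves are the full spectra of
#' those two pixels, and the "average" curve is the per-band arithmetic mean
#' over all ROI pixels. Ties for brightest/darkest break to the first pixel
#' in row-major order. `pixel_rule = "pointwise"` instead returns the
#' per-band pointwise max/min envelopes; for cubes whose pixel spectra share
#' one spectral shape the two rules coincide.
#'
#' @param cube calibrated [hypercube()].
#' @param region [roi()] or `NULL` for the full frame.
#' @param pixel_rule `"brightest"` (single brightest/darkest pixel spectrum,
#'   the default) or `"pointwise"` (per-band envelope).
#' @return An object of class `"spectral_profile"`: list with
#'   `wavelengths_nm`, `max_cu`, `mean_cu`, `min_cu`.
#' @export
roi_profiles <- function(cube, region = NULL,
                         pixel_rule = c("brightest", "pointwise")) {
  stopifnot(inherits(cube, "hypercube"))
  pixel_rule <- match.arg(pixel_rule)
  if (!cube$calibrated) {
    hs_stop("cube must be calibrated before profiling", "hs_state_error")
  }
  sub <- crop_cube(cube, region)
  d <- dim(sub$data)
  if (d[1L] * d[2L] < 1L) {
    hs_stop("empty ROI", "hs_degenerate_input_error")
  }
  m <- matrix(sub$data, nrow = d[1L] * d[2L], ncol = d[3L])
  mean_cu <- colMeans(m)

  if (pixel_rule == "pointwise") {
    max_cu <- apply(m, 2L, max)
    min_cu <- apply(m, 2L, min)
  } else {
    tot <- rowMeans(m)
    # row-major first occurrence on ties; the matrix is column-major, so
    # order candidate indices by (row, col) explicitly
    pick <- function(idx) {
      rr <- (idx - 1L) %% d[1L] + 1L
      cc <- (idx - 1L) %/% d[1L] + 1L
      idx[order(rr, cc)][1L]
    }
    imax <- pick(which(tot == max(tot)))
    imin <- pick(which(tot == min(tot)))
    max_cu <- m[imax, ]
    min_cu <- m[imin, ]
  }
  structure(list(wavelengths_nm = sub$wavelengths_nm, max_cu = max_cu,
                 mean_cu = mean_cu, min_cu = min_cu),
            class = "spectral_profile")
}

#' @export
print.spectral_profile <- function(x, ...) {
  cat(sprintf("<spectral_profile> %d bands (%.1f-%.1f nm)\n",
              length(x$wavelengths_nm), min(x$wavelengths_nm),
              max(x$wavelengths_nm)))
  invisible(x)
}

#' @export
as.data.frame.spectral_profile <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelengths_nm, max_cu = x$max_cu,
             mean_cu = x$mean_cu, min_cu = x$min_cu)
}

#' Index of the band nearest a wavelength
#'
#' @param x a [hypercube()], a `"spectral_profile"`, or a numeric wavelength
#'   vector.
#' @param lambda_nm query wavelength; must lie within the grid's range.
#' @return 1-based band index; ties between two equidistant bands resolve to
#'   the lower index.
#' @export
band_index <- function(x, lambda_nm) {
  w <- if (is.numeric(x)) x else x$wavelengths_nm
  if (length(lambda_nm) != 1L || !is.finite(lambda_nm)) {
    hs_stop("lambda_nm must be a finite scalar", "hs_format_error")
  }
  if (lambda_nm < min(w) - 1e-9 || lambda_nm > max(w) + 1e-9) {
    hs_stop("wavelength %g nm outside grid range [%g, %g]",
            "hs_range_error", lambda_nm, min(w), max(w))
  }
  which.min(abs(w - lambda_nm))
}

#' Mean reflectance and max-min range at an analysis band
#'
#' Reads the mean curve and the difference between the maximum and minimum
#' curves of a [roi_profiles()] result at the band nearest `lambda_nm` -
#' the per-patient quantities compared before/after treatment at the 654 nm
#' melanin band.
#'
#' @param profile a `"spectral_profile"`.
#' @param lambda_nm analysis wavelength (default 654 nm).
#' @return Named list: `lambda_nm` (the selected band's wavelength),
#'   `mean_cu`, `range_cu`.
#' @export
band_metrics <- function(profile, lambda_nm = 654) {
  stopifnot(inherits(profile, "spectral_profile"))
  idx <- band_index(profile, lambda_nm)
  list(lambda_nm = profile$wavelengths_nm[idx],
       mean_cu = profile$mean_cu[idx],
       range_cu = profile$max_cu[idx] - profile$min_cu[idx])
}
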