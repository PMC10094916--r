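# End-to-end cohort analysis: ENVI cubes -> calibration -> texture + band
# metrics per patient and phase.

#' Analyze a paired before/after cohort of hyperspectral cubes
#'
#' For each patient and phase the cube is read, calibrated against the shared
#' white reference, cropped to the manifest ROI, and reduced to the five
#' per-ROI metrics: gray-level brightness, GLCM contrast, GLCM homogeneity,
#' and the ROI-mean reflectance and max-min reflectance range at the band
#' nearest `lambda_nm`.
#'
#' @param manifest cohort manifest data.frame (see [read_manifest()]); its
#'   `"white"` attribute, or the `white` argument, names the white-reference
#'   header.
#' @param white optional white-reference header path, overriding the
#'   manifest attribute.
#' @param params [glcm_params()]; defaults mirror the study protocol
#'   (d = 1, theta = 0, G = 256, asymmetric).
#' @param lambda_nm analysis wavelength (default 654 nm).
#' @param dark optional dark reference passed to [calibrate()].
#' @param keep_profiles,keep_gray also return the spectral profiles / gray
#'   images (for reporting).
#' @return A data.frame with one row per patient and phase and columns
#'   `patient_id`, `phase`, `brightness`, `contrast`, `homogeneity`,
#'   `refl_mean_cu`, `refl_range_cu`, `lambda_nm`. When profiles or gray
#'   images are kept they are attached as attributes `"profiles"` /
#'   `"gray_images"` (named `<patient>_<phase>`).
#' @export
analyze_cohort <- function(manifest, white = NULL, params = glcm_params(),
                           lambda_nm = 654, dark = NULL,
                           keep_profiles = FALSE, keep_gray = FALSE) {
  stopifnot(is.data.frame(manifest))
  white <- white %||% attr(manifest, "white")
  if (is.null(white)) {
    hs_stop("no white reference given (argument or manifest attribute)",
            "hs_validation_error")
  }
  if (!file.exists(white)) {
    hs_stop("white reference '%s' not readable", "hs_io_error", white)
  }
  white_cube <- read_envi(white)

  rows <- list()
  profiles <- list()
  grays <- list()
  for (i in seq_len(nrow(manifest))) {
    pid <- manifest$patient_id[i]
    region <- parse_roi(manifest$roi[i])
    for (phase in c("before", "after")) {
      path <- manifest[[phase]][i]
      if (!file.exists(path)) {
        hs_stop("patient %s: cube '%s' not readable", "hs_validation_error",
                pid, path)
      }
      cube <- calibrate(read_envi(path), white_cube, dark = dark)
      tm <- texture_metrics(cube, region, params)
      prof <- roi_profiles(cube, region)
      bm <- band_metrics(prof, lambda_nm)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, phase = phase,
        brightness = tm$brightness, contrast = tm$contrast,
        homogeneity = tm$homogeneity,
        refl_mean_cu = bm$mean_cu, refl_range_cu = bm$range_cu,
        lambda_nm = bm$lambda_nm, stringsAsFactors = FALSE)
      key <- sprintf("%s_%s", pid, phase)
      if (keep_profiles) profiles[[key]] <- prof
      if (keep_gray) grays[[key]] <- cube_to_gray(cube, region,
                                                  params$levels)
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  if (keep_profiles) attr(records, "profiles") <- profiles
  if (keep_gray) attr(records, "gray_images") <- grays
  records
}
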