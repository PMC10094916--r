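# Gray-level conversion and co-occurrence texture statistics.
#
# The texture model follows the classic Haralick setup: a quantized gray
# image, a normalized pair-frequency matrix p(i, j) for a fixed pixel offset,
# and the two statistics used to characterize hyperpigmented skin:
#   contrast     = sum_(i,j) (i - j)^2 p(i, j)
#   homogeneity  = sum_(i,j) p(i, j) / (1 + |i - j|)
# With the default offset (d = 1, theta = 0) a pair is a pixel and the pixel
# directly to its right.

#' Quantized gray-level image
#'
#' @param pixels integer matrix with values in `[0, levels - 1]`; gray level 0
#'   is black, `levels - 1` full scale.
#' @param levels number of gray levels G (>= 2); 256 for the 8-bit range used
#'   throughout the skin analysis.
#' @return An object of class `"gray_image"`.
#' @export
gray_image <- function(pixels, levels = 256L) {
  if (!is.matrix(pixels)) hs_stop("pixels must be a matrix", "hs_format_error")
  if (!is_count(levels) || levels < 2) {
    hs_stop("levels must be an integer >= 2", "hs_format_error")
  }
  if (length(pixels) < 2L) {
    hs_stop("image must contain at least two pixels", "hs_format_error")
  }
  if (anyNA(pixels) || any(pixels != round(pixels)) ||
      any(pixels < 0) || any(pixels > levels - 1)) {
    hs_stop("pixel values must be integers in [0, %d]", "hs_format_error",
            as.integer(levels) - 1L)
  }
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, levels = as.integer(levels)),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, %d levels, mean %.2f\n",
              nrow(x$pixels), ncol(x$pixels), x$levels, mean(x$pixels)))
  invisible(x)
}

#' GLCM parameters
#'
#' Offset definition: `theta_deg = 0` pairs each pixel with the pixel `d`
#' columns to its right; 90 with the pixel `d` rows above; 45 and 135 with
#' the upper-right / upper-left diagonal neighbours. The matrix is asymmetric
#' (ordered pairs) by default, matching the "neighbour directly to the right"
#' counting rule; `symmetric = TRUE` additionally counts each pair reversed.
#' For contrast and homogeneity - functions of `|i - j|` only - the choice
#' does not change the statistic.
#'
#' @param d pixel offset distance (>= 1).
#' @param theta_deg direction, one of 0, 45, 90, 135.
#' @param levels number of gray levels G.
#' @param symmetric count unordered pairs instead of ordered ones.
#' @return An object of class `"glcm_params"`.
#' @export
glcm_params <- function(d = 1L, theta_deg = 0, levels = 256L,
                        symmetric = FALSE) {
  if (!is_count(d) || d < 1) hs_stop("d must be an integer >= 1",
                                     "hs_format_error")
  if (!theta_deg %in% c(0, 45, 90, 135)) {
    hs_stop("theta_deg must be one of 0, 45, 90, 135", "hs_format_error")
  }
  if (!is_count(levels) || levels < 2) {
    hs_stop("levels must be an integer >= 2", "hs_format_error")
  }
  structure(list(d = as.integer(d), theta_deg = theta_deg,
                 levels = as.integer(levels), symmetric = isTRUE(symmetric)),
            class = "glcm_params")
}

# (row, col) displacement of the offset neighbour; rows grow downwards.
glcm_offset <- function(params) {
  d <- params$d
  switch(as.character(params$theta_deg),
         `0` = c(0L, d), `45` = c(-d, d), `90` = c(-d, 0L),
         `135` = c(-d, -d))
}

#' Convert a calibrated cube ROI to gray levels
#'
#' Per pixel, the band-mean reflectance ("total reflectance") is scaled to
#' the gray range: `gray = round_half_up((G - 1) * mean_band / scale_cu)`,
#' clipped to `[0, G - 1]`. Rounding is half-up so midpoints are
#' deterministic.
#'
#' @param cube calibrated [hypercube()].
#' @param region [roi()] or `NULL` for the full frame.
#' @param levels number of gray levels G (default 256).
#' @return A [gray_image()].
#' @export
cube_to_gray <- function(cube, region = NULL, levels = 256L) {
  stopifnot(inherits(cube, "hypercube"))
  if (!cube$calibrated) {
    hs_stop("cube must be calibrated before gray conversion", "hs_state_error")
  }
  tot <- total_reflectance(cube, region)
  g <- round_half_up((levels - 1) * tot / cube$scale_cu)
  g <- pmin(pmax(g, 0), levels - 1)
  gray_image(matrix(as.integer(g), nrow = nrow(tot)), levels)
}

#' Gray-level co-occurrence matrix
#'
#' Counts every ordered pixel pair `(p, q)` with `q` at the configured offset
#' from `p` and both inside the image, then normalizes the count matrix to
#' probabilities `p(i, j)` summing to one.
#'
#' @param img a [gray_image()] whose `levels` matches `params$levels`.
#' @param params a [glcm_params()].
#' @return An object of class `"cooccurrence_matrix"` with elements `p`
#'   (G x G probability matrix, `p[i + 1, j + 1] = p(i, j)`) and `params`.
#' @examples
#' img <- gray_image(rbind(c(0L, 0L), c(1L, 1L)), levels = 2)
#' glcm(img, glcm_params(levels = 2))$p
#' @export
glcm <- function(img, params = glcm_params(levels = img$levels)) {
  stopifnot(inherits(img, "gray_image"), inherits(params, "glcm_params"))
  if (params$levels != img$levels) {
    hs_stop("params declare %d levels but image has %d", "hs_format_error",
            params$levels, img$levels)
  }
  off <- glcm_offset(params)
  px <- img$pixels
  nr <- nrow(px); nc <- ncol(px)
  r0 <- max(1L, 1L - off[1L]); r1 <- min(nr, nr - off[1L])
  c0 <- max(1L, 1L - off[2L]); c1 <- min(nc, nc - off[2L])
  if (r0 > r1 || c0 > c1) {
    hs_stop("image too small for any (d = %d, theta = %g) pair",
            "hs_degenerate_input_error", params$d, params$theta_deg)
  }
  G <- img$levels
  i <- px[r0:r1, c0:c1, drop = FALSE]
  j <- px[(r0 + off[1L]):(r1 + off[1L]), (c0 + off[2L]):(c1 + off[2L]),
          drop = FALSE]
  counts <- tabulate(as.vector(i) * G + as.vector(j) + 1L, nbins = G * G)
  counts <- matrix(counts, nrow = G, ncol = G, byrow = TRUE)
  if (params$symmetric) counts <- counts + t(counts)
  structure(list(p = counts / sum(counts), params = params),
            class = "cooccurrence_matrix")
}

check_cooc <- function(m) {
  stopifnot(inherits(m, "cooccurrence_matrix"))
  if (abs(sum(m$p) - 1) > 1e-9 || any(m$p < 0)) {
    hs_stop("co-occurrence matrix is not normalized", "hs_format_error")
  }
}

#' GLCM contrast
#'
#' `sum_(i,j) (i - j)^2 p(i, j)`: zero for a perfectly uniform texture and
#' bounded above by `(G - 1)^2`. Large values mean adjacent pixels differ
#' strongly in gray level.
#'
#' @param m a `"cooccurrence_matrix"` from [glcm()].
#' @return Non-negative scalar.
#' @export
glcm_contrast <- function(m) {
  check_cooc(m)
  G <- nrow(m$p)
  lv <- 0:(G - 1L)
  sum(outer(lv, lv, `-`)^2 * m$p)
}

#' GLCM homogeneity
#'
#' `sum_(i,j) p(i, j) / (1 + |i - j|)`: equals 1 exactly when all pair mass
#' is diagonal (every neighbour pair equal) and decreases towards 0 as
#' neighbouring gray levels diverge. Inversely related to contrast.
#'
#' @inheritParams glcm_contrast
#' @return Scalar in `(0, 1]`.
#' @export
glcm_homogeneity <- function(m) {
  check_cooc(m)
  G <- nrow(m$p)
  lv <- 0:(G - 1L)
  sum(m$p / (1 + abs(outer(lv, lv, `-`))))
}

#' Mean gray level of an image
#'
#' @param img a [gray_image()].
#' @return Arithmetic mean of the pixel gray levels (0 .. G-1 scale).
#' @export
brightness <- function(img) {
  stopifnot(inherits(img, "gray_image"))
  mean(img$pixels)
}

#' Brightness, contrast and homogeneity of a cube ROI
#'
#' Composition of [cube_to_gray()] and [glcm()]: the three texture statistics
#' reported per skin ROI.
#'
#' @param cube calibrated [hypercube()].
#' @param region [roi()] or `NULL`.
#' @param params [glcm_params()]; its `levels` drives the gray conversion.
#' @return Named list with `brightness`, `contrast`, `homogeneity`.
#' @export
texture_metrics <- function(cube, region = NULL, params = glcm_params()) {
  img <- cube_to_gray(cube, region, params$levels)
  m <- glcm(img, params)
  list(brightness = brightness(img),
       contrast = glcm_contrast(m),
       homogeneity = glcm_homogeneity(m))
}
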