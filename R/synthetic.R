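# Synthetic skin textures with prescribed co-occurrence statistics.
#
# Design device: build each image row as a level sequence whose consecutive
# horizontal differences ("steps" e) are drawn from a symmetric integer
# distribution. Under the right-neighbour GLCM the pair (i, j) has j - i = e,
# so the texture statistics are plain moments of the step multiset:
#   contrast    = E[e^2]
#   homogeneity = E[1 / (1 + |e|)]
# Inverting those two equations for a three-level support {0, +-1, +-m2}
# gives a distribution hitting any feasible (contrast, homogeneity) pair, and
# laying the +e / -e steps down in adjacent pairs keeps every row inside a
# narrow corridor around the target brightness.

#' Symmetric integer step distribution
#'
#' @param support integer step values `e` (must come in `+e`/`-e` pairs,
#'   optionally with 0).
#' @param probs matching probabilities, non-negative, summing to 1, with
#'   `P(e) = P(-e)`.
#' @return An object of class `"step_distribution"`.
#' @export
step_distribution <- function(support, probs) {
  support <- as.integer(support)
  if (length(support) != length(probs) || anyDuplicated(support)) {
    hs_stop("support and probs must match, support unique", "hs_format_error")
  }
  if (any(probs < -1e-12) || abs(sum(probs) - 1) > 1e-9) {
    hs_stop("probs must be non-negative and sum to 1", "hs_format_error")
  }
  probs <- pmax(probs, 0)
  for (e in support[support != 0L]) {
    k <- match(-e, support)
    if (is.na(k) || abs(probs[match(e, support)] - probs[k]) > 1e-9) {
      hs_stop("distribution must be symmetric: P(%d) != P(%d)",
              "hs_format_error", e, -e)
    }
  }
  o <- order(support)
  structure(list(support = support[o], probs = probs[o]),
            class = "step_distribution")
}

#' Forward moments of a step distribution
#'
#' @param dist a [step_distribution()].
#' @return Named vector: `contrast = E[e^2]`,
#'   `homogeneity = E[1 / (1 + |e|)]`.
#' @export
step_moments <- function(dist) {
  stopifnot(inherits(dist, "step_distribution"))
  c(contrast = sum(dist$probs * dist$support^2),
    homogeneity = sum(dist$probs / (1 + abs(dist$support))))
}

#' Solve a step distribution for target contrast and homogeneity
#'
#' Finds a symmetric distribution on `{0, +-1, +-m2}` satisfying both moment
#' equations exactly: with combined probabilities `q1 = P(|e| = 1)` and
#' `q2 = P(|e| = m2)`,
#' `q1 + m2^2 q2 = contrast` and `q1 / 2 + q2 * m2 / (1 + m2) = 1 - homogeneity`
#' form a linear system solved for each candidate `m2 = 2, 3, ...` in turn;
#' the smallest `m2` giving probabilities inside `[0, 1]` wins, which makes
#' the solution deterministic. Degenerate targets (`contrast = 0` with
#' `homogeneity = 1`, or an exactly two-level texture) short-circuit.
#'
#' @param contrast_target target `E[e^2]` (>= 0).
#' @param homogeneity_target target `E[1/(1+|e|)]` in `(0, 1]`.
#' @param max_m2 largest outer support magnitude tried.
#' @return A [step_distribution()] with attribute `"m2"` (0 when unused).
#' @examples
#' d <- solve_step_distribution(5.86, 0.56)
#' step_moments(d)
#' @export
solve_step_distribution <- function(contrast_target, homogeneity_target,
                                    max_m2 = 128L) {
  ct <- contrast_target
  ht <- homogeneity_target
  if (!is.finite(ct) || ct < 0 || !is.finite(ht) || ht <= 0 || ht > 1) {
    hs_stop("need contrast >= 0 and homogeneity in (0, 1]",
            "hs_infeasibility_error")
  }
  tol <- 1e-9
  if (ct < tol) {
    if (abs(ht - 1) > tol) {
      hs_stop("contrast 0 forces homogeneity 1 (got %g)",
              "hs_infeasibility_error", ht)
    }
    return(structure(step_distribution(0L, 1), m2 = 0L))
  }
  if (abs(ht - 1) < tol) {
    hs_stop("homogeneity 1 forces contrast 0 (got %g)",
            "hs_infeasibility_error", ct)
  }
  # two-level support {0, +-1}: q1 = contrast, homogeneity = 1 - q1/2
  if (ct <= 1 + tol && abs(ht - (1 - ct / 2)) < 1e-9) {
    q1 <- min(ct, 1)
    return(structure(
      step_distribution(c(-1L, 0L, 1L), c(q1 / 2, 1 - q1, q1 / 2)),
      m2 = 0L))
  }
  rhs <- c(ct, 1 - ht)
  for (m2 in 2:max_m2) {
    A <- rbind(c(1, m2^2), c(0.5, m2 / (1 + m2)))
    q <- solve(A, rhs)
    q1 <- q[1L]; q2 <- q[2L]
    if (q1 >= -1e-12 && q2 >= -1e-12 && q1 + q2 <= 1 + 1e-12) {
      q1 <- max(q1, 0); q2 <- max(q2, 0)
      q0 <- max(1 - q1 - q2, 0)
      return(structure(
        step_distribution(c(-m2, -1L, 0L, 1L, m2),
                          c(q2 / 2, q1 / 2, q0, q1 / 2, q2 / 2)),
        m2 = as.integer(m2)))
    }
  }
  hs_stop("no feasible step distribution for contrast %g, homogeneity %g",
          "hs_infeasibility_error", ct, ht)
}

# Integer step-count plan for a whole image: T pairs total, magnitudes taken
# from the distribution plus {1, 2} as fine-tuning channels. Counts are even
# (steps are laid down in +m/-m blocks) and chosen so the realized multiset
# moments match the distribution's moments to O(1/T).
plan_step_counts <- function(dist, n_pairs) {
  mom <- step_moments(dist)
  C <- mom[["contrast"]]
  H <- mom[["homogeneity"]]
  mags <- sort(unique(abs(dist$support[dist$support != 0L])))
  qs <- vapply(mags, function(m) sum(dist$probs[abs(dist$support) == m]),
               numeric(1L))

  counts <- integer(0)
  big <- mags[mags > 2L]
  for (m in big) {
    counts[as.character(m)] <- 2L * round(qs[mags == m] * n_pairs / 2)
  }
  rem_c <- C * n_pairs - sum(as.integer(names(counts))^2 * counts)
  rem_h <- (1 - H) * n_pairs -
    sum(counts * vapply(as.integer(names(counts)),
                        function(m) m / (1 + m), numeric(1L)))
  # real-valued solution over magnitudes {1, 2}:
  #   n1 + 4 n2 = rem_c ;  n1/2 + (2/3) n2 = rem_h
  n2 <- 3 * (rem_c - 2 * rem_h) / 8
  n1 <- rem_c - 4 * n2
  if (n2 < 0) { n2 <- 0; n1 <- rem_c }
  if (n1 < 0) { n1 <- 0; n2 <- rem_c / 4 }
  N2 <- max(0L, 2L * as.integer(round(n2 / 2)))
  N1 <- max(0L, 2L * as.integer(round((rem_c - 4 * N2) / 2)))
  if (N1 > 0L) counts[["1"]] <- N1
  if (N2 > 0L) counts[["2"]] <- N2
  counts <- counts[counts > 0L]
  if (sum(counts) > n_pairs) {
    hs_stop("step plan exceeds available pixel pairs", "hs_parameter_error")
  }
  counts
}

#' Synthesize a gray image with prescribed brightness and step statistics
#'
#' Builds a `rows x cols` gray image whose horizontal-difference multiset
#' realizes the step distribution (rounded to the available pairs) and whose
#' mean gray level sits at the brightness target. Steps are laid down as
#' adjacent `+m`/`-m` blocks with alternating orientation, so every row stays
#' inside `brightness +- max(|e|)` and block deviations cancel; the seed only
#' shuffles where blocks fall inside each row, so brightness, contrast and
#' homogeneity are identical across seeds.
#'
#' @param brightness_target mean gray level (0 .. levels-1 scale).
#' @param dist a [step_distribution()], e.g. from [solve_step_distribution()].
#' @param shape `c(rows, cols)`; `cols >= 2`.
#' @param seed integer seed for the within-row shuffle.
#' @param levels gray range G (default 256).
#' @return A [gray_image()].
#' @export
pattern_synthesize <- function(brightness_target, dist, shape, seed = 1L,
                               levels = 256L) {
  stopifnot(inherits(dist, "step_distribution"))
  rows <- as.integer(shape[1L]); cols <- as.integer(shape[2L])
  if (rows < 1L || cols < 2L) {
    hs_stop("shape must be at least 1 x 2", "hs_parameter_error")
  }
  if (brightness_target < 0 || brightness_target > levels - 1) {
    hs_stop("brightness target outside [0, %d]", "hs_parameter_error",
            levels - 1L)
  }
  b0 <- as.integer(round_half_up(brightness_target))
  n_pairs <- rows * (cols - 1L)
  counts <- plan_step_counts(dist, n_pairs)
  mags <- as.integer(names(counts))
  if (length(mags)) {
    if (b0 + max(mags) > levels - 1L || b0 - max(mags) < 0L) {
      hs_stop(paste("brightness corridor [%d, %d] exits the gray range;",
                    "recenter brightness or reduce the largest step"),
              "hs_parameter_error", b0 - max(mags), b0 + max(mags))
    }
  }

  # one block = two adjacent steps (+m, -m) or (-m, +m); orientations
  # alternate within each magnitude so level deviations cancel
  block_mag <- rep(mags, counts %/% 2L)
  block_orient <- unlist(lapply(counts %/% 2L, function(k) {
    rep_len(c(1L, -1L), k)
  }), use.names = FALSE)
  B <- length(block_mag)
  cap <- rows * ((cols - 1L) %/% 2L)
  if (B > cap) {
    hs_stop("too many step blocks (%d) for a %d x %d image",
            "hs_parameter_error", B, rows, cols)
  }
  row_of <- if (B) (seq_len(B) - 1L) %% rows + 1L else integer(0)

  px <- matrix(0L, nrow = rows, ncol = cols)
  with_seed(seed, {
    for (r in seq_len(rows)) {
      bi <- which(row_of == r)
      nz <- (cols - 1L) - 2L * length(bi)
      items <- c(as.list(bi), as.list(rep(NA_integer_, nz)))
      if (length(items) > 1L) items <- items[sample.int(length(items))]
      steps <- unlist(lapply(items, function(it) {
        if (is.na(it[[1L]])) 0L else
          c(block_orient[it] * block_mag[it], -block_orient[it] * block_mag[it])
      }), use.names = FALSE)
      lv <- b0 + cumsum(c(0L, steps))
      px[r, ] <- lv
    }
  })
  if (any(px < 0L) || any(px > levels - 1L)) {
    hs_stop("synthesized levels exited the gray range", "hs_parameter_error")
  }
  gray_image(px, levels)
}

#' Expand a gray image into a hyperspectral reflectance cube
#'
#' Every pixel receives the same smooth skin-like spectral shape scaled
#' linearly by its gray level - a melanin-like model in which darker pixels
#' (more pigment) reflect less at every wavelength. The shape is a sigmoidal
#' rise through the visible range plus a mean-neutral Gaussian band at the
#' analysis wavelength whose amplitude is solved so that the ROI-mean
#' reflectance at the band nearest `lambda_nm` equals `refl_mean_target`
#' exactly; because the band term is mean-neutral across bands, the band-mean
#' of each pixel stays `gray * scale_cu / (levels - 1)` and
#' [cube_to_gray()] recovers the input image exactly.
#'
#' @param img a [gray_image()].
#' @param refl_mean_target ROI-mean reflectance (c.u.) wanted at the analysis
#'   band; must lie in `[0, scale_cu]`.
#' @param wavelengths_nm band grid.
#' @param lambda_nm analysis wavelength (default 654).
#' @param scale_cu counts-units scale (default 1023).
#' @param noise_sd additive Gaussian noise SD in c.u. (default 0 for
#'   moment-exact cubes).
#' @param seed RNG seed, used only when `noise_sd > 0`.
#' @return A calibrated [hypercube()].
#' @export
gray_to_cube <- function(img, refl_mean_target, wavelengths_nm,
                         lambda_nm = 654, scale_cu = 1023, noise_sd = 0,
                         seed = 1L) {
  stopifnot(inherits(img, "gray_image"))
  if (!is.finite(refl_mean_target) || refl_mean_target < 0 ||
      refl_mean_target > scale_cu) {
    hs_stop("reflectance target outside [0, %g]", "hs_parameter_error",
            scale_cu)
  }
  w <- as.numeric(wavelengths_nm)
  g <- img$pixels
  G <- img$levels
  mg <- mean(g)
  if (mg == 0) {
    hs_stop("cannot hit a reflectance target on an all-black image",
            "hs_parameter_error")
  }

  # base shape: melanin/haemoglobin-dark blue-green, bright red/NIR
  s0 <- 0.35 + 0.65 * stats::plogis((w - 600) / 45)
  mean_s0 <- mean(s0)
  idx <- band_index(w, lambda_nm)
  rho <- refl_mean_target * (G - 1) / (scale_cu * mg)
  bump <- exp(-((w - lambda_nm) / 30)^2 / 2)
  bump0 <- bump - mean(bump)       # mean-neutral: leaves band-means alone
  beta <- (rho * mean_s0 - s0[idx]) / bump0[idx]
  s <- s0 + beta * bump0
  if (any(s <= 0)) {
    hs_stop("reflectance target %g c.u. infeasible for mean gray %.1f",
            "hs_parameter_error", refl_mean_target, mg)
  }
  factor <- (scale_cu / (G - 1)) * s / mean_s0
  data <- array(outer(as.vector(g), factor), dim = c(dim(g), length(w)))
  if (noise_sd > 0) {
    noise <- with_seed(seed, stats::rnorm(length(data), 0, noise_sd))
    data <- data + array(noise, dim = dim(data))
    data[data < 0] <- 0
  }
  hypercube(data, w, calibrated = TRUE, scale_cu = scale_cu)
}
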