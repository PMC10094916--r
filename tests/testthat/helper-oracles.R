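# Independent brute-force oracles the fast implementations are tested
# against. Deliberately naive: double loops and literal enumeration.

# GLCM by looping over every pixel pair at the (d, theta) offset.
oracle_glcm <- function(px, G, d = 1L, theta = 0) {
  off <- switch(as.character(theta),
                `0` = c(0L, d), `45` = c(-d, d), `90` = c(-d, 0L),
                `135` = c(-d, -d))
  counts <- matrix(0, G, G)
  for (r in seq_len(nrow(px))) {
    for (c in seq_len(ncol(px))) {
      r2 <- r + off[1L]; c2 <- c + off[2L]
      if (r2 >= 1 && r2 <= nrow(px) && c2 >= 1 && c2 <= ncol(px)) {
        i <- px[r, c]; j <- px[r2, c2]
        counts[i + 1L, j + 1L] <- counts[i + 1L, j + 1L] + 1
      }
    }
  }
  counts / sum(counts)
}

oracle_contrast <- function(p) {
  G <- nrow(p); out <- 0
  for (i in 0:(G - 1L)) for (j in 0:(G - 1L)) {
    out <- out + (i - j)^2 * p[i + 1L, j + 1L]
  }
  out
}

oracle_homogeneity <- function(p) {
  G <- nrow(p); out <- 0
  for (i in 0:(G - 1L)) for (j in 0:(G - 1L)) {
    out <- out + p[i + 1L, j + 1L] / (1 + abs(i - j))
  }
  out
}

# Exact two-sided signed-rank p by literally enumerating all 2^m sign
# assignments over the tied-average ranks (m <= ~12).
oracle_wilcoxon_p <- function(before, after) {
  d <- after - before
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  W_all <- vapply(0:(2^m - 1), function(mask) {
    signs <- bitwAnd(mask, 2^(0:(m - 1))) > 0
    sum(r[signs])
  }, numeric(1L))
  lower <- mean(W_all <= W_obs + 1e-9)
  upper <- mean(W_all >= W_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# Small random gray image.
random_gray <- function(nr, nc, G) {
  gray_image(matrix(sample.int(G, nr * nc, replace = TRUE) - 1L, nr, nc), G)
}

# A tiny calibrated cube with chosen per-pixel flat spectra.
flat_cube <- function(level_matrix, nbands = 5L, scale_cu = 1023) {
  w <- 500 + (seq_len(nbands) - 1L) * 10
  data <- array(rep(level_matrix, nbands),
                dim = c(nrow(level_matrix), ncol(level_matrix), nbands))
  hypercube(data, w, calibrated = TRUE, scale_cu = scale_cu)
}
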