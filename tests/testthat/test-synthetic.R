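# Step-distribution inversion, texture synthesis, cube expansion, presets.

test_that("solve_step_distribution handles the degenerate corners", {
  d0 <- solve_step_distribution(0, 1)
  expect_equal(step_moments(d0), c(contrast = 0, homogeneity = 1))
  expect_equal(d0$support, 0L)

  # contrast 1 at homogeneity 0.5 is forced onto {-1, +1}
  d1 <- solve_step_distribution(1, 0.5)
  expect_equal(sort(d1$support[d1$probs > 1e-12]), c(-1L, 1L))
  expect_equal(sum(d1$probs[abs(d1$support) == 1]), 1)

  expect_error(solve_step_distribution(0, 0.5),
               class = "hs_infeasibility_error")
  expect_error(solve_step_distribution(3, 1),
               class = "hs_infeasibility_error")
  # jointly unreachable pair: high contrast with very low homogeneity
  expect_error(solve_step_distribution(6, 0.2),
               class = "hs_infeasibility_error")
})

test_that("the study-condition pair (5.86, 0.56) solves on a three-level
           support and forward evaluation recovers it exactly", {
  d <- solve_step_distribution(5.86, 0.56)
  # hand-derived: smallest feasible outer magnitude is m2 = 4, where the
  # linear system q1 + 16 q2 = 5.86, q1/2 + (4/5) q2 = 0.44 gives
  # q2 = 4.98/14.4, q1 = 0.88 - 1.6 q2
  expect_equal(attr(d, "m2"), 4L)
  q2 <- 4.98 / 14.4
  q1 <- 0.88 - 1.6 * q2
  expect_equal(sum(d$probs[abs(d$support) == 4]), q2, tolerance = 1e-12)
  expect_equal(sum(d$probs[abs(d$support) == 1]), q1, tolerance = 1e-12)
  expect_equal(d$probs[d$support == 0], 1 - q1 - q2, tolerance = 1e-12)
  mom <- step_moments(d)
  expect_equal(mom[["contrast"]], 5.86, tolerance = 1e-9)
  expect_equal(mom[["homogeneity"]], 0.56, tolerance = 1e-9)
})

test_that("inversion is exact across the feasible plane", {
  # sample feasible targets by evaluating random distributions forward
  set.seed(17)
  for (k in 1:300) {
    m2 <- sample(2:12, 1)
    q <- runif(3); q <- q / sum(q)
    dist <- step_distribution(c(-m2, -1L, 0L, 1L, m2),
                              c(q[3] / 2, q[2] / 2, q[1], q[2] / 2, q[3] / 2))
    mom <- step_moments(dist)
    solved <- solve_step_distribution(mom[["contrast"]], mom[["homogeneity"]])
    back <- step_moments(solved)
    expect_equal(back[["contrast"]], mom[["contrast"]], tolerance = 1e-9)
    expect_equal(back[["homogeneity"]], mom[["homogeneity"]], tolerance = 1e-9)
  }
})

test_that("synthesized patterns hit brightness and GLCM targets", {
  # degenerate distribution: constant image
  flat <- pattern_synthesize(143, solve_step_distribution(0, 1), c(8, 8))
  expect_true(all(flat$pixels == 143L))
  m <- glcm(flat, glcm_params())
  expect_equal(glcm_contrast(m), 0)
  expect_equal(glcm_homogeneity(m), 1)

  cases <- list(c(5.86, 0.56), c(5.21, 0.64), c(2.5, 0.75), c(7.8, 0.45))
  for (cs in cases) {
    d <- solve_step_distribution(cs[1], cs[2])
    img <- pattern_synthesize(143.33, d, c(64, 64), seed = 3)
    m <- glcm(img, glcm_params())
    expect_lt(abs(brightness(img) - 143.33), 0.5)
    expect_lt(abs(glcm_contrast(m) - cs[1]) / cs[1], 0.02)
    expect_lt(abs(glcm_homogeneity(m) - cs[2]), 0.01)
  }
})

test_that("different seeds change the arrangement but not the statistics", {
  d <- solve_step_distribution(5.86, 0.56)
  a <- pattern_synthesize(140, d, c(32, 32), seed = 1)
  b <- pattern_synthesize(140, d, c(32, 32), seed = 2)
  expect_false(identical(a$pixels, b$pixels))
  ma <- glcm(a, glcm_params()); mb <- glcm(b, glcm_params())
  expect_equal(brightness(a), brightness(b))
  expect_equal(glcm_contrast(ma), glcm_contrast(mb))
  expect_equal(glcm_homogeneity(ma), glcm_homogeneity(mb))
})

test_that("brightness targets near the gray bounds are rejected, not folded", {
  d <- solve_step_distribution(5.86, 0.56)   # needs a +-4 corridor
  expect_error(pattern_synthesize(2, d, c(16, 16)),
               class = "hs_parameter_error")
  expect_error(pattern_synthesize(254, d, c(16, 16)),
               class = "hs_parameter_error")
})

test_that("gray_to_cube hits the band target exactly and round-trips", {
  w <- 400 + (0:203) * 2.941
  d <- solve_step_distribution(5.5, 0.6)
  img <- pattern_synthesize(150, d, c(32, 32), seed = 5)
  cube <- gray_to_cube(img, 900, w)

  # ROI-mean reflectance at the 654 nm band equals the target
  bm <- band_metrics(roi_profiles(cube), 654)
  expect_equal(bm$mean_cu, 900, tolerance = 1e-9)
  # round trip through gray conversion recovers the image exactly
  expect_identical(cube_to_gray(cube)$pixels, img$pixels)

  # constant image: identical spectra everywhere
  const <- gray_image(matrix(120L, 8, 8))
  cc <- gray_to_cube(const, 854, w)
  expect_equal(band_metrics(roi_profiles(cc), 654)$mean_cu, 854)
  expect_equal(band_metrics(roi_profiles(cc), 654)$range_cu, 0)

  # monotone melanin-like model: a brighter pixel's spectrum dominates a
  # darker pixel's pointwise, at every band
  set.seed(12)
  img2 <- random_gray(6, 6, 256)
  cube2 <- gray_to_cube(img2, 700, w)
  g <- as.vector(img2$pixels)
  spectra <- matrix(cube2$data, nrow = length(g))
  o <- order(g)
  expect_true(all(diff(spectra[o, , drop = FALSE]) >= -1e-9))

  expect_error(gray_to_cube(img, 2000, w), class = "hs_parameter_error")
})

test_that("the packaged paper-cohort preset satisfies its design constraints", {
  preset <- paper_cohort_preset()
  expect_equal(nrow(preset$patients), 12L)
  s <- summarize_targets(preset)$summary
  pick <- function(met, col) s[s$metric == met, col]
  # cohort means and SDs to two decimals
  expect_equal(round(pick("brightness", "mean_before"), 2), 143.33)
  expect_equal(round(pick("brightness", "sd_before"), 2), 23.75)
  expect_equal(round(pick("brightness", "mean_after"), 2), 157.67)
  expect_equal(round(pick("brightness", "sd_after"), 2), 19.89)
  expect_equal(round(pick("contrast", "mean_before"), 2), 5.86)
  expect_equal(round(pick("contrast", "sd_before"), 2), 1.09)
  expect_equal(round(pick("contrast", "mean_after"), 2), 5.21)
  expect_equal(round(pick("contrast", "sd_after"), 2), 1.06)
  expect_equal(round(pick("homogeneity", "mean_before"), 2), 0.56)
  expect_equal(round(pick("homogeneity", "sd_before"), 2), 0.16)
  expect_equal(round(pick("homogeneity", "mean_after"), 2), 0.64)
  expect_equal(round(pick("homogeneity", "sd_after"), 2), 0.13)
  # direction counts and medians
  expect_equal(pick("brightness", "n_increase"), 9)
  expect_equal(pick("contrast", "n_decrease"), 10)
  expect_equal(pick("homogeneity", "n_increase"), 8)
  expect_equal(pick("brightness", "median_diff"), 15.5)
  expect_equal(pick("refl_mean_cu", "median_before"), 854)
  expect_equal(pick("refl_mean_cu", "median_after"), 932)

  # negating all paired differences flips every direction count
  p2 <- preset
  swap <- function(df) {
    for (m in c("brightness", "contrast", "homogeneity", "refl654")) {
      b <- df[[paste0(m, "_b")]]
      df[[paste0(m, "_b")]] <- df[[paste0(m, "_a")]]
      df[[paste0(m, "_a")]] <- b
    }
    df
  }
  p2$patients <- swap(p2$patients)
  s2 <- summarize_targets(p2)$summary
  expect_equal(s2$n_increase, s$n_decrease)
  expect_equal(s2$n_decrease, s$n_increase)
})

test_that("presets round-trip through their text format", {
  preset <- paper_cohort_preset()
  td <- withr::local_tempdir()
  path <- file.path(td, "preset.tsv")
  write_preset(preset, path)
  back <- read_preset(path)
  expect_equal(back$patients, preset$patients)
  expect_equal(back$seed, preset$seed)
  expect_equal(back$shape, preset$shape)
  expect_equal(back$name, preset$name)
  expect_error(read_preset(file.path(td, "nope.tsv")),
               class = "hs_config_error")
})

test_that("cohort builds are deterministic and analyzable end-to-end", {
  # a 2-patient slice keeps this quick; the full cohort runs in acceptance
  preset <- paper_cohort_preset(shape = c(32L, 32L, 204L))
  preset$patients <- preset$patients[1:2, ]
  td1 <- withr::local_tempdir(); td2 <- withr::local_tempdir()
  man1 <- build_cohort(preset, td1)
  man2 <- build_cohort(preset, td2)
  # bit-identical data files across builds
  for (f in setdiff(list.files(td1), "manifest.tsv")) {
    expect_identical(readBin(file.path(td1, f), "raw", 1e7),
                     readBin(file.path(td2, f), "raw", 1e7))
  }
  rec <- analyze_cohort(man1)
  expect_equal(nrow(rec), 4L)
  p <- preset$patients
  for (i in 1:2) {
    for (ph in c("before", "after")) {
      suf <- if (ph == "before") "_b" else "_a"
      row <- rec[rec$patient_id == p$patient_id[i] & rec$phase == ph, ]
      expect_lt(abs(row$brightness - p[[paste0("brightness", suf)]][i]), 0.5)
      expect_lt(abs(row$contrast - p[[paste0("contrast", suf)]][i]) /
                  p[[paste0("contrast", suf)]][i], 0.02)
      expect_lt(abs(row$homogeneity - p[[paste0("homogeneity", suf)]][i]),
                0.01)
      expect_lt(abs(row$refl_mean_cu - p[[paste0("refl654", suf)]][i]), 1)
    }
  }
})

test_that("noisy cubes still recover the gray pattern approximately", {
  w <- 400 + (0:203) * 2.941
  d <- solve_step_distribution(5.86, 0.56)
  img <- pattern_synthesize(143, d, c(32, 32), seed = 9)
  cube <- gray_to_cube(img, 854, w, noise_sd = 2, seed = 9)
  back <- cube_to_gray(cube)
  expect_lte(max(abs(back$pixels - img$pixels)), 2)
  expect_lt(abs(band_metrics(roi_profiles(cube), 654)$mean_cu - 854), 1)
})
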