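# Paired before/after cohort statistics: means, medians, quartiles,
# direction counts, normality checks and signed-rank tests per metric.

COHORT_METRICS <- c("brightness", "contrast", "homogeneity",
                    "refl_mean_cu", "refl_range_cu")

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over [stats::shapiro.test()] enforcing the test's 3..5000
#' sample-size domain; used to decide whether cohort metrics warrant a
#' nonparametric paired comparison.
#'
#' @param values numeric vector, 3 to 5000 observations.
#' @return Two-sided p-value for the null of normality.
#' @export
shapiro_wilk <- function(values) {
  n <- length(values)
  if (n < 3L || n > 5000L) {
    hs_stop("Shapiro-Wilk requires 3 <= n <= 5000 (got %d)",
            "hs_domain_error", n)
  }
  stats::shapiro.test(values)$p.value
}

#' Summarize a paired before/after cohort
#'
#' For every metric present in `records` this computes: mean and sample SD
#' (n - 1 denominator) per phase, medians per phase, the median and the
#' quartiles of the paired after-minus-before differences (linear
#' interpolation between order statistics, the spreadsheet quantile
#' convention), direction counts (an "increase" is a strictly positive
#' difference), Shapiro-Wilk p per phase, and a paired two-sided Wilcoxon
#' signed-rank p (`NA` with a warning when every difference is zero).
#' No multiple-testing correction is applied.
#'
#' @param records data.frame with columns `patient_id`,
#'   `phase` (`"before"`/`"after"`) and one column per metric, e.g. as
#'   returned by [analyze_cohort()].
#' @return An object of class `"cohort_summary"`: list with `summary` (one
#'   row per metric), `n` (patients) and `diffs` (named list of paired
#'   difference vectors).
#' @export
summarize_cohort <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("patient_id", "phase") %in% names(records)))
  metrics <- intersect(COHORT_METRICS, names(records))
  if (!length(metrics)) hs_stop("no metric columns found", "hs_format_error")

  before <- records[records$phase == "before", , drop = FALSE]
  after <- records[records$phase == "after", , drop = FALSE]
  ids <- sort(unique(records$patient_id))
  n <- length(ids)
  if (n < 2L) {
    hs_stop("cohort summaries need at least 2 patients (got %d)",
            "hs_insufficient_data_error", n)
  }
  missing_b <- setdiff(ids, before$patient_id)
  missing_a <- setdiff(ids, after$patient_id)
  if (length(missing_b) || length(missing_a)) {
    hs_stop("patient(s) missing a phase: %s", "hs_validation_error",
            paste(unique(c(missing_b, missing_a)), collapse = ", "))
  }
  before <- before[match(ids, before$patient_id), , drop = FALSE]
  after <- after[match(ids, after$patient_id), , drop = FALSE]

  rows <- list()
  diffs <- list()
  for (met in metrics) {
    b <- before[[met]]
    a <- after[[met]]
    dd <- a - b
    diffs[[met]] <- stats::setNames(dd, ids)
    q <- stats::quantile(dd, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    wil <- tryCatch(wilcoxon_signed_rank(b, a),
                    hs_degenerate_data_error = function(e) {
                      warning(sprintf("metric '%s': %s", met,
                                      conditionMessage(e)), call. = FALSE)
                      list(W = NA_real_, p = NA_real_)
                    })
    rows[[met]] <- data.frame(
      metric = met,
      mean_before = mean(b), sd_before = stats::sd(b),
      mean_after = mean(a), sd_after = stats::sd(a),
      median_before = stats::median(b), median_after = stats::median(a),
      median_diff = q[2L], q1_diff = q[1L], q3_diff = q[3L],
      n_increase = sum(dd > 0), n_decrease = sum(dd < 0),
      n_tie = sum(dd == 0),
      prop_increase = mean(dd > 0), prop_decrease = mean(dd < 0),
      wilcoxon_W = wil$W, wilcoxon_p = wil$p,
      shapiro_p_before = shapiro_wilk(b), shapiro_p_after = shapiro_wilk(a),
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  structure(list(summary = summary, n = n, diffs = diffs),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d patients\n", x$n))
  s <- x$summary
  for (k in seq_len(nrow(s))) {
    cat(sprintf(
      "  %-13s %6.2f +/- %5.2f -> %6.2f +/- %5.2f  (%d up / %d down / %d tie, p = %.4g)\n",
      s$metric[k], s$mean_before[k], s$sd_before[k], s$mean_after[k],
      s$sd_after[k], s$n_increase[k], s$n_decrease[k], s$n_tie[k],
      s$wilcoxon_p[k]))
  }
  invisible(x)
}

#' Write cohort report tables and figures
#'
#' Emits, under `out_dir`: `table1_style.tsv` (per-phase mean +/- SD of
#' brightness, contrast and homogeneity), `cohort_summary.tsv` (the full
#' numeric summary), `patient_metrics.tsv` (one row per patient and phase),
#' `narrative_stats.tsv` (key-value file of medians, quartile shifts,
#' direction percentages and p-values), and - when profiles or gray images
#' are supplied - per-patient reflectance line charts and 3-D brightness
#' surfaces as PNG files. Tables are written deterministically, so repeated
#' calls on the same summary are byte-stable. With fewer than two patients
#' the per-patient table is still written, with a warning that cohort
#' statistics are omitted.
#'
#' @param records per-patient metric table (see [summarize_cohort()]).
#' @param out_dir output directory, created if needed.
#' @param summary optional precomputed [summarize_cohort()] result.
#' @param profiles optional named list of `"spectral_profile"` objects
#'   (names like `"p01_before"`) to plot.
#' @param gray_images optional named list of [gray_image()] objects for 3-D
#'   brightness surfaces.
#' @return Invisibly, the output directory.
#' @export
write_report <- function(records, out_dir, summary = NULL, profiles = NULL,
                         gray_images = NULL) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok) hs_stop("cannot create '%s'", "hs_io_error", out_dir)

  write_tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_tsv(records, "patient_metrics.tsv")

  n <- length(unique(records$patient_id))
  if (is.null(summary) && n >= 2L) summary <- summarize_cohort(records)
  if (is.null(summary)) {
    warning("single-patient cohort: statistical tables omitted",
            call. = FALSE)
  } else {
    s <- summary$summary
    fmt <- function(mu, sd) sprintf("%.2f ± %.2f", mu, sd)
    pick <- function(met, col) s[s$metric == met, col]
    t1 <- data.frame(
      phase = c("before", "after"),
      brightness = c(fmt(pick("brightness", "mean_before"),
                         pick("brightness", "sd_before")),
                     fmt(pick("brightness", "mean_after"),
                         pick("brightness", "sd_after"))),
      contrast = c(fmt(pick("contrast", "mean_before"),
                       pick("contrast", "sd_before")),
                   fmt(pick("contrast", "mean_after"),
                       pick("contrast", "sd_after"))),
      homogeneity = c(fmt(pick("homogeneity", "mean_before"),
                          pick("homogeneity", "sd_before")),
                      fmt(pick("homogeneity", "mean_after"),
                          pick("homogeneity", "sd_after"))),
      stringsAsFactors = FALSE)
    write_tsv(t1, "table1_style.tsv")
    write_tsv(s, "cohort_summary.tsv")

    kv <- do.call(rbind, lapply(seq_len(nrow(s)), function(k) {
      met <- s$metric[k]
      data.frame(
        key = paste0(met, c("_median_diff", "_q1_diff", "_q3_diff",
                            "_pct_increase", "_pct_decrease", "_wilcoxon_p")),
        value = c(s$median_diff[k], s$q1_diff[k], s$q3_diff[k],
                  round(100 * s$prop_increase[k]),
                  round(100 * s$prop_decrease[k]), s$wilcoxon_p[k]),
        stringsAsFactors = FALSE)
    }))
    kv <- rbind(kv, data.frame(key = "multiple_testing_correction",
                               value = "none", stringsAsFactors = FALSE))
    write_tsv(kv, "narrative_stats.tsv")
  }

  if (!is.null(profiles)) {
    for (nm in names(profiles)) {
      pr <- profiles[[nm]]
      grDevices::png(file.path(out_dir, sprintf("profile_%s.png", nm)),
                     width = 640, height = 480)
      graphics::matplot(pr$wavelengths_nm,
                        cbind(pr$max_cu, pr$mean_cu, pr$min_cu),
                        type = "l", lty = 1, lwd = 2,
                        col = c("blue", "red", "darkgreen"),
                        xlab = "wavelength [nm]", ylab = "reflectance [c.u.]",
                        main = nm)
      graphics::legend("bottomright", c("maximum", "average", "minimum"),
                       col = c("blue", "red", "darkgreen"), lty = 1, lwd = 2)
      grDevices::dev.off()
    }
  }
  if (!is.null(gray_images)) {
    for (nm in names(gray_images)) {
      img <- gray_images[[nm]]
      grDevices::png(file.path(out_dir, sprintf("surface_%s.png", nm)),
                     width = 640, height = 480)
      graphics::persp(seq_len(nrow(img$pixels)), seq_len(ncol(img$pixels)),
                      img$pixels, theta = 35, phi = 30,
                      xlab = "pixels", ylab = "pixels", zlab = "brightness",
                      main = nm, col = "lightblue", shade = 0.5)
      grDevices::dev.off()
    }
  }
  invisible(out_dir)
}
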