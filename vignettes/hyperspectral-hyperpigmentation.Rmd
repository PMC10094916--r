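---
title: "Quantifying skin hyperpigmentation change from hyperspectral cubes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying skin hyperpigmentation change from hyperspectral cubes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperskin)
```

## The measurement problem

Depigmenting treatments (here the motivating case is a 3% kojic-acid series
applied to post-acne facial hyperpigmentation) are usually judged by eye or by
RGB photography. A push-broom hyperspectral camera instead records, for every
pixel of a skin patch, a full reflectance spectrum across ~200 contiguous
bands in 400–1000 nm. Because melanin absorbs strongly through the visible
range, less pigment means more reflected light; and because hyperpigmented
skin is *spatially* irregular, a successful treatment should also make the
patch more uniform. `hyperskin` turns a pair of cubes per patient — before and
after a treatment series — into a small set of quantitative endpoints and a
paired cohort analysis.

The pipeline has four stages, each an exported function family:

1. **Calibration** (`read_envi()`, `calibrate()`). Raw counts are divided,
   band by band, by the spatial mean of a white-reference cube:
   \[ R(\lambda) = S \cdot \frac{\mathrm{raw}(\lambda) - \mathrm{dark}(\lambda)}
   {\mathrm{white}(\lambda) - \mathrm{dark}(\lambda)}, \]
   with scale \(S = 1023\) c.u. ("counts-units", a 10-bit-like convention
   under which 1023 c.u. = 100% reflectance of the reference panel). The dark
   term defaults to zero — most portable protocols skip a dark capture — and
   values driven below zero by noise clip to zero rather than erroring.
2. **Texture** (`cube_to_gray()`, `glcm()`). Each ROI pixel's band-mean
   reflectance is quantized to \(G = 256\) gray levels; the gray-level
   co-occurrence matrix \(p(i,j)\) counts ordered (pixel, right-neighbour)
   pairs at offset \(d = 1\), \(\theta = 0^\circ\); and three statistics
   summarize the patch: brightness \(= \overline{g}\), contrast
   \(= \sum_{i,j} (i-j)^2\, p(i,j)\), homogeneity
   \(= \sum_{i,j} p(i,j) / (1 + |i-j|)\).
3. **Spectral profiling** (`roi_profiles()`, `band_metrics()`). The spectra
   of the brightest and darkest ROI pixels (by band-mean reflectance) and the
   per-band mean give the maximum / average / minimum profile curves; the
   mean and the max−min range are read off at the band nearest the analysis
   wavelength, 654 nm by default.
4. **Cohort statistics** (`summarize_cohort()`, `wilcoxon_signed_rank()`).
   Per metric: mean ± SD per phase, medians, quartiles of the paired
   differences, direction counts, Shapiro–Wilk normality checks, and an
   exact two-sided Wilcoxon signed-rank test on the paired differences.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `scale_cu` | 1023 | c.u. | counts-units scale; 1023 ≡ 100% reflectance, matching the 10-bit magnitude range of the reported reflectances (hundreds of c.u.) |
| `levels` (G) | 256 | gray levels | full 8-bit gray range; cohort brightness values in the 140–160 range imply a 0–255 scale |
| `d`, `theta_deg` | 1, 0° | px, deg | immediate right-neighbour pairs — the finest, direction-specific texture probe |
| `symmetric` | `FALSE` | — | ordered pairs ("the pixel directly to the right"); symmetric counting is available but changes neither contrast nor homogeneity, which depend on \(|i-j|\) only |
| `lambda_nm` | 654 | nm | analysis band for melanin; an operator-chosen empirical wavelength, not a physical constant — melanin absorption is monotone across the range, so the exact choice is a convention the package treats as configuration |
| quantiles | type 7 | — | linear interpolation between order statistics, the spreadsheet convention, stated explicitly because quartile values are reported |

Two conversion details are deliberately pinned down because they are visible
in tests: gray conversion rounds half-up (`floor(x + 0.5)`), so exact
midpoints such as \(255 \cdot 0.5 = 127.5\) map deterministically to 128; and
`band_index()` resolves equidistant wavelength ties to the lower band.

## The exact signed-rank test

At \(n = 12\) with quantized metrics, ties among \(|d_i|\) are routine, and
`stats::wilcox.test()` then refuses an exact p-value. `wilcoxon_signed_rank()`
therefore computes the exact null distribution itself: zero differences are
dropped, absolute differences are ranked with average ranks on ties, and the
distribution of \(W^+\) across all \(2^m\) sign assignments is obtained by
convolution over the doubled (hence integer) ranks — numerically identical to
full enumeration, but polynomial cost. The reported `W` is
\(\min(W^+, W^-)\) and the two-sided p doubles the smaller tail (capped at 1),
the same convention `wilcox.test` uses. Above \(m = 25\) pairs a normal
approximation with tie and continuity corrections takes over. The test suite
checks the exact path against a literal \(2^m\) enumeration oracle for all
\(m \le 10\) and against `wilcox.test` on tie-free data.

The Shapiro–Wilk check is delegated to `stats::shapiro.test()` — the
reference implementation — behind a thin domain-checked wrapper.

## The synthetic cohort generator

No raw patient cubes are publicly available for this kind of study, so the
package ships a generator whose outputs are *constructed* to hit prescribed
per-patient endpoints, giving the analysis pipeline a closed loop to be
tested against.

**Textures with prescribed GLCM statistics.** For a texture built row by row
from consecutive gray-level steps \(e\), the right-neighbour GLCM statistics
are plain moments of the step multiset: contrast \(= E[e^2]\) and homogeneity
\(= E[1/(1+|e|)]\). `solve_step_distribution()` inverts the pair of moment
equations on a symmetric three-level support \(\{0, \pm 1, \pm m_2\}\):

\[ q_1 + m_2^2\, q_2 = \text{contrast}, \qquad
   \tfrac{q_1}{2} + \tfrac{m_2}{1+m_2}\, q_2 = 1 - \text{homogeneity}, \]

solved as a linear system for each \(m_2 = 2, 3, \dots\) in turn; the
smallest \(m_2\) with all probabilities in \([0,1]\) is returned, making the
solution deterministic. (The inversion is underdetermined — many supports
work — so smallest-feasible is a tie-break, chosen because it keeps the
brightness corridor narrow.) For the study-condition pair (5.86, 0.56) this
lands on \(m_2 = 4\) with \(q_0 = 0.3275\), \(q_1 = 0.3267\),
\(q_2 = 0.3458\); forward evaluation returns the targets to \(10^{-9}\), a
property the tests assert across 1000 random feasible pairs.

**Moment-exact synthesis.** `pattern_synthesize()` rounds the ideal step
counts to the available \((\text{cols}-1) \times \text{rows}\) pairs and lays
steps down as adjacent \(+m/-m\) blocks with alternating orientation:
every row stays inside `brightness ± max(|e|)`, block deviations cancel so
the measured brightness sits within half a gray level of the target, and the
realized contrast/homogeneity equal the rounded multiset's moments *exactly*
(the pair counts are known by construction). Magnitude-2 steps serve as a
fine-tuning channel: trading eight \(\pm1\) steps against two \(\pm2\) steps
leaves contrast untouched while nudging homogeneity in increments of
\(\approx 2.7/T\), which brings the worst-case homogeneity error below
\(10^{-3}\) for 64×64 frames. The seed shuffles only where blocks fall inside
each row — the statistics are identical across seeds by construction, which
is why cohort builds are reproducible regardless of the seed used.

**From gray image to cube.** `gray_to_cube()` gives every pixel the same
smooth spectral shape scaled linearly by its gray level — a melanin-like
model: darker pixel, more pigment, proportionally less reflected light at
every band. The shape is a sigmoidal rise through the visible range plus a
mean-neutral Gaussian band at the analysis wavelength whose amplitude is
solved so the ROI-mean reflectance at the 654 nm band equals the target
exactly. Because the band term is mean-neutral across bands, each pixel's
band-mean stays \(g \cdot S/(G-1)\) and `cube_to_gray()` recovers the input
image *exactly*; with additive noise (an option, default SD 0) recovery is
within the noise-scaled rounding bound instead.

**The packaged 12-patient preset.** `paper_cohort_preset()` returns a frozen
target table designed once, by seeded constrained search, to satisfy all the
published cohort summaries simultaneously: brightness 143.33 ± 23.75 →
157.67 ± 19.89 (9/12 increases, median paired shift 15.50), contrast 5.86 ±
1.09 → 5.21 ± 1.06 (10/12 decreases), homogeneity 0.56 ± 0.16 → 0.64 ± 0.13
(8/12 increases), and 654 nm ROI-mean reflectance with medians 854 → 932 c.u.
and a significant Wilcoxon increase. Individual patient values are free
design parameters — only the cohort summaries are published — so the table is
one documented solution, not a reconstruction of any real cohort. Brightness
targets are integers (so cohort means like 1720/12 = 143.33 are exact), and
the reflectance targets scale roughly linearly with brightness so that the
spectral bump stays within its positivity window for every patient.

## Problem sizes and defaults

Synthetic cubes default to 64 × 64 pixels × 204 bands (400 + k·2.941 nm) —
a desk-scale stand-in for the camera-native 512 × 512 frame that keeps a full
12-patient build-plus-analysis loop under ten seconds; the full frame is one
argument away (`paper_cohort_preset(shape = c(512L, 512L, 204L))`). Cubes are
written as float32 ENVI/BSQ with a flat white-reference cube at 800 counts;
calibration against that reference reproduces the designed reflectances to
float precision.

## What the closed loop does and does not show

Passing the closed-loop tests demonstrates that the *measurement* chain —
ENVI I/O, calibration, gray conversion, GLCM statistics, band extraction,
paired statistics — is internally consistent and recovers known ground truth
through every file-format and arithmetic step. It does not validate the
biological interpretation: the generator's spectra share one spectral shape
per cube (real skin mixes melanin and haemoglobin signatures with spatial
chromophore gradients), its texture is stationary noise-like structure rather
than blotchy pigment spots, brightness and reflectance are exactly collinear
by construction, and acquisition artifacts (micromovement smear, illumination
drift) are out of scope. Two cohort-level behaviours of real data are also
not emulated: the published non-normality of metric distributions (the
designed targets happen to pass Shapiro–Wilk) and the published
non-significance of the reflectance-range endpoint, which the preset leaves
unconstrained.

## Numerical and degenerate-input choices

* Interleave handling is pure index permutation; the three layouts
  round-trip bit-identically.
* `calibrate()` refuses a reference with `white ≤ dark` in any band
  (degenerate-reference error) instead of producing infinities.
* `glcm()` errors on images with no valid pair at the requested offset; a
  single-column image is fine at θ = 90° but degenerate at θ = 0°.
* Ties: brightest/darkest-pixel selection breaks ties by row-major first
  occurrence; `band_index()` ties go to the lower band; rank ties in the
  signed-rank test take average ranks.
* `pattern_synthesize()` rejects brightness targets whose corridor would
  leave `[0, G-1]` (suggesting a recentred brightness or smaller outer
  magnitude) rather than clipping, which would distort the step multiset.
* Zero paired differences are dropped before ranking; an all-zero difference
  vector is a degenerate-data error surfaced as an `NA` p-value with a
  warning at the cohort level.

## Known limitations

* The gray conversion uses the unweighted band mean; no spectral weighting
  or illuminant model is applied.
* Only rectangular ROIs are supported; multi-ROI mosaics and segmentation
  are out of scope.
* The ENVI reader handles the uncompressed header + raw convention
  (data types 1, 2, 3, 4, 5, 12; BIL/BIP/BSQ; little/big endian) but not
  compressed or tiled variants.
* `refl_range_cu` (max−min at the analysis band) inherits the
  brightest/darkest-pixel convention; on cubes violating the shared-shape
  assumption it can differ from the pointwise envelope range, which is
  available via `roi_profiles(pixel_rule = "pointwise")`.
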