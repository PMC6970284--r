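---
title: "Z-score mapping of cardiac MOLLI T1: model, phantoms and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Z-score mapping of cardiac MOLLI T1: model, phantoms and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t1zmap)
library(dplyr)
library(purrr)
```

## The problem

Native myocardial T1 is a quantitative tissue property, but its absolute
value in milliseconds depends heavily on the measurement platform: field
strength (1.5 T vs 3 T), scanner vendor and model, and the MOLLI sampling
scheme all shift the healthy range. A septal T1 of 1100 ms is unremarkable
on one 3 T system and grossly abnormal on a 1.5 T system. This breaks the
comparability of T1 results across sites and makes "is this T1 abnormal?"
answerable only relative to platform-specific normal data.

`t1zmap` standardizes T1 maps by the classical Z-score transform, applied
pixel-wise:

$$Z = \frac{T1 - \mu}{\sigma}$$

where $\mu$ and $\sigma$ are the mean and SD of healthy septal myocardial
T1 measured *on the same platform* — the same hardware, field strength and
MOLLI variant. A Z-score map is platform-agnostic by construction: healthy
myocardium is centred at 0 with unit spread everywhere, and the clinical
normal range $(\mu - 2\sigma,\ \mu + 2\sigma)$ becomes $|Z| \le 2$ on
every platform.

## The reference model

A reference entry is built from a healthy cohort as the arithmetic mean
and **sample SD (n − 1)** of per-subject septal mean T1. Two points matter:

* The SD is the *between-subject* spread of septal means, not a pooled
  pixel SD. Pixel noise within one map is much larger than the
  between-subject spread of means and would produce a falsely wide normal
  range.
* References are keyed by the full platform tuple (field strength, vendor,
  system, MOLLI scheme) and a lookup miss is a hard error. There is no
  cross-platform fallback: non-interchangeability of platforms is the
  reason the method exists.

The ROI feeding the reference is the **septal core**: contours are
rasterized, each myocardial pixel gets a normalized transmural depth
$d \in [0, 1]$ (0 at the endocardium, 1 at the epicardium), and the outer
20% layer at each surface ($d < 0.2$ or $d > 0.8$) is excluded to guard
against partial-volume contamination from the blood pool and
extra-myocardial tissue. The exclusion is a transmural *proportion*, not a
fixed pixel erosion, so it adapts to wall thickness. Depth is computed
from exact Euclidean point-to-contour distances,
$d = d_\mathrm{endo} / (d_\mathrm{endo} + d_\mathrm{epi})$; on concentric
annuli this reproduces the analytic radial position to well under a tenth
of a pixel, which the test suite checks against the closed-form oracle.

## Storage and rendering

DICOM pixel intensities are integers, so Z maps are stored as
$\mathrm{round}(100\,Z)$ — a Z of 1.5 is stored as 150. Rounding is half
away from zero so that negative Z is treated symmetrically; storage is
signed 16-bit with sentinel −32768 for background, and the PGM-16 on-disk
form adds an offset of 32768 declared in the JSON sidecar (the analogue of
a DICOM rescale intercept). The quantization error is at most 0.005 Z
units, far below any clinical decision margin.

Rendering uses an 11-class symmetric diverging palette (blue → white →
red, ColorBrewer RdBu reversed) with classes 1 Z unit wide centred on
Z = 0 and saturation at |Z| = 5. The exact published scheme for the
original prototype is not printed anywhere we can cite, so the palette is
configurable and this default is our own choice; only its symmetry is
enforced (a non-symmetric palette is rejected).

## The synthetic phantom

No clinical images ship with the package; every claim is exercised on
synthetic short-axis phantoms with known ground truth:

* geometry: an LV blood-pool disc inside a concentric circular myocardial
  annulus on a square grid (default 128², endo/epi radii 20/30 px). Real
  myocardium is crescentic; a circular annulus is geometrically ideal, but
  it is exactly what makes the transmural-depth oracle analytic, and none
  of the downstream mathematics depends on annulus shape.
* per-subject septal mean drawn from
  $\mathcal N(\texttt{myo\_mean}, \texttt{between\_subject\_sd})$; pixel
  noise $\mathcal N(0, 20\ \mathrm{ms})$ within the myocardium, truncated
  at 0 ms; blood pool $\mathcal N(\texttt{blood\_mean}, 30\ \mathrm{ms})$.
* disease: a global additive T1 elevation (amyloidosis-like), expressed in
  ms or in multiples of the between-subject SD.
* seeding: a cohort master seed deterministically derives per-subject
  seeds, so every cohort is reproducible bit for bit.

The built-in platform profiles span the empirically reported spread of
healthy-cohort SDs: 24–33 ms at 1.5 T, 44–58 ms at 3 T, plus one 3 T
outlier profile at 97 ms (a 3-3-5b scheme whose recovery periods are short
relative to 3 T myocardial T1). Mean levels (950 ms at 1.5 T, 1150 ms at
3 T, blood 1600/1900 ms) are order-of-magnitude plausible defaults — the
per-platform mean tables of the source cohorts are not public — and no
test depends on them: the validated quantities (mean Z of self-referenced
cohorts, SD recovery, classification agreement) are invariant to the mean
level by construction.

What the phantom deliberately does **not** model: the MOLLI signal
generation itself (inversion pulses, heart-rate dependence, T1* vs T1
correction), motion and registration artifacts, crescent geometry, partial
volume at sub-pixel resolution, and 3D slice stacks. Passing tests
therefore demonstrate that the *processing* — geometry, normalization,
storage, statistics, classification — is correct, not that any acquisition
scheme is accurate.

## Statistics suite

The cohort statistics mirror standard multi-platform comparison practice:

* normality per group by Shapiro–Wilk and Lilliefors-corrected
  Kolmogorov–Smirnov (normal null with estimated parameters; the
  Lilliefors correction is the defensible choice when $\mu,\sigma$ are
  estimated from the sample);
* Levene's test (centre = mean) gates the omnibus in auto mode: classic
  one-way ANOVA when Levene's $p \ge 0.05$, Welch's ANOVA otherwise; both
  are also callable explicitly;
* Bonferroni post-hoc: all pairwise independent t-tests with p multiplied
  by $\binom{k}{2}$ and clamped at 1. Run it per field strength to keep
  the family within one field strength. Pairwise tests default to pooled
  variance (the classic post-hoc convention) and can be switched to Welch;
* independent t-tests default to Welch — the safer default when variance
  homogeneity is exactly what is in question;
* TOST equivalence: two one-sided Welch t-tests of
  $H_0: |\Delta| \ge \varepsilon$, $p_\mathrm{TOST} = \max(p_1, p_2)$.
  The reported interval is the $(1 - 2\alpha)$ = 90% CI, the standard TOST
  interval at $\alpha = 0.05$; a 95% interval is also reportable via
  `ci_level` since both conventions circulate in applied reports and we do
  not assert which one any given software produced.
* classification: abnormal iff $|Z| > k$ (default $k = 2$), with a
  **strict** inequality — a subject at exactly 2 SDs is normal. The
  boundary decision is arbitrary but must be fixed and documented;
  classifying in ms against $(\mu \pm k\sigma)$ and classifying mean Z are
  provably identical and the suite asserts this on random cohorts.

## Numerical and design choices

* Sample SD with n − 1 everywhere, including ROI pixel statistics.
* Pixel membership: even-odd rule at pixel centres (via `mgcv::in.out`);
  0-based (row, col) coordinates; sector angles measured from the positive
  column axis towards the positive row axis, modulo 360°, half-open
  intervals that may wrap through 0°.
* Z maps are computed for every valid pixel (blood pool included); ROI
  masks apply only at statistics time. Blood-pool Z values are meaningless
  diagnostically but harmless, and whole-image maps are what a viewer
  renders.
* Degenerate inputs are hard errors, not silent defaults: zero reference
  SD, empty masks, exclusion fraction ≥ 0.5, duplicate database keys,
  missing references, malformed rasters. Two constant samples with equal
  means in a t-test return $t = 0, p = 1$ with a warning (a logged
  convention, since the statistic is 0/0).
* A cohort needs at least 2 subjects (SD undefined below that); normality
  tests need 3.

## Validation scales

The shipped validation uses problem sizes chosen to make every check
sharp while keeping the full suite under a minute on a laptop core:
15-subject cohorts on 128² grids for self-reference normalization (the
cohort mean of per-subject mean Z is zero to 10⁻⁹, and its SD is 1),
n = 200 cohorts for parameter recovery (reference mean within
$3\sigma/\sqrt n$, SD inside the 99% chi-square interval), 1000-replicate
null simulations for type-I calibration of the omnibus test and of TOST's
non-equivalence control (both inside the 95% binomial band around 0.05),
and a 2000-subject end-to-end run on 64² grids where a 6-SD disease shift
is detected with sensitivity 1.0 and specificity within Monte-Carlo error
of the analytic $1 - 2\Phi(-2) \approx 0.954$. The specificity check uses
a self-referenced cohort of 1000 so that the finite-reference t-tail
inflation (appreciable at n = 15) is negligible against the normal-tail
prediction.

## A compact worked example

```{r example}
geom <- phantom_geometry(128)
cohort <- generate_cohort("siteA_15T_5s", geom, n_subjects = 15,
                          master_seed = 11)
mask <- septal_core_mask(cohort[[1]]$contours, 128, geom)

means <- map_dbl(cohort, ~ roi_statistics(.x$map, mask)$mean)
ref <- build_reference_stats(means, builtin_profiles(TRUE)[[1]]$key)
ref
normal_range(ref)

z_means <- map_dbl(cohort, ~ mean_roi_z(compute_z_map(.x$map, ref), mask)$mean)
round(c(cohort_mean_z = mean(z_means), cohort_sd_z = sd(z_means)), 12)
```

```{r pipeline}
res <- run_pipeline(pipeline_config(profiles = c("siteA_15T_5s", "siteA_3T_5s"),
                                    n_healthy = 15, n_diseased = 25,
                                    disease_shift_sd = 6, seed = 1,
                                    geometry = phantom_geometry(64)))
res$performance
res$comparisons
```

## Known limitations

* The angular-sector "septum" is a geometric stand-in; clinical septal
  delineation is anatomical and operator-driven.
* Reference databases carry a free-text ROI descriptor rather than a
  machine-checkable ROI definition; mixing ROI conventions across entries
  is the user's responsibility.
* No DICOM parametric-map object is written; the PGM-16 + sidecar pair
  mirrors the semantics (integer pixels, rescale, sentinel) without
  modality metadata.
* Between-subject SD recovery assumes the phantom's Gaussian
  between-subject model; heavy-tailed real cohorts would widen normal
  ranges in ways the phantom does not probe.
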