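---
title: "Quantifying dermal collagen architecture: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dermal collagen architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermometry)
```

## The scientific problem

Topical hyaluronic acid (HA) is believed to remodel the dermal
extracellular matrix (ECM): it hydrates the amorphous ground substance and,
through swelling and spacing effects, changes the architecture of the
collagen network. dermometry quantifies that remodelling on calibrated
microscopy images at two scales:

* **Light microscopy (LM).** In an H&E-stained dermis section the fibrillar
  ECM takes up eosin (dark), while the amorphous ground substance stays
  unstained (bright). The fraction of unstained pixels inside the dermal
  region of interest is the *amorphous-ECM percentage*,
  $100\cdot N_u/(N_u+N_s)$, reported separately for the compact papillary
  and the looser reticular dermis.
* **Transmission electron microscopy (TEM).** Five measurements on
  longitudinally sectioned collagen: bundle thickness (nm), bundle
  linearity index (path length of the bundle profile divided by the
  straight-line distance between its endpoints, $\ge 1$, higher = more
  tortuous), fibril diameter (nm), interfibrillar distance (edge-to-edge
  gap, nm), and the axial D-band period (nm, canonically ~67 nm and a few
  nm lower in chemically fixed tissue).

Measurements are pooled per condition (control CT vs HA-treated), timepoint
(24 h, 48 h) and dermis layer (papillary, reticular), summarized as
mean ± SEM, and compared pairwise: Mann–Whitney U for the five non-normal
variables, two-sample t-test for the D band, two-sided, $\alpha=0.05$,
without multiple-testing correction. "Paired comparisons" is read as
*pairwise group comparisons*: the compared groups are distinct tissue
measurements with no pairing key, so independent-samples tests are used;
this reading is recorded in the report's provenance block.

## Synthetic data as ground truth

Raw micrographs of HA-treated human skin are rarely available for reuse,
so the package ships a seeded generator whose outputs carry exact ground
truth; every estimator is validated against it.

**H&E sections.** A Gaussian random field (white noise smoothed with an
isotropic Gaussian of correlation length `blob_length_scale_um`, default
6 µm) is thresholded at the empirical quantile matching the target
amorphous fraction. This gives organic blob shapes and an *exactly known*
mask: the realized area fraction equals the target to one-pixel
granularity. The two phases get mean intensities 0.3 (stained) and 0.8
(unstained) with additive Gaussian noise (SD 0.05); the separation is
validated to exceed $4\times$ the noise SD so the phases are separable by
construction. Color is not simulated: the classification criterion is a
single intensity threshold, so one channel suffices (RGB input is reduced
to luminance at the reader).

**TEM fields.** A bundle is a stack of parallel fibrils following offset
curves of a sinusoidal centerline $y = A\sin(2\pi x/\lambda + \phi)$, with
phase $\phi$ drawn per image. Every pixel's signed perpendicular offset and
axial arc-length coordinate relative to the centerline are obtained by a
vectorized Newton iteration on the nearest-point condition (7 iterations;
the offset-curve construction is validated so the bundle half-width stays
below 0.8 times the minimum radius of curvature, where the iteration is
well-conditioned and offset curves do not self-intersect). Fibril interiors
(intensity 0.25) are modulated along the axis as
$I(s) = I_f\,(1 + c\cos(2\pi s/D + \phi_i))$ with per-fibril phases;
gaps and background are bright (0.85). Sinusoids were chosen as the path
family because their arc length has a cheap, independent quadrature oracle.

Two acquisition regimes mirror the two magnifications of a TEM study:
a *bundle scale* (8 nm/px, ~8900×) where interfibrillar gaps are
unresolved — emulated by giving intra-bundle gaps intensity 0.45, below the
half-depth level, so the bundle reads as one dark band — and a *fibril
scale* (1.5 nm/px, ~36,000×) where gaps resolve bright.

**Cohorts.** `cohort_design()` describes the full 2×2×2×2 design with the
study sample sizes: 40 LM images per condition (20 per duplicate), 40
bundle- and fibril-scale measurements per condition, 100 D-band
measurements per condition (50 per duplicate, up to one per fibril per
image). Per-image *biological heterogeneity* is drawn from the image seed:
the amorphous target uniformly in mean ± 2.5 pp (so control papillary spans
11–16% and reticular 23–28%, the ranges typical of healthy dermis at these
two depths), bundle size
with CV 6%, per-image linearity target with SD 0.015, fibril diameter CV
6%, gap CV 12%, D period SD 1.2 nm (all truncated at ±2.5 SD). Without
this spread every image would hit its target exactly and group SEMs would
collapse to zero, which no real cohort does.

The `ha_effect_design()` preset encodes the HA effects in the reticular
dermis at 24 h relative to a 0.23 control baseline: amorphous fraction
+5 pp (0.23→0.28), bundle thickness −10%, linearity +5%, fibril diameter
+10%, interfibrillar distance −20%, D period unchanged.

**What the generator does not emulate.** Epidermis, cells and appendages;
stain variability and color; optics (no PSF), detector artifacts; fibril
branching, orientation dispersion within a bundle, or 3-D sectioning
effects. Passing tests therefore demonstrate that the estimators and
statistics are correct *given* well-formed two-phase images with the
stated geometry — not that segmentation would survive arbitrary real-world
staining or imaging pathology. For real data the ROI and annotations are
supplied by the user, exactly as an expert would delineate them.

## Estimators

* **Threshold selection.** The expert-chosen threshold of a real study is
  modelled as `method = "fixed"`; the automated default for synthetic data
  is Otsu's between-class-variance criterion on the ROI histogram (256
  bins). With well-separated phases the variance surface has a broad
  plateau; any plateau threshold classifies equivalently.
* **Amorphous percentage** counts ROI pixels strictly above the threshold.
  Both counts are kept so either the percentage of total connective tissue
  (the reported quantity) or the unstained/stained ratio can be recovered.
* **Centerline tracing** thresholds the dark phase (Otsu), takes the
  connected component under the seed point and follows its ridge column by
  column as the membership centroid, lightly smoothed (SD 2 columns). A
  darkness-weighted centroid was rejected: the axial D-band modulation
  biases it sideways. The tracer assumes the bundle runs within ~45° of
  the image x-axis, which the generator guarantees; strongly vertical or
  branching structures are out of scope. The seed tolerates single
  noise-flipped pixels by accepting the darkest pixel in a 5×5 patch.
* **Bundle thickness** casts 20 perpendicular transects at evenly spaced
  stations of the centerline, samples them at half-pixel steps (bilinear
  interpolation), smooths (Gaussian, σ = 1 px) and measures the dark-band
  width by the half-depth criterion — the midpoint between the local
  background (median of the probe tails) and the band minimum — with
  sub-sample crossing interpolation. Probes that exit the image, find no
  band, or are truncated are dropped; more than 50% dropped is an error.
  The mean of probe widths is returned. When a protocol records only "one
  measure per bundle", averaging along the bundle versus measuring at a
  single site is an open choice; the mean-of-probes definition is this
  package's, and is flagged in the report metadata.
* **Fibril segmentation** applies the same half-depth criterion to a
  transect profile: maximal runs below the level are fibril intervals,
  interval widths are diameters, bright spans between consecutive
  intervals are interfibrillar distances. Intervals truncated by the
  profile ends are discarded. Interfibrillar distance is defined
  edge-to-edge (gap width), not center-to-center, consistent with
  "minimal interfibrillar distances" relative to fibril size.
* **D-band period** samples the axis polyline at half-pixel steps,
  removes a linear trend and reads the period from the autocorrelation.
  Because sub-pixel sampling correlates noise over neighbouring samples,
  peaks are only accepted beyond the first zero crossing. The first
  prominent peak (floor 0.1) is refined by parabolic interpolation, then
  divided out of the highest consistent peak multiple, which shrinks the
  sub-sample quantization error by the multiple's order. The estimate is
  cross-checked against the dominant periodogram peak; disagreement beyond
  10% flags the value low-confidence (the flag propagates into the
  measurement table's `note` column). Autocorrelation is preferred over
  the raw spectral peak for the returned value because it behaves better
  for slightly anharmonic banding; the spectrum serves as the consistency
  check. The profile must cover at least five periods.

Numerical conventions: intensities in [0, 1]; continuous (row, col) pixel
coordinates with pixel centres at integers; physical lengths always via
the stored pixel size; images are quantized to the 16-bit grid *before*
measurement so in-memory results and disk round trips agree bit for bit.

## Statistics

`mann_whitney_u()` computes U from midranks. With no ties and
min(n₁, n₂) ≤ 8 the two-sided p is exact (null distribution of U; the
cutoff keeps full enumeration of the checkable space at C(16,8) = 12,870
labelings, which the test suite enumerates independently). Otherwise the
normal approximation with tie correction and continuity correction is
used; at n₁ = n₂ = 8 its worst-case deviation from the exact p over all U
is 0.0109 (without the continuity correction: 0.046). `t_test()` defaults
to the pooled-variance (Student) variant — the classical reading of an
unqualified "t-test" — with Welch available; degenerate zero-variance
input follows fixed conventions (identical means → p = 1, distinct
means → p = 0, flagged). The comparison plan per variable is fixed: CT vs
HA at each timepoint and 24 h vs 48 h within each condition, per layer
(8), plus papillary vs reticular within every condition × timepoint cell
(4) — 12 comparisons × 6 variables.

## Replicate simulations and problem sizes

Two simulation utilities quantify the statistical behaviour of the whole
chain. `simulate_null_type1()` builds replicate null cohorts by pooling a
null-design cohort's measured values per variable and resampling every
group cell from the common pool (no group differences by construction);
200 replicates put the empirical type-I error of both test families near
the nominal 0.05. `simulate_effect_pattern()` builds replicate effect
cohorts as *fresh truth + resampled measurement error*: per-image truths
are redrawn from the design's generative laws and the pipeline's empirical
residuals (measured − truth) are bootstrapped within each variable × group
cell. Redrawing the truths matters: resampling measured values directly
would freeze one cohort's chance group-mean differences into the
simulation and, for example, inflate the D-band rejection rate from the
nominal ~5% to ~13%.

Problem sizes used by the test suite and the acceptance script — one full
image cohort per design (960 images: 8 groups × 40 LM + 40 bundle-scale +
40 fibril-scale), 200 resampled replicates for type-I, 100 for the effect
pattern, a 14–27-cell recovery grid — were chosen so the whole study
re-runs comfortably on a laptop while keeping every binomial check
well-powered. Canvas defaults (LM 256² px at 0.74 µm/px; TEM 256×384 px at
8 nm/px and 1.5 nm/px) are likewise this package's choice; all estimators
are calibration-linear, so results transfer across sensible acquisition
geometries.

## Known limitations

* The tracer and thickness probes assume a single, roughly horizontal,
  unbranched bundle per field.
* Interfibrillar gaps near the smoothing scale (≲ 3 px) are measured with
  upward bias of a fraction of a pixel; the recovery grid covers gaps down
  to 5 nm at 1.5 nm/px, where the median error stays within 5%.
* Exact Mann–Whitney p-values are only defined for tie-free data; the
  16-bit quantization makes exact ties across images possible in
  principle, in which case the tie-corrected approximation is used.
* The D-band low-confidence flag is advisory; flagged values stay in the
  table with their `note` so downstream filtering is the analyst's call.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(design = ha_effect_design(), seed = 1,
                  out_dir = "ha_run")
report <- run_synthetic_experiment(cfg)
subset(report$comparisons, label == "CT_vs_HA_24h_reticular",
       select = c(variable, test, p_value, significant))
```
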