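# dermometry

Morphometry of dermal collagen in light and electron micrographs.

Topical hyaluronic acid (HA) remodels the dermal extracellular matrix:
it hydrates the amorphous ground substance, swells collagen fibrils and
changes the spacing and tortuosity of collagen bundles. dermometry is an R
package for histologists and skin-biology labs who want to quantify that
remodelling on calibrated microscopy images, and for methodologists who
want a fully testable stand-in for such a study when no raw images are
available.

## What it computes

**Light microscopy.** On an H&E-stained dermis section, eosin-stained
fibrillar ECM is dark and the amorphous ground substance is bright. For a
dermal region of interest with `N_u` unstained and `N_s` stained pixels,
the amorphous-ECM percentage is

    amorphous_pct = 100 * N_u / (N_u + N_s)

with the threshold either fixed (expert-chosen) or selected by Otsu's
between-class-variance criterion. Papillary and reticular dermis are
evaluated separately.

**Transmission electron microscopy.** Five measurements on longitudinally
sectioned collagen, all in physical units via the image calibration:

| measurement             | definition |
|-------------------------|------------|
| bundle thickness        | mean half-depth width of the dark band across perpendicular probes along the bundle axis (nm) |
| bundle linearity index  | path length of the bundle profile / straight-line distance between its endpoints (≥ 1; higher = more tortuous) |
| fibril diameter         | half-depth interval width on a transect across the fibrils (nm) |
| interfibrillar distance | edge-to-edge bright gap between consecutive fibrils (nm) |
| D-band period           | lag of the first prominent autocorrelation peak of the detrended axial intensity profile, cross-checked against the periodogram (nm) |

**Statistics.** Measurements are pooled per condition (CT/HA) × timepoint
(24/48 h) × dermis layer, summarized as mean ± SEM, and compared with a
fixed 12-comparison plan per variable: Mann–Whitney U (exact enumeration
p-value for small tie-free samples, tie- and continuity-corrected normal
approximation otherwise) for all variables except the D-band period, which
uses a two-sample t-test; two-sided, α = 0.05, no multiple-testing
correction.

**Synthetic cohorts.** A seeded generator produces calibrated H&E-like
sections (thresholded Gaussian random fields with an exactly known
amorphous mask) and TEM-like fields (wavy bundles of parallel fibrils with
controlled diameter, gap, tortuosity and D-band modulation, rendered by
perpendicular distance to the true centerline), each paired with exact
ground truth, so the entire measurement and statistics chain is testable
end to end.

## Worked example

```r
library(dermometry)

# one synthetic H&E section with a 25% amorphous target
sec <- generate_he_section(synth_histology_params(
  target_amorphous_fraction = 0.25, seed = 1))
amorphous_percentage(sec$image, threshold = select_threshold(sec$image))
#> amorphous ECM: 25.00% (16384 unstained / 65536 ROI px, threshold 0.5449)

# D-band period of one synthetic fibril (64 nm designed)
tem <- generate_tem_bundle(synth_tem_params(d_period_nm = 64, seed = 2))
d_band_period(tem$image, tem$truth$fibril_axes[[2]])
#> D-band period: 63.81 nm (spectral check 63.92 nm, low confidence: FALSE)

# full synthetic study with the HA reticular-24h effects encoded
cfg <- run_config(design = ha_effect_design(), seed = 1)
report <- run_synthetic_experiment(cfg)   # ~1 min: 960 images
subset(report$comparisons, label == "CT_vs_HA_24h_reticular")
#>                 variable         test statistic  p_value significant
#>            amorphous_pct mann_whitney     0.000 1.43e-14        TRUE
#>         bundle_thickness mann_whitney  1548.000 6.35e-13        TRUE
#>          linearity_index mann_whitney     6.000 2.25e-14        TRUE
#>              fibril_size mann_whitney   151.000 4.37e-10        TRUE
#>  interfibrillar_distance mann_whitney  1444.000 5.94e-10        TRUE
#>            d_band_length       t_test     0.184 8.54e-01       FALSE
```

The five designed effects (more amorphous ECM, thinner and more tortuous
bundles, thicker fibrils, smaller gaps) come out significant in the
treated reticular dermis at 24 h, while the D-band period — deliberately
left unchanged, as molecular collagen assembly is not expected to shift —
does not.

Reports can be persisted (`out_dir`) as `measurements.csv`,
`comparisons.csv`, `summaries.json` and `provenance.json`; synthetic
cohorts can be exported to disk (16-bit TIFF + JSON sidecars + manifest)
and re-ingested through the real-data path, reproducing the in-memory
report exactly. A thin command-line wrapper lives in
`inst/cli/dermometry.R`.

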