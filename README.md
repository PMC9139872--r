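# erythema

Quantification of gastric ulcer severity from ordinary RGB photographs.

Gastric ulcers in animal models and endoscopy are conventionally scored by
eye: trained observers measure each hemorrhagic corrosion and apply a
length/width point rubric (conventional clinical observation, CCO). That
score is subjective and varies across raters. This package implements the
image-analysis alternative: erythema — the mucosal redness that marks
ulceration — is segmented by red-channel thresholding and counted in pixels,
and the count is normalized into an **ulcer index**

> UI = 100 × (erythema fraction of the sample) / (mean erythema fraction of
> the untreated control group),

so the control group averages exactly 100%. Around that core the package
provides:

- **Imaging**: PNG/TIFF/JPEG I/O, computational cellophane-film shielding
  (`shield_channel()`), low-red background suppression
  (`suppress_low_red()`), per-channel affine color-card correction
  (`correct_with_card()`), and white-balance brightness levels 50/100/200
  (`adjust_brightness()`).
- **Segmentation**: tissue masking that excludes specular/juice whites and
  unlit blacks, 256-bin red histograms, erythema bisection at an expert or
  automatic (Otsu) red threshold (`segment_erythema()`), 3D color-density
  relief maps, and a dark-spot detector for stress-model (WIRS) lesions.
- **Calibration**: the two-fold blood-dilution erythema standard
  (50% … 3.125%, 0% blank), OLS standard-curve fitting with R²
  (`fit_standard()`), inverse prediction clamped to the 0–80%
  blood-concentration-equivalent range, and 10%-wide severity bins with the
  severe flag at ≥ 60%.
- **Scoring**: the CCO rubric as a reference scorer (`cco_score()`, with the
  rubric's two published ambiguities exposed as arguments), and a
  nearest-centroid severity classifier on mean RGB with class means
  247.964 / 233.184 / 206.857 (`classify_rgb()`).
- **Reproducibility**: per-subject rater SD and Bland–Altman bias and limits
  of agreement (`bland_altman()`), with `autoplot()` methods.
- **Synthetic fixtures**: seeded, bit-reproducible generators for lesion
  images with exact ground-truth masks, blood-dilution well plates, and
  multi-rater score panels (`make_gastric_image()`, `make_well_plate()`,
  `make_rater_panel()`, `write_fixture_dir()`).

All tabular results are tibbles; fitted objects have `tidy()`/`glance()`
methods; a thin CLI (`inst/cli/erythema.R`) exposes the pipeline as
subcommands. See `vignettes/erythema-methods.Rmd` for the full methods
account.

## Worked example

Generate a synthetic study (3 control, 3 ethanol-phenotype treated images)
and run the pipeline with the published erythema standard:

```r
library(erythema)

dir <- tempfile()
write_fixture_dir(dir, n_control = 3, n_treated = 3, size = c(256, 256), seed = 1)

res <- run_pipeline(list(
  controls = file.path(dir, sprintf("control_%02d.png", 1:3)),
  images   = file.path(dir, sprintf("treated_%02d.png", 1:3)),
  calibration = list(slope = 0.4432, intercept = -0.0282)
))
res[, c("sample_id", "group", "raw_fraction", "ui", "class")]
```

```
   sample_id   group raw_fraction   ui  class
1 control_01 control     0.009995  100 severe
2 control_02 control     0.009995  100 severe
3 control_03 control     0.009995  100 severe
4 treated_01  sample     0.119995 1201 severe
5 treated_02  sample     0.119995 1201 severe
6 treated_03  sample     0.119995 1201 severe
```

Controls carry ~1% erythema and define UI = 100; treated images carry ~12%
and score a twelve-fold ulcer index. (The severity `class` column compares
each frame's mean RGB against centroids derived from bright endoscopy
photographs, so the deliberately darker synthetic tissue classes as severe —
on clinical frames the three labels separate at the 240.574 and 220.0205
midpoints.)

The calibration standard round-trips its published line exactly:

```r
conc <- dilution_series()                    # 0.50 0.25 0.125 0.0625 0.03125 0
fit_standard(data.frame(concentration = conc,
                        response = 0.4432 * conc - 0.0282))
#> <calibration_curve> response = 0.4432 * concentration -0.0282  (R^2 = 1.0000, n = 6)
```

And the reference rubric scores a 1.5 mm × 0.5 mm linear corrosion at 3
points:

```r
cco_score(data.frame(kind = "linear", length_mm = 1.5, width_mm = 0.5))
#> <cco_score> 1 lesion(s), total 3 points
```

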