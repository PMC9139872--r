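---
title: "Methods: quantifying gastric ulcer erythema from RGB photographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying gastric ulcer erythema from RGB photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erythema)
```

## The measurement problem

Gastric ulcer severity in animal models and endoscopy is traditionally scored
by eye: trained observers measure hemorrhagic corrosions with a caliper and
apply a length/width point rubric. That score is subjective, and panels of
raters disagree. The alternative implemented here replaces the caliper with
pixel arithmetic on ordinary RGB photographs: erythema (mucosal redness from
increased blood flow) is the visual marker of damage, red-channel
thresholding isolates it, and lesion burden becomes a pixel count that any
two analysts can reproduce exactly.

The package implements the full computational chain: channel shielding and
low-red suppression, tissue masking, red-histogram segmentation, ulcer-index
normalization, a blood-dilution calibration standard, a mean-RGB severity
classifier, the manual rubric as a reference scorer, and Bland–Altman
agreement statistics to compare the two.

## Pixel model and imaging operations

Images are 8-bit RGB arrays (`rgb_image`, H×W×3, values 0–255, sRGB as
shot). No gamma linearization is applied: every published quantity in this
workflow is defined directly on raw 8-bit values, so the package operates on
them too. All scaling operations round half-up and clip to [0, 255];
half-up rounding is chosen over R's default round-half-even because it is
the convention image software users expect and it makes worked examples
platform-stable.

*Channel shielding* (`shield_channel()`) emulates photographing through a
colored cellophane film by zeroing the two non-designated channels. A hard
zero rather than a spectral filter model is deliberate: the physical films
make markers of the shielded color vanish entirely against black, and
zeroing reproduces exactly that.

*Low-red suppression* (`suppress_low_red()`) sets pixels whose red value is
below a threshold to black and drops them from the foreground mask. Healthy
tissue carries a modest red component that would otherwise be counted as
erythema.

*Color-card correction* (`correct_with_card()`) fits, per channel, a linear
gain + offset mapping measured card patch means onto their reference values
by ordinary least squares, then applies the map to every pixel. The affine
model is the minimal one that leaves a correctly exposed image untouched
(identity when measured = reference) and inverts a uniform cast exactly; it
requires at least two distinct patches per channel, and fails loudly when
all patches measure identically.

*Brightness levels* (`adjust_brightness()`) follow the endoscopy
white-balance convention in which the level number runs opposite to
brightness: 50 = high (×2), 100 = medium (identity), 200 = low (×0.5); in
general each channel is scaled by 100/level. Note that one figure caption in
the source literature for this method gives the displayable range as 0–225
rather than 0–255; we read that as a typo and clip at 255 throughout.

## Erythema segmentation

Analyzable tissue is everything that is neither near-white — specular glare
and gastric juice, excluded when `min(R,G,B) >= white_cutoff` (default 240)
— nor near-black — unlit background, excluded when `max(R,G,B) <=
black_cutoff` (default 20). The defaults clear the white and black extremes
without touching tissue pinks around (205, 145, 150).

Within the tissue mask, only the red channel is consulted: a 256-bin red
histogram is built and the tissue is bisected at a red threshold, pixels at
or above it counting as erythematous. In the original workflow that
bisection point was set "based on medical doctors' suggestions"; since no
number was published, the package's default is Otsu's method on the masked
red histogram — deterministic, reproducible, and overridable wherever an
expert threshold exists (`red_threshold` argument, CLI `--threshold`). Our
Otsu maximizes between-class variance over splits `red < t` vs `red >= t`
and resolves plateaus (common when the two modes are well separated and the
gap bins are empty) to the smallest maximizing `t`; any in-gap choice yields
the same segmentation.

The 3D relief view (`relief_map()`) renders one channel as heights, channel
value / 255. Normalizing to [0, 1] rather than keeping raw 0–255 makes the
export scale-free for any 3D viewer.

Dark-spot lesions of the water immersion-restraint stress (WIRS) model are
not red; the published protocol notes only that the method "was modified"
for them. `dark_spot_mask()` exposes our reading of that modification — a
low-value detector flagging tissue pixels with `max(R,G,B)` below a darkness
cutoff — as a separate, clearly named operation rather than silently folding
it into the erythema path.

## Ulcer index and reference scoring

The ulcer index (`ulcer_index()`) normalizes each sample's erythema pixel
fraction by the mean fraction of the untreated control group and scales by
100, so the control group averages exactly 100%. The index is linear in the
sample fraction and invariant to any common rescaling of sample and control
fractions.

The manual rubric (`cco_score()`) assigns 1 point to small round corrosions
and 2/3/4/5 points to linear ones by length band, doubling a lesion's points
when its width exceeds 1 mm. The published band list has two genuine
ambiguities, and both resolutions are arguments rather than silent choices:

- the 5-point band is stated as "> 4 mm", leaving lengths in (3, 4] without
  a score. The default extends the 5-point band down to > 3 mm because a
  monotone, gap-free rubric is the only defensible reading for a scorer
  that must accept any lesion; `five_point_min = 4` keeps the literal bands
  and scores (3, 4] with 4 points.
- "the scores were added and doubled when the width … was > 1 mm" can double
  each wide lesion or the grand total. The default doubles per lesion, which
  is order-independent and granular; `double_scope = "total"` doubles the
  sum when any lesion is wide.

Stated bands are read closed on the side stated first ("1–2 mm" = [1, 2]),
so every boundary length has exactly one score.

## Blood-dilution calibration

The erythema standard relates a measured color response to true blood
concentration: a two-fold serial dilution (50%, 25%, 12.5%, 6.25%, 3.125%,
plus a 0% saline blank — `dilution_series()`) is photographed, a response is
read per well, and `fit_standard()` fits response = slope × concentration +
intercept by ordinary least squares with R² = 1 − SS_res/SS_tot. The
published image-side standard, y = 0.4432x − 0.0282, is available as a
ready-made curve via `calibration_curve(0.4432, -0.0282)`. Which image
statistic plays "y" was never published; the module accepts any response
column, and our well-plate generator defines its own (mean red of the well
region / 255).

Degenerate inputs follow fixed conventions: identical concentrations are an
error (no line exists); identical responses yield slope 0 with R² defined
as 0, so downstream code sees a deterministic object rather than NaN.

`predict_concentration()` inverts the line and clamps into [0, 0.8], the
0–80% blood-concentration-equivalent reporting range; clamping rather than
erroring is required because the line is applied to whole photographs where
out-of-range responses are routine. `bin_severity()` tiles that range into
eight 10%-wide bins — a width chosen so the ~60% severe balance point is a
bin edge — and flags concentrations ≥ 60% as severe. (An epsilon guards the
floor division so 0.6 lands in the [0.6, 0.7) bin despite floating-point
representation.)

In the full pipeline the calibration response of an image is the mean red
value of its segmented erythema zone divided by 255 — the statistic most
directly comparable to a blood-filled well — with lesion-free images pinned
to concentration 0.

## Severity classification

`classify_rgb()` assigns normal / mild / severe by the nearest of three
fixed mean-RGB centroids (247.964, 233.184, 206.857 — specialist-judged
class means; overridable). Nearest-centroid with three points is equivalent
to midpoint thresholds at 240.574 and 220.0205. Ties break toward the more
severe label — the safer default for a screening aid — and the comparison
carries a 1e-9 tolerance so an exact midpoint resolves severe-ward even when
the two distances differ by a floating-point ulp. Whether the published
class means average all three channels or red alone was not stated; the
all-channel mean is the default and `mean_rgb(..., channels = "red")` is the
alternative.

## Agreement statistics

`rater_sd()` computes the per-subject sample SD (n−1 denominator —
appropriate for small panels of ~8 raters) across raters.
`bland_altman()` summarizes two methods' paired scores by bias (mean
difference) and limits of agreement, bias ± 1.96 × SD of differences; 1.96
is the conventional multiplier, exposed as an argument. No significance test
of LoA differences is performed — how "significance" was assessed for the
published reproducibility comparison was never stated, so the package
reports the intervals and leaves inference to the analyst.

## Synthetic fixtures: what they emulate and what they don't

No lesion photographs are deposited with the published method, so the
package generates its own inputs with known ground truth
(`make_gastric_image()`, `make_well_plate()`, `make_rater_panel()`,
`write_fixture_dir()`). All generators draw from R's Mersenne-Twister
generator (normal.kind "Inversion") under an explicit seed and restore the
caller's RNG state, so identical specs give identical bytes.

Lesion images are a pink tissue field (default (205, 145, 150)) with
per-pixel Gaussian noise (default SD 3 — the residual channel noise of a
controlled-photography setup, small against the ≥ 40-level lesion/background
contrast). Ethanol-phenotype lesions are elongated stripes (default red 245,
near-saturated erythema); WIRS-phenotype lesions are dark round spots
(default red 50). The ground-truth mask is built by ranking pixels on
distance to randomly placed lesion skeletons (segments or points) and taking
exactly the requested area fraction, so the mask area is exact to one pixel
and lesion geometry stays stripe- or spot-shaped. Optional extras: a
near-white specular disk (drawn off-lesion, so ground truth is unaffected)
and a horizontal lighting ramp. Default frame 512×512; the test-suite builds
its fixtures at 32–96 pixels per side, which keeps the full suite under a
minute without changing any generator default.

These fixtures emulate contrast, noise, glare and uneven lighting. They do
not emulate specular anatomy, rugal folds, depth, motion blur, JPEG
artifacts, or the continuum of lesion colors in real tissue — so a passing
suite demonstrates that the arithmetic chain is correct under its stated
model, not that the thresholds generalize to arbitrary clinical images.

The well-plate generator renders each well's mean red as 255 × (slope ×
concentration + intercept), clipped; under the published standard line the
blank and the two most dilute wells have (slightly) negative ideal
responses and clip to black, which the response table flags (`clipped`) so
round-trip fits can restrict themselves to the linear wells. Rater panels
add method-specific Gaussian noise (defaults: manual SD 15, image analysis
SD 3 per rater on a 0–400 UI scale, 8 raters — the ordering, not the exact
magnitudes, is the published claim) and floor scores at 0.

## Interfaces

Everything tabular enters and leaves as a tibble; fitted objects carry
`tidy()`/`glance()` methods and each result type has an `autoplot()`.
Run configuration, card layouts and calibration curves use JSON sidecars;
tabular inputs and outputs are header-bearing, dot-decimal CSV. A thin
command-line wrapper (`inst/cli/erythema.R`) exposes the subcommands
calibrate, segment, index, score-cco, classify, agree, simulate and
pipeline over the exported functions, logging to stderr.

## Known limitations

- Red-channel thresholding is the published criterion and the implemented
  one; hue- or ratio-based criteria, texture and learned segmentation are
  out of scope.
- The severity centroids are fixed published constants; the 140 clinical
  images behind them are not available, so the classifier cannot be
  re-derived, only applied.
- Scoring is two-dimensional; lesion depth is invisible to it.
- The Otsu default assumes a reasonably bimodal red histogram; nearly
  lesion-free images make the split arbitrary, which is why an expert
  threshold override exists at every level.
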