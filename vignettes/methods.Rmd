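---
title: "Quantifying mitochondrial superoxide from high-content plate images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial superoxide from high-content plate images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Mitochondrial superoxide (mROS) in adherent endothelial cells is commonly
read out with a mitochondria-targeted fluorogenic probe. On a bulk
fluorescence plate reader the readout is the total well fluorescence, which
confounds three things: probe that actually oxidised inside mitochondria,
probe oxidised elsewhere in the cell (non-specific signal), and background
fluorescence of the well and medium. Confocal high-content imaging removes
the first two confounds by *colocalization masking*: the superoxide-reporter
signal is only counted where it overlaps a mitochondrial-dye mask, per cell.
`mitoscreen` implements that workflow end to end for three-channel
(nuclear dye / mitochondrial dye / superoxide reporter) images of 96-well
plates, together with the plate-level normalisations and the statistical
layer of a small drug screen.

The per-well quantity is

> mean mROS signal per cell = (sum over all analysed cells of the
> background-corrected reporter intensity inside the cell's mitochondrial
> mask) / (number of cells analysed),

replicate wells are averaged per condition, and condition means are reported
as percent of a designated control: `(ratio - 1) * 100` for increases,
`(1 - ratio) * 100` for reductions. Alongside the mROS readout the same mask
provides a membrane-potential proxy (mean mitochondrial-dye intensity, RFU —
mean, not sum, so it is independent of mask area) and the mitochondrial area
(mask pixels x `pixel_size_um`^2, in um^2).

## Segmentation chain

The imaging software this mirrors documents *what* is segmented (nuclei,
then the mitochondrial region surrounding each nucleus) but not *how*; the
chain here is the standard robust one, fully parameterised
(`segment_params()`):

1. **Nuclei** — Gaussian smoothing (sigma 2 px), Otsu threshold on the
   max-normalised image, hole filling, distance-transform watershed to split
   touching nuclei, size filter (40 px), and exclusion of border-touching
   nuclei (their mitochondria may be clipped; configurable).
2. **Cell regions** — the foreground (union of nuclei and above-Otsu
   mitochondrial signal, closed with a 5 px disc) is partitioned by distance
   to the nearest nucleus. A distance partition rather than fixed-radius
   rings adapts to confluency and is testable against a nearest-centroid
   oracle.
3. **Mitochondrial mask** — per-cell Otsu threshold inside each cell region,
   falling back to a global in-region quantile (0.9) for cells too dim or
   uniform to split; connected speckles under 4 px are removed. The mask is
   a subset of its cell region by construction, and a cell with an empty
   mask is retained with zero measurements.

All thresholds are relative, so the label maps are invariant to a global
intensity rescale.

## Background correction: sliding parabola vs. background well

Two correction strategies are implemented because their disagreement is
scientifically meaningful:

* **Sliding parabola** (`sliding_parabola()`): the corrected image is
  `image - P(image)` where `P` is the grayscale morphological opening with a
  paraboloid structuring element `z(dx, dy) = -c (dx^2 + dy^2)` — the
  "rolling paraboloid" swept under the image. Because the paraboloid is
  additively separable, the erosion and dilation are computed *exactly* as
  1-D lower/upper-envelope passes along rows then columns (linear time,
  unbounded support; implemented in C++). The opening never exceeds the
  image, so the residual is non-negative; it is invariant to constant
  offsets; and the estimated background is idempotent. Steeper paraboloids
  (larger `c`) hug the image more and leave a *smaller* residual; the
  default `c = 0.05` intensity/px^2 is chosen to be several-fold steeper
  than the synthetic illumination dome (curvature about 0.004 at the default
  amplitude, about 0.008 at double amplitude) while still passing under
  mitochondria-scale structures (a structure of width w is shaved by at most
  `c w^2 / 4`, about 1-2% of granule height at w ~ 30 px).
* **Background well** (`background_well_subtract()`): the mean reporter
  intensity of designated empty, cell-free wells is subtracted as a scalar;
  negative results clamp to zero (clamps are reported).

The known failure mode of the well method — and the reason the imaging
comparison favours the parabola — is that an empty well *underestimates* the
background of a well containing cells: residual probe, conditioned medium
and cellular autofluorescence add diffuse signal that only a per-image filter
can see. The synthetic generator reproduces this with `bg_cellwell_factor`
(default 1.5: cell wells carry 1.5x the background surface of empty wells),
plus the parabolic illumination dome itself. Under these conditions the
well-subtracted fold change is compressed toward zero while the
sliding-parabola estimate stays close to truth; with noise, the parabola
carries a small residual of its own (its opening rides on the lower envelope
of shot noise), which stays well under the well method's structural bias.

## The synthetic plate generator

No real image data ships with the package; every downstream stage is tested
against `simulate_field()` / `simulate_plate()`, which emulate the assay at
the level that matters for the *measurement*, not photorealism:

* **Nuclei**: non-overlapping flat-top blobs (rejection-sampled minimum
  separation 26 px), radius ~5 px at the default 0.6 um/px.
* **Mitochondria**: per cell, 70 small anisotropic flat-top kernels
  scattered in a perinuclear annulus 1-3 nucleus radii out, saturating at
  `mito_amp` — a granular, plateau-like network whose ground-truth mask
  (texture above 15% of `mito_amp`) nearly coincides with any sensible
  relative threshold. Masks of neighbouring cells are made disjoint by
  max-texture ownership.
* **Reporter**: `s x 0.6 x` (mitochondrial texture) exactly on the true
  mask, where `s` is the condition scale factor the assay estimates; plus an
  optional non-specific cytoplasmic component carrying a fraction `f` of the
  total reporter signal outside mitochondria; plus the parabolic
  illumination dome; plus noise.
* **Noise**: Poisson shot noise on expected counts, then additive Gaussian
  read noise (sd 8) — the standard camera model; both optional.
* **Non-specific scaling**: the cytoplasmic component scales as
  `s^2` by default (`cyto_exponent`). This is the design choice that lets
  unmasked, plate-reader-style totals show *larger* fold changes than the
  masked per-cell readout, as bulk assays notoriously do; with a linear
  cytoplasmic response the two folds would be equal and the specificity
  contrast could not be exercised.
* **Determinism**: per-field seeds derive arithmetically from the master
  seed; `(seed, params)` fully determine every image and its ground truth.

What the generator does **not** emulate: real mitochondrial morphology
(networks, fission/fusion), cell-to-cell biological heterogeneity in `s`,
spectral bleed-through, focus drift, or 3-D structure (fields are single
2-D planes; z-stacks must be projected upstream). Passing tests therefore
demonstrate that the *pipeline arithmetic and its estimators* behave as
specified under a controlled camera model — not that segmentation would be
this accurate on arbitrary real data.

## Statistics

* Two-group comparisons use the classical pooled-variance Student t-test
  (Welch and paired modes by flag), reporting the mean difference with its
  95% CI on the same scale as the inputs. Degenerate zero-variance cases
  resolve to p = 1 (equal means) or a degenerate CI with p -> 0 (constant
  shift) rather than erroring.
* Multi-group screens use one-way ANOVA followed by Dunnett's many-to-one
  comparisons. Adjusted p-values and simultaneous CIs integrate the
  max-|t| multivariate-t distribution with the correlation matrix implied by
  the group sizes (`mvtnorm::pmvt`, quasi-Monte-Carlo with a fixed internal
  seed; the global RNG stream is untouched), so unbalanced designs need no
  separate fallback. With two groups this reduces exactly to the unadjusted
  t-test.
* Cohort tables use the uncorrected Pearson chi-squared (df = 1). The
  continuity-corrected statistic is deliberately not used: on the bundled
  cohort worked example only the uncorrected form reproduces the
  conventionally reported p-value.
* Dose-response uses the four-parameter logistic
  `y = bottom + (top - bottom) / (1 + (x/IC50)^h)`, fitted by
  Levenberg-Marquardt in log-IC50 parameterisation; the IC50 standard error
  is delta-method transformed from the log scale. Non-convergence is
  reported, never silent, and a fitted Hill slope opposite to the
  pharmacological expectation is flagged (`hill_sign_inverted`).
* Reporting conventions: two-sided tests, alpha 0.05, 95% intervals; both
  SD and SEM are emitted at the condition level.

## Numerical and design notes

* **Channel order** is fixed as (nuclei, mito, reporter) in 3-plane TIFFs,
  matching the instrument's laser listing order (405/640/561 nm); 16-bit
  writes clamp at 65535 with a warning and integer images round-trip
  exactly.
* **Pixel calibration** is a required configuration value (default
  0.6 um/px); areas are `mask_px x pixel_size_um^2`.
* **Membrane potential** is read from the *uncorrected* mitochondrial
  channel by default (RFU convention); a flag applies the background model
  there too.
* **Per-cell metric**: the reporter metric is the masked *sum* per cell
  (then averaged across cells); a mean-intensity alternative is available by
  flag.
* **Ties and degeneracy**: nearest-nucleus ties resolve to the lower label;
  zero-nucleus fields yield empty maps with a warning; wells with no
  detected cells anywhere are flagged `no-cells`, excluded from condition
  means, and warned about.
* **Problem sizes** used throughout the test suite were chosen to keep a
  full run comfortable on a laptop: unit tests use 160 px fields with ~6
  cells; the end-to-end recovery studies use the generator defaults (320 px,
  ~30 cells/field, 10 fields/well, duplicate wells) with three master seeds,
  and the error-rate simulations use 5000 (t-test) and 2000 (Dunnett)
  replicates.

## Known limitations

* The cell "region" is a distance partition of the foreground; at very high
  confluency it will split shared mitochondrial clouds geometrically rather
  than biologically.
* The parabola residual carries a small positive noise-floor offset under
  strong shot noise; it is common-mode across conditions and cancels almost
  entirely in percent-of-control terms, but absolute masked sums are best
  compared under a single correction method.
* The probe cannot distinguish its two oxidation products; nothing in the
  analysis layer can recover that specificity, and the package does not try.
* No learning-based segmentation, no 3-D, no tracking, no flat-field
  calibration from reference images, and no reading of proprietary
  instrument formats.
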