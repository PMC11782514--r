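---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures implemented in
`colonoidquant`, the parameters that matter and why their defaults are what
they are, what the synthetic generators do and do not emulate, and the
design choices made where more than one reasonable reading existed.

## The experimental design the package serves

Colonoid cultures from several donors are differentiated under two oxygen
levels (2% "physioxia" vs 20% atmospheric) and six treatment arms: DMSO
vehicle (the reference), tofacitinib (50 µM; 25.2 µg/mL at 504.5 g/mol),
budesonide (10 µM; 4.3 µg/mL at 430.5 g/mol), TNF + Poly(I:C) inflammatory
stimulation, and each drug combined with stimulation.
`condition_levels()`, `condition_manifest()` and `validate_design()` keep
every downstream table keyed consistently; `normalize_condition()` resolves
the synonyms that appear in instrument exports. Donor diagnosis (healthy
control vs ulcerative colitis) is carried as metadata only — no computation
branches on it.

## Brightfield morphometry

The well statistic is the mean area of the 100 largest colonoids per well.
The stages, and the conventions inside them:

* **Phansalkar threshold.** `t = m(1 + p e^{-qm} + k(s/r - 1))` on the
  image rescaled to [0, 1], with `m`, `s` the mean and *population* standard
  deviation of the `(2·radius+1)²` window. Constants default to the
  standard published values (k = 0.25, r = 0.5, p = 2, q = 10). Window
  statistics use mirror (symmetric) padding at the borders. Polarity is
  `dark_objects` by default because colonoids image as dark rims on a bright
  background; the threshold radius is a per-experiment setting (different
  optical setups need different radii), with 15 px used for the synthetic
  scenes.
* **Particle analysis.** Holes are filled on the full mask *before*
  labeling (a colonoid's bright lumen belongs to the colonoid), components
  are labeled 8-connected (the ImageJ convention), particles touching the
  image border or leaving the region of interest are dropped, and particles
  below the minimum size are dropped. The minimum-size field is interpreted
  as an **area in µm²** (default 10), matching how calibrated
  particle-analysis size fields behave; because the phrase "10 µm" is
  genuinely ambiguous, `size_is_area = FALSE` switches to an
  equivalent-diameter reading.
* **Top-K mean.** Particles are sorted by area descending with ties broken
  by ascending id, so results are deterministic under equal areas. Wells
  with fewer than K particles average what they have and set `truncated`.

Solidity (area / convex-hull area) is measured per particle from the convex
hull of the pixel squares and clipped at 1.

## Optical density and stain separation

Chromogenic images are handled in optical-density space, where stains mix
linearly (Beer–Lambert): `OD_c = -log10((I_c + 1) / I0_c)` with `I0 = 255`
and the +1 guarding zero intensities; OD is clipped to [0, 3]. Colour
deconvolution solves `M c = od` per pixel, where the columns of `M` are
unit-norm stain vectors. The slide-specific vectors used on the original
scanner are not recoverable, so the default basis is the standard published
H-DAB set (hematoxylin ≈ (0.65, 0.70, 0.29), DAB ≈ (0.27, 0.57, 0.78),
residual completed as the normalised cross product); any other basis can be
supplied. Negative concentrations are clipped to zero. On the float path
the transform is exactly invertible; through an 8-bit image the round trip
is accurate to ≤ 0.02 OD at OD ≤ 1, which the synthetic H-DAB generator
verifies empirically.

## Chromogenic quantification

The trained pixel classifiers used interactively in slide-analysis software
are not shippable artifacts, so colonoid segmentation here is a documented
fixed-threshold segmenter: Gaussian-smoothed total OD (hematoxylin + DAB)
above a threshold, closed (2 px), hole-filled, labeled. It is deliberately
pluggable — anything producing the same annotation table can replace it.
Annotations are then filtered by mean OD sum ≥ 0.15, solidity ≥ 0.25 and
residual-channel mean ≤ 0. Two readings deserve a note:

* "OD Sum" is aggregated as the **mean** total OD over the object (the
  per-object aggregation is not otherwise pinned down).
* "presence of residual colour (cut off 0)" is applied with a numerical
  tolerance of 1e-3 OD — a literal `> 0` test would exclude every object
  under float noise.

CK20 positive area smooths the DAB channel (σ = 2.5 px), thresholds at
0.3 OD and reports positive pixels as a percentage of all annotation
pixels. Ki67 nucleus detection resamples the hematoxylin channel to 0.5 µm
pixels, estimates background by morphological opening (radius 8 µm) and
subtracts it, smooths (σ = 1.3 µm), thresholds at 0.1, splits touching
nuclei by watershed on the distance map, and keeps areas of 15–200 µm².
Classification follows the stated inequalities strictly: hematoxylin mean
**< 0.11** excludes; DAB mean **> 0.15** is positive.

## Fluorescence quantification

The nucleus detector is pluggable behind the interface
`(DAPI matrix, params) -> (labels, scores)`. The default,
`detect_nuclei_classical()`, replaces a pretrained deep segmentation network
with a deterministic classical pipeline (Gaussian smoothing, fixed
threshold, hole filling, watershed splitting); its per-object score is the
peak smoothed response normalised by 256, so it is strictly below 1 and the
probability threshold (default 0.6) behaves like a detection confidence.
This keeps tests deterministic and the package free of weight files; a
learned detector can be substituted without touching anything downstream.

Exclusion rules: nucleus area within 12–175 µm² (read as µm², the plausible
nuclear range) and mean DAPI signal at least 60 (TUNEL analysis) or 25
(compound-marker analysis) — both retained as mode-specific defaults.
Intensities are treated as 8-bit (0–255); the cut-offs (15, 25, 60, 68.2)
only make sense on that scale, which is why the synthetic generator renders
8-bit channels (configurable).

Cytoplasm simulation dilates each nucleus by 5 µm (a common default; the
value is not pinned by the source settings and is configurable), resolving
overlaps by nearest-nucleus partition via geodesic region growing, so
cytoplasm masks are disjoint by construction. Compound classification:
CK20⁺ iff cytoplasm CK20 mean > 15, Ki67⁺ iff nucleus Ki67 mean > 25.

TUNEL burden: the green channel is smoothed (σ = 1 px — whether the
original classifier saw smoothed or raw pixels is unstated, so the σ is an
explicit config default), thresholded at 68.2, and each connected region is
converted to its boundary polygon in pixel-corner coordinates (the shoelace
area of that polygon equals the pixel count exactly). Shape simplification
is Visvalingam vertex elimination with triangle-area tolerance 1.5 px²; the
induced area change is bounded by the tolerance times the number of removed
vertices and is checked to stay within 2% for convex regions. Simplified
polygons are re-rasterized by scanline and the metric is total area (µm²)
per kept DAPI cell.

## Blot normalisation and panel statistics

Immunoblot folds are computed on the linear scale: `target/GAPDH` per lane,
divided by the DMSO lane's ratio within each donor × oxygen group. Bands at
or below an intensity floor are rejected rather than clipped, to avoid
silent division blow-ups. Paired marker ratios (pMLKL/MLKL, cleaved
caspase-3/caspase-3) divide GAPDH-normalised values per matched key before
the same fold step.

Multiplex preprocessing strips trailing asterisks, parses numerics, and
substitutes "OOR <" tokens with 50% of the analyte's minimum detected value
(per analyte, across all its rows). "OOR >" rows are flagged and excluded
rather than imputed — substitution is only defined for the low side. The
detection-range rule is operationalised as: analyte retained when its
median observed value is ≥ 10 pg/mL and ≤ its upper detection limit, and
no more than 10% of its rows are above range; the per-analyte aggregation
is not pinned down by the source description, so it is documented here and
configurable.

The mixed model is `log(Value) ~ Condition + Oxygen + Condition:Oxygen +
(1 | Donor)` — natural log (log2 is used only for ELISA, as stated),
treatment coding with DMSO and 2% oxygen as references, REML, Satterthwaite
degrees of freedom for the coefficient t-tests (the default behaviour of
the mixed-model testing package the analysis mirrors). Singular fits (zero
donor variance at the boundary) are returned flagged, not thrown; on
degenerate data where the mixed fit cannot be computed at all the fixed
effects fall back to ordinary least squares — on a balanced design the
point estimates coincide — and the fit is flagged `ols-degenerate`.
A Shapiro–Wilk p-value on the residuals is carried as the residual-normality
diagnostic. Across analytes, p-values are Benjamini–Hochberg adjusted
within each term.

The RM one-way ANOVA treats subject as a blocking factor
(`F = MS_condition / MS_error`, df `(k-1)` and `(k-1)(n-1)`); post-hoc
pairwise contrasts use the pooled error mean square
(`se = sqrt(2 MS_error / n)`, error df) with Šídák adjustment
`1 - (1 - p)^m` over the requested comparisons. All-constant data returns
F = 0, p = 1 by convention. The reporting rule lists every comparison with
p < 0.2 (inter-donor variability makes sub-threshold trends informative),
with tiers `*` < 0.05, `***` < 0.001, `****` < 0.0001.

## What the synthetic generators emulate — and what they do not

Each generator plants a scene whose truth table suffices to predict the
pipeline output without re-reading pixels, and a fixed seed reproduces the
scene bit-identically.

* **Brightfield wells**: bright background, dark-rimmed ellipses with a
  lighter lumen (the polarity the threshold stage must handle), log-normal
  areas (median 2000 µm², sdlog 0.6 — heavy-tailed like real colonoid
  sizes), a configurable fraction of objects straddling the border. The
  default 60–120 objects per well is a deliberately scaled-down well (a
  tenth of a full one) chosen to keep a validation run around a second per
  well; truth areas are rasterized pixel counts, so recovery can be asserted
  exactly.
* **H-DAB sections**: per-pixel OD maps (hematoxylin disks, DAB on a known
  subset of nuclei) composed to RGB by Beer–Lambert mixing — the exact
  inverse of the analysis path, so the deconvolution round trip isolates
  8-bit quantization as the only error source.
* **Fluorescence sections**: nuclear DAPI/Ki67 disks, perinuclear CK20
  rings, diffuse TUNEL patches of known rasterized area; class counts are
  planted exactly (largest-remainder rounding).
* **Panels and blots**: log-normal concentrations with additive
  condition/oxygen/interaction effects, donor random intercepts and
  lower-limit censoring to "OOR <" tokens — the generative model the LMM
  assumes; blot tables with known fold changes and multiplicative noise.

None of the image generators attempt photorealism: no texture, no uneven
illumination, no focus artifacts, no overlapping or clumped objects, no 3-D
structure. Passing recovery tests therefore demonstrates that the
*algorithms* are implemented correctly and are self-consistent, not that
they are robust to the full messiness of real microscopy — segmentation
quality on real slides still needs the usual visual QC, and the pluggable
detector/segmenter interfaces exist precisely so stronger models can be
swapped in.

## Validation problem sizes

The shipped validation (test suite and `scripts/acceptance.R`) uses: three
wells of 60/90/120 planted colonoids; 200-nucleus H-DAB sections; 300-cell
fluorescence sections (and 100-cell TUNEL scenes with ~500 µm² of planted
patch); 100 random 64×64 images for the threshold oracle; 200 simulation
replicates for mixed-model effect recovery and 500 for null calibration.
These sizes were chosen so the whole validation completes in a few minutes
on a single CPU while keeping Monte-Carlo error well inside the asserted
bounds.

## Known limitations

* Whole-slide pyramidal formats are out of scope; inputs are in-memory
  rasters (TIFF/PNG). TIFF calibration metadata travels in a JSON sidecar.
* Stain vectors are inputs, not estimated from images.
* The classical nucleus detector assumes reasonably separated,
  roughly convex nuclei; heavily clumped tissue will need a substituted
  detector.
* The statistics layer implements the analyses described for this design
  (paired t, RM-ANOVA + Šídák, the donor-intercept LMM); it is not a
  general mixed-model toolbox.
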