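---
title: "Grid-based microvascular stereology: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based microvascular stereology: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vascmorph)
library(dplyr)
```

`vascmorph` quantifies microvessel morphology in sectioned spinal cord
tissue at two scales: light-microscopy stereology of vessel-profile masks,
and electron-microscopy thickness morphometry of the capillary wall. This
vignette explains the estimators, the assumptions behind them, the
parameters that matter, and the design choices made where the methodology
left room.

## The stereological model

A micrograph field (318 µm × 429 µm by default) carries a binary mask of
endothelial-stained vessel profiles, a region-of-interest (ROI) mask, and
optionally a lesion-cavity mask. A square test system of pitch
*d* = 12.25 µm — so each lattice point represents *d*² = 150.0625 µm²,
nominally 150 µm² — is overlaid at a uniformly random offset in
[0, *d*)² per field. Three raw tallies are taken:

* **P** — lattice points whose pixel is vessel foreground inside the ROI;
* **hI, vI** — crossings of vessel boundaries with the horizontal and
  vertical line families, counted as foreground/background transitions
  along each line at pixel resolution;
* **N** — distinct profiles intersecting an unbiased counting frame whose
  left and bottom edges (with their extensions) are forbidden.

Raw quantities convert as B = ½ π L d with L = (hI + vI)/2 and
A = d² P, and are divided by the cavity-corrected ROI area to give
numerical density N_A, boundary density B_A, areal density A_A, and
S/V = B_A / A_A. With a square grid the total test-line length per unit
area is 2/d, so B_A is exactly the classical Cauchy–Crofton surface
estimator (π/2)·I_L; uniform random offsets make E[d²P] the true profile
area and E[B] the true boundary length, with no assumption on profile
shape and only isotropy (or isotropic grid orientation) needed for the
boundary estimator. The package's property tests verify both
expectations to within 2% over 1000 random offsets against exact
elliptic-integral ground truth.

Assumptions worth stating: masks are taken as correct segmentations
(segmentation itself is out of scope); boundary crossings are counted at
pixel resolution, so a profile tangent to a line registers as one
entry/exit pair only if it covers at least one pixel on that line; runs
clipped by the field edge contribute only their interior crossing.

## Parameters

| parameter | default | units | why |
|---|---|---|---|
| `pitch_um` | 12.25 | µm | gives the 150 µm²-per-point test system |
| field size | 318 × 429 | µm | one micrograph field |
| `pixel_size_um` | 0.33 | µm/px | renders the smallest profiles at ≥ 6 px diameter; rasterised areas within 1% of analytic |
| `cavity_threshold` | 0.95 | fraction | a field is "all cavity" when ≥ 95% of its ROI is cavity; no numeric cutoff is standard, so it is configurable |
| counting frame | whole field, left/bottom forbidden | — | a stated, bias-controlled rule (Gundersen frame) replaces ad-hoc operator conventions |

Missing fields (all-cavity) propagate as absent values and are excluded
from every denominator downstream; they are never imputed as zero, since a
zero would mimic total vessel loss in surviving tissue.

## TEM thickness morphometry

Basement-membrane and intercellular-cleft thickness is measured from
ordered inner/outer contour traces in nm. At a sample point on the inner
trace the local tangent is estimated by central difference (one-sided at
endpoints); thickness is the distance along the local normal to the first
crossing of the outer trace, taking the nearer of the two normal
directions. Rays that miss within a 1000 nm sanity bound, or degenerate
tangents, are skipped with a warning rather than recorded. Sample points
are placed equidistantly along the inner trace's arc length (8 per
basement membrane, 4 per cleft by default) — manual point choice is not
reproducible, equidistant placement is. Capillaries with fewer than 4
basement-membrane or 2 cleft measurements are excluded from that
structure's summary.

Analytic validation uses parallel lines, concentric circles and true
parallel (normal-offset) curves of an ellipse, where the orthogonal
distance is known exactly; the suite requires agreement to 0.5% and
isometry invariance to 1e-9 relative tolerance.

Group summaries pool individual measurements within group × location by
default, matching presentations that plot technical replicates as points;
per-capillary pooling is available (`tem_summary(unit = "capillary")`)
because with very few animals the choice of analysis unit is genuinely
open, and both views should be inspectable.

## Aggregation and statistics

Field estimates aggregate as means of means — fields within section, then
sections within animal — weighting replicate sections equally regardless of
how many fields survived the cavity rule. Per-animal values feed a
group × segment two-way ANOVA per region, fitted with sum-to-zero
contrasts and type-III sums of squares so the unbalanced day-45 group
(n = 3) and cavity-dropped cells are handled by omission, not imputation.
The headline statistic is the interaction F with its (interaction, within)
degrees of freedom; Tukey-adjusted pairwise group contrasts are computed
within each segment via `emmeans`, and by default only the group-vs-sham
contrasts are displayed (full pairwise behind `full_pairwise = TRUE`).
TEM thickness uses Kruskal–Wallis over group × segment cells with Dunn's
post-hoc z tests (tie-corrected, Bonferroni-adjusted by default); the Dunn
procedure is implemented in-package and cross-checked against the identity
z² = H in the two-group case. A Shapiro–Wilk screen runs per cell first
and is *reported*, not used to switch tests: the test choices are fixed
per data type, and the flags surface in the output for the analyst.

No multiplicity correction is applied across regions or read-outs; each
region × read-out test stands alone, consistent with reporting each as its
own bracketed `[F(df1, df2) = F, p]` line.

## The synthetic cohort generator

The generator exists so that every estimator can be validated against
exact ground truth, and so that the statistical stage can be calibrated.
It emulates:

* **Profile geometry.** Capillaries are modelled as tilted cylinders: a
  lumen radius r (log-normal, median 4.0 µm, sdlog 0.25) cut at obliquity
  θ ~ uniform[0°, 60°] gives an ellipse with semi-axes (r/cos θ, r). The
  median was chosen once so that the circle-limit S/V ≈ 2/E[r] of the
  sham population lands in the 0.41–0.44 µm⁻¹ range typical of transverse
  capillary profiles — a smaller, purely luminal radius would push S/V
  near 0.9 µm⁻¹, inconsistent with those summaries.
* **Spatial statistics.** Profile counts are Poisson with mean
  density × field area; placement is uniform, non-overlapping by rejection
  (capillary profiles essentially never overlap at these densities), and
  wholly inside the field by default so that full-ellipse ground truth is
  exact. A `placement = "uniform"` mode lets profiles overhang edges for
  counting-frame studies.
* **The cohort structure.** Baseline sham densities 571/484/90/88 mm⁻²
  (VG/DG/VW/DW); a multiplicative group × segment × region effect map
  whose default entries are the published epicentre and perilesional
  reductions (e.g. day-2 T10: ×0.008 ventral grey, ×0.047 dorsal grey;
  day-45 T10: ×0.56/×0.51), with unpublished cells set once to values
  consistent with the qualitative time course; a log-normal animal effect
  (sdlog 0.08) calibrated so cohort SDs approximate the reported sham
  spread (571 ± 45); and the 4/4/4/4/3 animals × 3 sections × 3 fields
  replication.
* **TEM samples.** Truncated-normal thickness draws at the published
  group means/SDs, dealt to synthetic capillaries in blocks that always
  satisfy the minimum-sampling rule.

What it does **not** emulate: staining artefacts, segmentation error,
erythrocyte or scar-tissue false positives, spatial clustering of
capillaries, within-animal correlation between neighbouring segments, or
any deviation from elliptical profile shape. Passing recovery tests
therefore demonstrates correctness of the estimators and pipeline on
idealised input, not robustness to imperfect segmentation.

## Numerical choices and degenerate inputs

* Raster convention: row = y, column = x, origin top-left, physical
  coordinate = index × pixel size; grid lines live in the open interval
  (0, extent), which makes the expected line count per family exactly
  extent/pitch under uniform offsets.
* A pixel is foreground iff its centre is inside an ellipse; rendering is
  refused when the smallest semi-minor axis is under 3 px.
* Zero ROI area without a cavity flag is an error (it signals a
  segmentation failure); an all-cavity field is not.
* All-tied samples make Kruskal–Wallis degenerate and error out
  explicitly; constant or n < 3 cells are flagged `untestable` by the
  normality gate.
* Every stochastic step takes an explicit seed; per-field subseeds are
  derived deterministically from the master seed so whole cohort trees are
  byte-reproducible.

## Problem sizes used in the validation suite

Monte-Carlo estimator checks use 1000 random grid offsets per scene (400
in the faster unit tests); statistical calibration uses 1000 null
replicates per test stage and 200 replicates for the power and recovery
checks; end-to-end recovery uses the full 4 + 4 animal × 3 × 3 replication
of the sham/day-2 epicentre comparison (72 rendered fields). At these
replications the Monte-Carlo standard errors sit comfortably inside the
asserted 2–5% tolerances.

## Known limitations

* Profile counting assumes one label per profile; overlapping vessels in a
  real segmentation would need instance separation upstream.
* The boundary estimator's isotropy requirement is met here by isotropic
  profile orientations; strongly anisotropic vessel beds (e.g. white-matter
  tracts cut longitudinally) would need isotropic grid rotation instead.
* TEM thickness is 2-D: section obliquity inflates true 3-D thickness;
  comparisons between groups remain valid under equal obliquity
  distributions.
* With n = 2 animals per TEM group, pooled-measurement statistics describe
  the sampled capillaries, not the animal population; the per-capillary
  mode tempers but does not remove this.
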