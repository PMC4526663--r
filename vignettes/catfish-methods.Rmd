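---
title: "Methods: catFISH classification, the similarity score, and synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: catFISH classification, the similarity score, and synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catfishr)
```

## The measurement model

catFISH reads out *when* a neuron was active from *where* its *Arc* mRNA
sits. After two 5-minute behavioral epochs separated by ~25 minutes,
epoch-2 activity shows as two intense intranuclear transcription foci
(one per allele), epoch-1 activity as cytoplasmic staining surrounding
the nucleus, and activity in both epochs as both. The analysis unit is a
two-channel 3D confocal stack: a nuclear counterstain and the Arc/Cy3
channel, typically 34–50 optical sections of ~0.3 µm through a 20 µm
section.

`classify_stack()` runs the chain: preprocessing, segmentation,
neuron/glia discrimination, optical-dissector sampling, per-cell evidence
extraction, and classification. Each stage is exposed separately
(`preprocess`, `segment_nuclei`, `is_neuron`, `optical_dissector`,
`detect_foci`, `cyto_coverage`, `classify_cell`), and a pre-tabulated
counts CSV can bypass imaging entirely (`run_config(mode =
"counts_csv")`), because the imaging stages are replaceable plumbing —
the scientific content is in the criteria and the score.

### Classification criteria

A neuron is **nuclear** Arc-positive when it has at least 2 focus tracks
each persisting ≥ 3 *consecutive* planes. We read "across 3 or more
planes" as consecutive because a genuine transcription focus is a
contiguous object in z; consecutiveness also rejects single-plane noise
detections. A neuron is **cytoplasmic** when the fraction of perimeter
sectors containing Arc signal exceeds 0.60 in ≥ 4 planes; these planes
are *not* required to be consecutive (the criterion says "in", not
"across"), though `classify_options(ring_consecutive = TRUE)` restores
the stricter reading. **Double** requires both full criteria;
**negative** neither. Thresholds are strict inequalities: coverage of
exactly 0.60 does not qualify.

"Surrounded" is operationalized as angular-sector coverage: the per-plane
nucleus mask is dilated by `annulus_width` (default 5 px) and the
dilation band is divided into 36 sectors of 10° around the mask centroid;
a sector counts as covered when it contains at least one Arc pixel at or
above `ring_threshold`. Coverage is then covered-sectors / 36.

### Numerical and robustness choices

These were set by running the classifier against rendered ground truth
and inspecting every failure:

* **Stack-wide Otsu threshold.** The counterstain threshold is computed
  on the pooled voxels of the whole stack, not per plane — per-plane
  thresholds on planes without nuclei split the noise floor instead.
* **Opening before hole-filling.** Per-plane masks are opened with a 3×3
  diamond, then hole-filled. Under heavy noise, supra-threshold noise
  clusters attach to nucleus rims and bulge the mask outward over the
  perinuclear ring, hiding ring sectors from the annulus; opening removes
  them. Hole-filling restores interior pixels where nuclear speckle
  texture dips below threshold.
* **Equatorial-radius focus gating.** A detected Arc component counts as
  intranuclear when its centroid lies within 0.85 of the cell's
  *equatorial* effective radius (from its largest plane mask). Strict
  mask-pixel membership fails: the thresholded rim wobbles over
  rim-adjacent foci, and at off-center planes the noisy per-plane mask
  underestimates the radius. Ring fragments sit beyond the limit in
  either case.
* **Dissector window.** With `n` planes and fraction `f`, cells whose
  mask centroid lies in the closed 0-based window
  `[ceil(n(1−f)/2), floor(n(1+f)/2)]` are kept (planes 14–26 of a
  40-plane stack at the default f = 0.30). Boundary planes are included;
  membership is by centroid, since the criterion ("found in") does not
  define inclusion.
* **Neuron/glia rule.** A nucleus is neuronal when its within-mask
  counterstain coefficient of variation is ≥ `cv_min` (0.10) *and* its
  mean intensity is ≤ `brightness_max` (0.5): neuronal nuclei are
  textured and dim, glial nuclei solid and bright. Degenerate one-voxel
  masks are excluded as glial with a warning. The published analyses did
  this discrimination by eye; the quantitative rule (and its defaults,
  calibrated on synthetic truth) is this package's operationalization.

## The similarity score

With counts (Neg, Nuc, Cyt, Dob) and Total their sum:

$$E_1 = \frac{Cyt + Dob}{Total},\quad E_2 = \frac{Nuc + Dob}{Total},\quad
\mathrm{SiSc} = \frac{Dob/Total - E_1 E_2}{\min(E_1, E_2) - E_1 E_2}.$$

The numerator is the excess of doubly active cells over the chance
expectation under independence; the denominator is the maximum possible
excess, reached when the smaller ensemble is entirely contained in the
larger. Hence SiSc = 1 for one faithfully reactivated population, 0 for
independent populations, and negative values (fewer doubles than chance)
are reported as-is — clipping them would bias group means upward.

When $\min(E_1, E_2) = E_1 E_2$ (an epoch with zero or complete
activation) the score is undefined; `similarity_score()` returns `NA`
with an `undefined` flag, and `run_pipeline()` counts such exclusions in
its manifest, never silently dropping or inventing a number.

SiSc is computed on counts pooled per animal and region (`sisc_table()`
rejects duplicate keys); computing per-stack scores and averaging is
possible by calling `similarity_score()` on per-stack tallies. Pooling is
the default because the score is a ratio of proportions — averaging
ratios of small counts is noisier and slightly biased. Cage-control
animals are excluded from score tables: with a single epoch of ambient
activity the two-ensemble overlap question is not defined for them.

## The synthetic-data generator

The generator defines the study conditions under which every claim in
the test suite is verified.

**Activation model.** Each neuron's (epoch-1, epoch-2) activity is a
bivariate Bernoulli with marginals $p_1, p_2$ and joint probability
$p_{11} = p_1 p_2 + \kappa(\min(p_1,p_2) - p_1 p_2)$. This
parameterization inverts the SiSc formula, so the expected score of the
generated population equals $\kappa$ exactly — parameter recovery is a
sharp test, not an approximation. Feasibility of $\kappa$ follows from
the Fréchet bounds on $p_{11}$ (`kappa_bounds()`). Defaults $p_1 = 0.33,
p_2 = 0.25$ reflect the reported scale of hippocampal pyramidal
recruitment (roughly a third and a quarter of neurons per epoch); since
per-animal raw counts are not published, these are realistic defaults,
not a claimed match to any study's distribution. Glia (default 25% of
nuclei) are never active.

**Rendering.** Stacks default to 40 planes (within the 34–50 range of
0.3 µm sectioning). Nuclei are spheres of in-plane radius 8 px,
z-compressed by `z_ratio = 0.5` (9-plane extent). Neuronal nuclei get
multiplicative speckle (smoothed Gaussian field, CV 0.30, clipped at
±2 sd) on a mean of 0.35; glia are uniform at 1.8× that mean — so the
neuron/glia thresholds are learnable from the rendered truth. Epoch-2
neurons get two foci of radius 2 px at 0.45 r from the center — far
enough apart that the median filter cannot bridge them, far enough
inside that the thresholded outline never cuts them — spanning
`foci_planes` (default 4) consecutive planes. Epoch-1 neurons get a ring
hugging the per-plane nucleus outline (thickness 3 px) over `ring_planes`
(default 5) planes. Both defaults sit one plane above the classification
minima so that default simulations are unambiguous; boundary fixtures
override them per cell (`foci_planes`, `ring_planes`, `ring_coverage`
columns in the truth table).

**Sector-quantized rings.** Rendered ring arcs cover a whole number of
10° sectors (`round(ring_coverage * 36)`), aligned to the measurement
grid. A continuous arc of exactly 60% coverage is geometrically ambiguous
at sector resolution (21.6 sectors); quantization makes the rendered
truth well-defined, and `expected_labels()` derives the criterion-implied
label from the same geometry. Consequently a requested coverage of 0.60
renders 22 sectors (0.611) and is expected cytoplasmic, while 0.58
renders 21 (0.583) and is expected negative; the strict-inequality
behavior at exactly 0.60 is tested directly on stored evidence, where it
is exact.

**Placement.** Rejection sampling enforces a rim-to-rim clearance of
10 px, which guarantees non-overlapping nuclei and keeps each cell's
5-px measurement annulus clear of its neighbors' 4-px rings. Overcrowded
configurations fail with a capacity error rather than degrading.

**Determinism.** All randomness flows through one seed; the same
`sim_config` yields bit-identical truth tables and stacks, and no
function touches the caller's RNG state.

**What the generator does not emulate** — and hence what passing tests do
not show about real tissue: confocal point-spread blurring and z-bleed,
photobleaching, tissue deformation, anisotropic pixel sizes, nuclear
shape irregularity, partial cells at stack faces (the dissector is tested
on whole rendered cells), and biological heterogeneity of staining
intensity. Results on synthetic stacks bound what the pipeline can do
when its model assumptions hold; they do not certify performance on any
particular microscope's output.

## Densitometry

`calibrate_thresholds()` picks one Otsu threshold per channel on a
control image and freezes it for the slide — an automatic, reproducible
stand-in for the experimenter's manual, slide-constant threshold setting;
the *rule* is fixed rather than the value, preserving the slide-constancy
contract. `map2_roi()` thresholds Map2 inside the hand-drawn polygon and
dilates until the mask first reaches 110% of the thresholded area
("about 10% enlargement" given no published radius; the first-crossing
radius and overshoot are recorded). `measure_area_fraction()` then
reports 100 × synaptophysin area / ROI area. The 14 default ROI names
follow the standard CA3/CA1 dendritic parcellation (SOd…SRpd, CA1_SO,
CA1_SR); polygons are supplied by file because the segments are
anatomical judgments, not something to auto-segment. `map2_area_check()`
runs the per-ROI ANOVA of Map2 areas across groups — the denominator
validity check that must stay non-significant for fractions to be
comparable.

The synthetic mosaic places synaptophysin puncta on the *same* ROI mask
the analysis computes, so recovery to within rasterization error
(≤ 0.5 percentage points) is the correctness criterion, verified for all
14 ROIs.

## The statistics layer

`one_way_anova` / `two_way_anova` (balanced crossed designs only; empty
cells are an error, not a silent fallback), `pearson_cor`, and `paired_t`
wrap the classical procedures and return uniform result objects. Both
Fisher-LSD and Bonferroni post hocs are available because published
analyses alternate between them without a stated rule; the choice is an
explicit argument and is recorded in output. p-values are descriptive; no
cross-ROI multiple-testing correction is applied by default, matching
standard practice for this assay. Type-I calibration of all four tests
(rejection rate in [0.03, 0.07] at α = 0.05 under simulated nulls) is
part of the acceptance suite.

## Problem sizes used in the test suite

Stack-level validation uses 20 rendered stacks per noise level (45 nuclei
in 256 × 256 × 40 voxels, plus hand-placed boundary-fixture stacks), κ
recovery uses 200 replicates of 1000 cells per κ, the independence null
500 replicates, and statistical calibration 2000 null replicates per
test. These sizes give Monte-Carlo standard errors small enough for
3-s.e. assertions while keeping the default suite runnable on a laptop in
a few minutes.

## Known limitations

* Segmentation assumes roughly convex, non-clumped nuclei; heavily
  overlapping nuclei rely on a per-plane watershed split that is tested
  on mild contact only.
* The neuron/glia rule is a two-feature threshold classifier; real
  tissue would warrant validation against immunohistochemical markers.
* Evidence extraction is 2D-per-plane with z-linking, not true 3D
  filtering; very anisotropic stacks may need retuned linking distances.
* The densitometry is single-plane mosaic arithmetic; no z-integration
  or illumination-field correction is attempted.
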