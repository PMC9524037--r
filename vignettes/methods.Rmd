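---
title: "Methods: plaque quantification, housekeeping normalization and the reversal statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plaque quantification, housekeeping normalization and the reversal statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaqglia)
```

# Scope

`plaqglia` implements the quantitative core of a confocal
immunofluorescence + multiplexed expression study of amyloid pathology
and neuroinflammation: (i) calibrated segmentation and measurement of
amyloid plaques and of glial cells defined by nucleus/marker overlap,
with plaque association at a physical radius realized through the exact
Euclidean distance transform (EDT); (ii) nCounter-style count
processing — negative-control background subtraction, geometric-mean
housekeeping normalization, fold-change + ANOVA/Tukey DEG calling, and
a directional fold-change-reversal statistic; (iii) mean ± SEM group
summaries with one-way ANOVA / Tukey or Student t tests. Synthetic
generators provide ground-truth scenes and count matrices so every
stage is testable without animal data.

# Image quantification model

## Geometry and calibration

A field is a set of co-registered 2D channels (`plaque`, `glial`,
`nuclear`) with a single calibration in µm/pixel. The reference
acquisition is 1024 × 1024 px at 0.63 µm/px, i.e. a field area of
`r format(field_area_um2(c(1024, 1024), 0.63), big.mark = ",")` µm²
(`field_area_um2()`); all areas are pixel counts × pixel_size², with a
pixel located at its centre and no subpixel boundary correction.
Coordinates are 0-based.

## Segmentation

The original analysis was performed in a commercial imaging suite with
constant but unpublished settings, so the package uses a deterministic,
parameter-light stand-in: a global threshold (Otsu on a 256-level
histogram by default, or a user-fixed value), 8-connected component
labelling, and removal of objects below `min_area_um2` (default
10 µm²). Objects touching the field border are kept, because whole
fields of view were analysed. Components are renumbered 1..N by the
column-major scan position of their first pixel, which makes labels
deterministic. An all-background channel yields an empty mask rather
than an error. 8-connectivity was chosen so that diagonal bridges do
not split an object; a 4-connectivity option exists for sensitivity
analysis.

## Cell positivity

A detected nucleus is a marker-positive glial cell iff its mask shares
at least one pixel with the glial-channel foreground (`any_pixel`
rule). This is the most literal reading of overlap-based positivity; a
stricter `centroid` rule (nucleus centroid must lie on glial
foreground) is exposed as an option because the two differ for
glancing overlaps.

## Plaque association at a physical radius

Plaque masks are dilated to a physical distance by thresholding the
exact EDT: a pixel is in the dilated zone iff its Euclidean distance to
the nearest plaque pixel is ≤ r. This is mathematically identical to
morphological dilation with a Euclidean disk but honours non-integer
pixel radii — 20 µm at 0.63 µm/px thresholds the distance map at
31.746 px, which no iterated 3 × 3 dilation can represent. Zone pixels
carry the label of the nearest plaque, ties going to the lower label
for determinism. A positive cell is associated iff its nucleus overlaps
any zone pixel; each cell is credited once, to the plaque whose zone it
touches at the smallest boundary distance, so per-plaque counts
partition the associated set exactly.

Two radius conventions appear in the source literature for this
workflow: "within 20 µm of the plaque surface" (a 20 µm boundary
radius) and "increase the diameter up to an additional 20 µm" (which
would mean +10 µm of radius). These are mutually inconsistent; the
package defaults to the radius reading — 20 µm for microglia, 50 µm
for astrocytes — and exposes `interpretation = "diameter"` on
`dilate_labels()` so the alternative can be computed rather than
silently resolved.

# The synthetic scene generator

`render_scene()` rasterizes disk plaques (stated peak intensity,
pixelwise maximum where disks overlap, overlap flagged as merged), disk
somata (marker-positive cells only) and disk nuclei (all cells) onto a
constant background with additive Gaussian noise clipped at zero,
one independent noise draw per channel, all derived from one seed. A
pixel belongs to a disk iff its centre is within the radius — no
anti-aliasing — so disk areas have exact pixel-counting oracles.
Channels never bleed into one another (crosstalk is out of scope).

Ground truth records continuous geometry: each cell's exact distance to
the nearest plaque boundary circle and to the nearest plaque region.
The rasterized mask boundary deviates from the continuous circle by up
to about √2/2 px diagonally, so raster-derived boundary distances agree
with the ground truth only to within a one-pixel band; recovery checks
therefore exclude cells whose effective distance falls within ±1 px of
the association radius, and match everything else exactly.

Defaults encode the reference acquisition: 1024 × 1024 px, 0.63 µm/px,
background mean 10 and noise sd 2 (arbitrary intensity units), soma
radius 5 µm, nucleus radius 3 µm, plaque radii 8–20 µm with peaks
80–160. The staining-intensity and background distributions are
conventions chosen to be cleanly separable by a global threshold — the
source study does not publish them — so passing recovery tests
demonstrates correctness of the measurement chain on well-separated
objects, not robustness to real-world artefacts (uneven illumination,
touching cells, autofluorescence, z-leakage).

# Expression model

## Simulation

`simulate_expression()` draws counts NB(µ, size = 1/φ) with
µ = baseline · 2^effect · L_s, where L_s is a per-sample log-normal
library factor (σ = 0.2 by default, so normalization has something to
remove) and φ is the NB dispersion (default 0.05, i.e. ~22% biological
CV at high counts — a realistic replicate-to-replicate spread for a
hybridization panel). A Poisson background (mean 20) is added to every
probe; negative-control rows carry background only and are not scaled
by L_s, because background in a hybridization assay is additive rather
than proportional to input. The default panel is 770 genes including
the ten housekeeping genes (Csnk2a2, Ccdc127, Xpnpep1, Lars, Supt7l,
Tada2b, Aars, Mto1, Tbp, Fam104a), which carry zero planted effect by
construction.

The canonical three-group layout (control, disease, treated) plants
`n_up` genes (default 99) at +3 log2 units in disease vs control —
large enough that downstream classification is exact — and gives a
fraction (default 71/99) a treated-vs-disease effect of −1.5 log2 units
(reversal) while the rest continue at +0.75 (no reversal).

## Processing

*Background subtraction* removes, per sample, mean + k·sd of the
negative controls (k = 2 by default). This is a common convention for
such panels, not a published fact of the original analysis, and k is a
parameter. Subtraction floors at zero and deliberately over-subtracts
by 2 negative-control standard deviations relative to the mean
background.

*Normalization* scales sample s by f_s = G_ref/G_s with G_s the
geometric mean of the sample's housekeeping counts and G_ref the
geometric mean of all G_s. Afterwards every sample's housekeeping
geomean equals G_ref; the transform is idempotent. Because G_ref
itself depends on all samples, multiplying one sample's raw counts by
c rescales the whole normalized matrix by the single global factor
c^(1/n): the normalized *profile* and every cross-sample comparison
are invariant, and that is the invariance the tests assert. A zero
housekeeping count makes the geometric mean degenerate and is an
error naming the gene and sample.

*DEG calling* uses the linear fold change of normalized group means
(reported fold changes in this assay family are conventionally linear)
and, as primary p-value, the Tukey-adjusted pairwise comparison from a
one-way ANOVA across all groups; with exactly two groups a Welch t-test
is used. Both Tukey and Welch p-values are emitted because volcano
plots in the source literature are ambiguous about which pairwise p
they display. Thresholds are strict: up requires FC > 1.5 and
p < 0.05, down FC < 0.66 and p < 0.05, so a fold change of exactly 1.5
is not significant. A zero denominator mean leaves the fold change
undefined (record flagged, excluded from classing); a zero numerator
mean receives a 0.5 pseudo-count on both means for the ratio only, so
log fold changes stay finite.

*Reversal statistic*: over the disease-contrast DEGs (class up or
down), a gene is reversed iff the sign of its treatment-contrast log
fold change is opposite to the disease direction. Direction only — no
significance requirement on the treatment side, because the claim being
quantified is that treatment pulls expression back toward control, not
that it does so significantly per gene. A treatment fold change of
exactly 1 is not a reversal.

## Calibration properties

Under the global null the caller's rejection rate is close to the
nominal α (slightly conservative when library factors are present).
The *across-replicate variance* of that empirical rate exceeds the
binomial variance by roughly a factor of 4–9, because dividing every
gene by the same noisy housekeeping geomean induces weak positive
correlation among genes. This is a property of geometric-mean
normalization itself, worth remembering when interpreting panel-wide
false-positive counts. With more than two groups the Tukey-adjusted
pairwise p is family-wise conservative by construction; the
calibration suite therefore evaluates the two-group (Welch) path.

# Group statistics

`compare_groups()` reports per-group n, mean and SEM (sd/√n), a
one-way ANOVA with Tukey's range test for ≥ 3 groups or an unpaired
Student t-test for exactly 2 (mirroring the convention of the source
analyses; the DEG caller's two-group fallback is Welch because
expression variances are rarely equal), and significance stars at
0.05/0.01/0.001/0.0001, boundaries falling on the less significant
side. All-constant inputs return statistic 0 and p 1 rather than an
error, so degenerate measures (e.g. identical plaque counts in every
field) flow through pipelines.

# Numerical and design choices

- EDT: exact Euclidean transform (verified against brute force);
  per-label transforms give nearest-plaque assignment with strict-<
  updates so ties go to the lower label.
- 8-connectivity via 4-connected labelling plus a union-find merge of
  diagonally adjacent components; verified against a flood-fill oracle.
- Otsu threshold computed on the channel rescaled to [0, 1] with 256
  histogram levels, returned in original units; constant channels have
  no foreground.
- TIFF export quantizes intensities to 16 bits under a recorded
  full-scale value; a YAML sidecar carries channel names and
  calibration. Tables are plain CSV; reversal summaries JSON; run logs
  JSON lines. Given one seed, pipeline tables are byte-identical across
  runs.
- Seeds: every generator takes one integer seed; the pipeline derives
  per-field seeds from the base seed by a fixed affine map modulo
  2^31 − 1.

# Verification problem sizes

The test suite exercises: 50 random 128 × 128 label masks × radii
{0, 5, 20, 50} µm for the dilation/morphology equivalence; 20
noise-free full-geometry (1024 × 1024) scenes for exact ground-truth
recovery; 1,000 null genes at n = 10/group for type-I calibration and
200 planted genes at n = 50/group for fold-change recovery; 20 random
small datasets for the ANOVA/Tukey oracle (agreement to 1e-8). The
standalone results script repeats these at 20 masks and 10 fields.
These sizes are the package's choice of a thorough-but-quick battery;
all expected values are computed by independent oracles (brute-force
distance transforms, disk-stamp dilation, flood fill, first-principles
F and studentized-range probabilities), never copied from the
implementation under test.

# Known limitations

- 2D single-plane fields only; no z-stacks, PSF or optics simulation.
- Global thresholding only; no adaptive or machine-learned
  segmentation, no separation of touching cells.
- The synthetic scenes use circular objects and well-separated
  placement; recovery results do not certify behaviour on confluent or
  irregular morphology.
- Expression processing assumes the housekeeping panel is truly
  unregulated; violations bias all fold changes multiplicatively.
- Resource-equation sample-size planning from the source methodology is
  documentation-only; no power tooling is included.
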