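---
title: "Quantifying non-autonomous effects of mosaic gene deletion in epithelia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying non-autonomous effects of mosaic gene deletion in epithelia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaictile)
library(dplyr)
```

## The problem

Planar cell polarity (PCP) genes such as *Vangl2* are required for neural
tube closure. When a PCP gene is deleted *mosaically* — in a random subset
of neuroepithelial cells, lineage-traced by a membrane-reporter switch
(tdTomato to EGFP) — the phenotype is not confined to the deleted cells.
Gene-replete cells that *touch* a deleted cell fail to constrict their
apical surface, while replete cells with no deleted contact behave
normally. Because an epithelial cell has on average six neighbours
(Lewis' law), each deleted cell can silence several replete ones, so a
small deleted fraction is amplified into a large non-constricting
fraction — but cells share neighbours, which caps the amplification.

`mosaictile` implements the quantitative pipeline for this analysis:

1. **Mosaic classification** — call cells EGFP+/EGFP− from fluorescence,
   build the apical neighbour graph, and label cells *deleted*,
   *neighbour* (replete, touching a deleted cell) or *distant*.
2. **Neighbour-sharing statistics** — Lewis'-law fits, the fraction of
   replete cells neighbouring a deleted cell, unique neighbours per
   deleted cell, and a closed-form lattice model of all of these.
3. **Constriction kinetics** — alignment and comparison of pulsatile
   apical-area time series, ablation-retraction analysis with the embryo
   as the unit of measure, and the two-group sample-size calculation.
4. **Border and cap/cortex intensity** — junctional signal by border
   class and the cap-versus-cortical myosin pattern split.
5. **A synthetic-epithelium generator** providing ground truth for all of
   the above, so every step can be validated without microscope data.

## The classification model

The EGFP call uses two one-sided pixel-fraction rules on a channel
rescaled to \[0, 1\]: a cell is EGFP+ when at least 75% of its
intracellular pixels exceed 0.08, EGFP− when at least 75% fall below
0.06. Intensities between the thresholds support neither rule, so a cell
can satisfy neither: such cells are reported `UNCLASSIFIED`, excluded
from all class counts and denominators, but allowed to carry graph
edges — silently forcing a call would fabricate data. All three
thresholds are exposed as arguments.

Neighbourhood is defined by mask dilation: two cells are adjacent when
the dilation of one label (3 × 3 square element, applied `radius` times;
corner contacts count) overlaps the other. The default radius of 1 px is
the minimal dilation that bridges a one-pixel watershed line between
touching segments. Border cells are handled before any of this: every
label with at least one pixel inside the 30-px image margin is removed
entirely, because truncated masks would bias area and perimeter.

## The neighbour-sharing model

For independent Bernoulli(*p*) deletion on a lattice of degree *k*, the
probability that a replete cell touches at least one deleted cell is

  *f*(*p*) = 1 − (1 − *p*)^*k*,

and the expected number of *unique* replete neighbours per deleted cell
is

  *u*(*p*) = (1 − *p*) *f*(*p*) / *p*,  with *u*(0⁺) = *k*, *u*(1) = 0.

*f* increases and *u* decreases strictly on (0, 1): single deleted cells
have the largest per-cell impact at low recombination, and
neighbour-sharing limits amplification as recombination rises. The
degree-distribution generalisation `1 − Σ q_k (1 − p)^k` is exact under
independence; the *u* formula assumes a *k*-regular graph and is an
approximation for degree-heterogeneous Voronoi mosaics (the package's
tests quantify the agreement by simulation).

```{r closed-form}
analytic_neighbour_model(c(0.05, 0.16, 0.5))
```

## The synthetic epithelium

`generate_tessellation()` builds either a Lloyd-relaxed Voronoi
tessellation (realistic degree heterogeneity) or an exact hexagonal
lattice, on a periodic (toroidal) or bounded domain. Periodic domains are
the default for statistical validation: every trivalent tessellation on a
torus has mean degree exactly 6 by Euler's formula, giving a sharp truth
for graph-reconstruction checks, whereas bounded domains emulate a
microscope field of view with boundary effects (and are analysed with
border exclusion, as real images are).

```{r tess}
tess <- generate_tessellation(tessellation_spec(300, c(256, 256), seed = 1))
tess
ras <- rasterize_labels(tess)
mos <- assign_mosaic(tess, p = 0.16, seed = 2)
ch  <- render_channels(ras$labels, mos, render_spec(noise_sd = 0, psf_sigma = 0))
calls <- classify_egfp(ras$labels, ch$egfp)
graph <- build_neighbour_graph(ras$labels, periodic = TRUE)
classes <- assign_cell_classes(graph, calls)
neighbour_count_summary(graph, classes)
```

The renderer reproduces the membrane-reporter geometry: tdTomato signal
on all membranes, EGFP only on membranes of recombined cells, plus a
configurable cytoplasmic EGFP fill (default 0.15 of the membrane level).
The fill matters: real recombined cells carry diffuse EGFP, and it is
this diffuse signal that makes an *intracellular* pixel-fraction
threshold meaningful. Gaussian PSF blur and additive noise complete the
model. Synthetic channels are calibrated to \[0, 1\] by construction;
the min–max rescale step (`rescale_unit_interval()`) exists for
arbitrary-scale microscope data and is deliberately skipped for
noise-free synthetic fields with no background reference (an
all-recombined field has no zero anchor, and rescaling would corrupt the
calls).

### What the generator does and does not emulate

It emulates: near-trivalent tessellation topology, Bernoulli mosaicism,
membrane-localised two-channel fluorescence, class-dependent single-pulse
area dynamics, hierarchical (embryo/cell) ablation retraction, and
embryo cohorts whose neural-fold eversion is linear in the
neighbour-class fraction. It does not emulate: pseudostratified 3-D
geometry, cell division or neighbour exchange during imaging,
photobleaching or drift, spatially clustered recombination, or
planar-polarised cell elongation. Passing round-trip tests therefore
demonstrates the correctness of the measurement code under the stated
statistical structure, not robustness to every property of real images.

## Area-trace kinetics

Live-imaged cells pulse asynchronously, so traces are aligned at each
cell's largest observed area (T = 0, ties to the earliest timepoint) and
expressed as % of the per-cell maximum. Negative aligned times are
dilation, positive times constriction. Group comparisons first average
cells within embryo, then apply Welch t-tests across embryo means per
aligned timepoint with Bonferroni correction — a deliberately
conservative replacement for mixed-model machinery whose random-effects
structure would otherwise need to be specified, and one that makes the
embryo the unit of measure (cells from one embryo are not independent;
the package's tests show cell-level pooling inflates the null rejection
rate while embryo-level averaging calibrates it to α).

The generator's dynamics use a single dilation ramp to a uniformly drawn
interior peak followed by a linear constriction decay — one pulse per
window, because the analysis aligns at a single maximum within a short
(20-min, 1-min sampling) recording. Class defaults encode the studied
phenotype and are free parameters where the source data give no
magnitude: control/distant dilate at 0.015 /min and constrict at
0.020 /min; deleted cells dilate twice as fast (0.030 /min) and
constrict normally; neighbour cells dilate normally and do not constrict
at all. Per-cell rates vary lognormally (CV 0.2) and measurement noise
is multiplicative (SD 0.05).

```{r kinetics}
spec <- dynamics_spec(seed = 7)
traces <- simulate_area_traces(make_trace_cohort(5, 8), spec)
aligned <- align_at_max(traces)
head(group_mean_trace(aligned))
compare_groups_per_timepoint(aligned, "neighbour", "control") |>
  filter(p_adjusted < 0.05)
```

### A known artifact of max-alignment

Aligning at the largest *observed* area interacts badly with cells that
genuinely do not constrict. Their post-peak trace is a flat plateau, so
under measurement noise the observed argmax lands wherever the noise
happens to peak — on average several minutes after the true peak. Their
"pre-peak" aligned values are then contaminated with plateau points and
sit systematically above a constricting reference group at negative
aligned times. With the default generator settings this bias is a few
percent of maximal area and is regularly Bonferroni-significant; it is a
property of the alignment procedure itself, not of the underlying
dynamics, and should be kept in mind when interpreting pre-peak
differences involving non-constricting cell classes. (Really pulsatile
cells, whose maxima are sharp, are far less affected.) For this reason
slope summaries in the package's tests start one timepoint after T = 0,
where the same selection effect biases the first step down for every
group.

## Ablation retraction and the sample-size calculation

Retraction is the percentage area change of a cell or cluster
immediately after annular ablation (negative = retraction; the measure
is scale-invariant). Per-cell values are averaged within embryo and cell
type before testing. `sample_size_two_group()` returns the smallest
integer group size reaching a target power for a two-sample t-test,
using exact noncentral-t power; the pilot-style calculation for a
difference equal to one SD at α = 0.05, power 0.8 gives n = 17. The SD
underlying any published pilot n is an input here, not a constant: it is
not recoverable from a reported n alone.

## Border classes and cap/cortex patterns

Signal on a cell–cell border is shared between the two adjacent cells,
so junctional intensity is summarised per *border class*:
deleted–neighbour, neighbour–neighbour and distant–distant borders are
the three analysed contrasts; every other pair (including any border
with an unclassified endpoint) is `OTHER` and excluded, since pooling
mixed pairs would dilute the contrast. Per-embryo normalisation to a
reference class = 100% is provided for cross-embryo comparability.

The cap/cortex split erodes each cell by `erosion_r` px (default 2,
square element, matching the graph's dilation convention): the eroded
core is the medio-apical cap, the rim the junctional cortex. A cell is
`CAP` when the cap/cortex mean-intensity ratio ≥ θ (default 1; a uniform
cell classifies as CAP by this boundary convention, which is exposed as
an argument). Both θ and `erosion_r` are this package's constructions —
the visual classification they stand in for has no published numeric
criterion — and the defaults are chosen to reproduce the unambiguous
cases (signal only on the rim → CORTICAL; only in the core → CAP).

## Numerical choices and conventions

- **Orientation**: the acute angle between the apical long axis
  (equivalent-ellipse convention, axes = 4√eigenvalue of the pixel
  covariance) and the rostrocaudal image-row axis, folded to \[0, 90\]°
  with 90° = mediolateral. Images must be acquired or generated with RC
  along rows. Folding assumes axial (undirected) orientations.
- **Perimeter**: length of the traced 8-connected boundary contour
  (unit and √2 steps). Pixelated perimeters are convention-dependent;
  this convention is fixed and stated.
- **Solidity**: pixel count over the boundary-inclusive pixel count of
  the filled convex hull of pixel centres.
- **Median** of an even-count sample: midpoint of the central pair.
- **Orientation histograms**: 10° bins over \[0, 90\] by default
  (configurable); χ² homogeneity tests apply Yates continuity correction
  only to 2 × 2 tables.
- **Fisher's exact test** (two-sided): sum of hypergeometric
  probabilities of tables no more probable than the observed one — the
  convention of `stats::fisher.test`, stated because tail-doubling
  variants differ.
- **Ties at maximum area**: earliest timepoint.
- **Degenerate inputs**: constant channels refuse to rescale; empty
  classes abort or warn rather than returning silent zeros; single-pixel
  cells are flagged as degenerate; erosions that empty a cell leave its
  pattern undefined.
- **Seeds**: every stochastic operation takes one integer seed; cohort
  operations derive child streams deterministically, so any member is
  reproducible in isolation.

## Validation scales

The test-suite and acceptance computations run at deliberately chosen
problem sizes: 1000-cell Voronoi epithelia (800² px) for topology
recovery, 10⁴-cell hexagonal lattices for closed-form agreement
(8 mosaic replicates per deletion fraction, agreement within 3
Monte-Carlo SE), 20 simulated live-imaging cohorts (3 × 36 cells, 5
embryos) for kinetics, and 1000 null cohorts (5 + 5 embryos, 3 cells
each) for type-I calibration. These sizes give Monte-Carlo errors well
below the effects under test while keeping a full validation run in the
order of a minute.

## Limitations

- The closed-form *u*(*p*) is exact only on regular lattices; on Voronoi
  mosaics it is an approximation whose error grows with degree variance.
- Max-alignment biases pre-peak values of non-constricting classes (see
  above).
- The generator's eversion model is linear with Gaussian embryo noise —
  adequate for testing correlation machinery, not a biomechanical model.
- No spatial clustering of recombination is modelled; real Cre mosaics
  can be clonally clumped, which raises deleted–deleted adjacency above
  the Bernoulli expectation and lowers both *f* and per-deleted
  neighbour counts.
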