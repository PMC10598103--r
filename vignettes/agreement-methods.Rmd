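---
title: "Measuring interobserver agreement of target volume delineations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring interobserver agreement of target volume delineations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segagree)
```

## The problem

In stereotactic body radiotherapy (SBRT) of pancreatic cancer, several
experts delineating the same lesion on the same imaging produce visibly
different contours. `segagree` measures that disagreement for the three
clinically relevant volumes — the gross tumour volume (GTV), the internal
target volume (ITV, the GTV's envelope over respiratory motion), and the
planning target volume (PTV, the ITV plus a setup margin) — by comparing
every pair of observers and summarising the pairwise values.

No single geometric index captures delineation disagreement: an overlap
score cannot distinguish a size error from a position error, and a volume
score is blind to position entirely. The package therefore computes a
quartet per observer pair. With `tp`, `fp`, `fn` the voxel counts of
$A\cap B$, $A\setminus B$, $B\setminus A$:

* **DSC** $= 2tp/(2tp+fp+fn)$ — overlap, range $[0,1]$, higher is better.
* **HD** — the symmetric Hausdorff distance in mm: the larger, over both
  directions, of the greatest distance from a voxel centre of one mask to
  the nearest voxel centre of the other, with anisotropic physical
  spacing. Outlier-sensitive by construction; lower is better. The
  maximum (100th percentile) directed distance is used — not HD95 — since
  no percentile qualifier applies here.
* **PBD** $= (fp+fn)/(2tp)$ — the probabilistic distance in its binary
  form; penalises misalignment of correctly sized volumes. For binary
  masks it satisfies $\mathrm{PBD} = (1-\mathrm{DSC})/\mathrm{DSC}$
  whenever $tp>0$; disjoint pairs give $+\infty$. The general fuzzy form
  (whose range extends to $-1$) is out of scope.
* **VS** $= 1 - |fp-fn|/(2tp+fp+fn)$ — volumetric similarity: compares
  sizes only, assuming alignment is optimal. $VS \ge DSC$ always, with
  equality iff $\min(fp,fn)=0$.

The Jaccard index, $\mathrm{JCI} = \mathrm{DSC}/(2-\mathrm{DSC})$, is
provided for comparability with studies that report it.

True negatives appear in no formula. The package makes this exact rather
than approximate: before any distance transform, mask pairs are cropped
to the union bounding box of their set voxels, so even the floating-point
trajectory of the Hausdorff computation is independent of how much
background surrounds the contours. Padding a cohort with background
changes nothing, bit for bit.

## Geometric conventions

Masks live on an `image_grid`: axis order (slice, row, column), positive
spacings in mm, and a voxel-centre origin — the physical position of
voxel $(i,j,k)$ (zero-based) is $\mathrm{origin} + (i,j,k)\cdot
\mathrm{spacing}$. Metrics demand identical grids (spacing within
$10^{-6}$ mm, origin within $10^{-3}$ mm — enough to absorb format
round-trip noise, not enough to accept different geometry). Resampling is
never silent: `resample_nearest()` is an explicit, logged step
(nearest-centre rule, midpoint ties to the lower index), because
resampling changes metric values and must stay auditable.

Degenerate inputs are defined exactly where the formulas are: with both
masks empty every metric errors; with one empty mask DSC, JCI and VS are
0, PBD is $+\infty$, and HD is undefined (`metric_quartet()` returns
`hd_mm = NA` and names it in `undefined`).

## Pairwise engine and summaries

All comparisons are performed between all observers: $\binom{n}{2}$
unordered pairs per (case, volume kind), each computed once. Observers
who did not submit a given volume are omitted from that group with a
logged count — ragged participation is normal in multi-observer studies.
Summaries report minimum, maximum, mean, median and std per metric:

* median with midpoint interpolation for even counts (even-count medians
  are the usual source of small DSC/PBD rounding inconsistencies in
  printed tables, which is why the identity
  $\mathrm{PBD}=(1-\mathrm{DSC})/\mathrm{DSC}$ can appear violated at
  two decimals);
* sample (n−1) standard deviation, 0 for a single pair;
* infinite PBD values (disjoint pairs) excluded from mean/std with a
  warning, kept as the largest value for min/max/median;
* pooled "all patients" blocks concatenate the per-case pairwise values
  — they are not means of per-case summaries.

Values are rounded (half-even, 2 decimals) only at serialization; all
internal arithmetic is full precision, so the algebraic identities hold
to $10^{-12}$ in tests. Output row order is deterministic (cases
lexically, kinds GTV < ITV < PTV), and reports are byte-identical across
runs for the same inputs.

## Hausdorff distance: implementation and verification

HD is computed from an exact anisotropic Euclidean distance transform
(separable lower-envelope algorithm, compiled code): each mask's
transform gives the distance from every voxel centre to that mask, and
the symmetric HD is the root of the larger of the two directed maxima.
This voxel-point-set definition is deterministic and spacing-aware; a
surface-based continuum definition would differ by at most a voxel
diagonal. An independent $O(|A||B|)$ brute-force oracle
(`hausdorff_bruteforce_mm()`) is part of the public API, and the test
suite requires agreement within $10^{-9}$ mm on hundreds of seeded random
pairs.

## File formats

The native mask exchange format is a minimal NRRD single-volume
container (3-D, uint8, axis-aligned directions, `ascii` or `raw`
encoding) — chosen because it is a standard neuroimaging container whose
header is plain text. Contour input uses a JSON structure-set dialect
mirroring clinical RT structure sets: planar closed polygons as
patient-coordinate $(x,y,z)$ triplets grouped by ROI name, with a
planarity check of $10^{-3}$ mm. Rasterization is even-odd
centre-sampling: a voxel is set iff its centre lies inside an odd number
of that slice's polygons, so disjoint contours union and nested contours
carve holes under one rule, independent of vertex orientation; a centre
exactly on an edge counts as inside (deterministic tie-break). Polygons
are assigned to the nearest slice within half a slice spacing, else
dropped with a warning. The rasterizer is verified against an
independent per-voxel point-in-polygon oracle.

## The synthetic cohort: a stated world

The motivating study's imaging cannot be redistributed, so the package
ships a generator whose defaults state the world the pipeline is tested
in — they are conditions, not tuning knobs:

* **3 cases** with target median GTV volumes 31.75, 45.3 and 45.7 ml
  (the per-case medians the emulated cohort reported), on 128³ grids at
  2 mm isotropic spacing;
* **19 observers** per case (the number of structure sets evaluated per
  case there);
* tumours are **star-convex**: radius field $r(d) = r_0(1 + \sum_{l=1}^{4}
  \sum_m a_{lm} Y_{lm}(d))$ with $a_{lm}\sim N(0, 0.05^2)$ and $r_0 =
  (3V/4\pi)^{1/3}$. Degree 0 is excluded: a constant term only rescales
  the mean radius, which $r_0$ already carries, so excluding it keeps the
  expected volume on target (the quadratic volume bias from zero-mean
  perturbations is ~1.5%, well inside the 15% volume contract);
* each **observer** adds a systematic radial bias (drawn once per
  observer from $N(0, 1.5\,\mathrm{mm}^2)$) plus a smooth zero-mean
  spherical-harmonic field of degree ≤ 6 with pointwise sd 2 mm
  (roughness). The per-coefficient variance is set via the addition
  theorem so the pointwise sd is exactly the requested roughness. These
  defaults put median pairwise GTV Dice near 0.8, inside the 0.6–0.81
  band such expert cohorts report;
* the **ITV** is the union of the GTV translated by $A\sin(2\pi p/10)$
  over 10 respiratory phases, amplitude 5 mm cranio-caudal (slice axis),
  translations rounded to whole voxels (halves away from zero, keeping
  the envelope symmetric) — a desk-scale stand-in for a 4D-CT envelope
  under abdominal compression;
* the **PTV** is the ITV expanded by a 5 mm isotropic Euclidean margin
  (distance-transform thresholding). The study states no margin recipe;
  5 mm is a typical SBRT-scale choice, stated once here.

Seeds derive as `base_seed·10000 + case·100 + observer`, so cohorts are
bit-reproducible across machines; the observer's bias and boundary field
use separated streams (offset +50) within that scheme.

What the generator does **not** emulate: real pancreatic tumour shapes
(star-convexity excludes concavities and disconnected components),
imaging appearance and modality effects (which were the study's clinical
question), deformable intra-observer motion, or organ-at-risk anatomy. A
green simulator test therefore establishes that the *metrics pipeline*
behaves correctly on controlled inputs with known truth — not that any
clinical conclusion transfers.

## Numerical choices

* Distance transform thresholds use an absolute $10^{-9}$ slack
  ($d^2 \le m^2 + 10^{-9}$) so exact lattice distances at the margin are
  kept on all platforms.
* `line_mask_pair()` realizes prescribed overlap counts as intervals on
  a line grid; metric values that the count formulas force (the printed
  median-PBD anchors among them) are reproduced through the full mask
  pathway, not from the counts directly.
* The motion-envelope rounding uses halves-away-from-zero, not banker's
  rounding, so symmetric sine displacements give symmetric voxel offsets.
* Radius fields driven non-positive by extreme perturbations are clipped
  at one voxel with a warning (at the default roughness this never
  triggers; at 4 mm it occasionally does).

## Known limitations

* HD is defined on voxel centre point sets; sub-voxel surface placement
  is not modelled (differences vs. a continuum surface HD are bounded by
  a voxel diagonal).
* The probabilistic distance is implemented only in its binary form; the
  fuzzy generalisation (range $[-1,\infty)$) is out of scope.
* NRRD support is deliberately minimal (axis-aligned, uint8, ascii/raw);
  DICOM itself is not read or written — contours travel via the JSON
  structure-set dialect.
* Grid harmonization is nearest-neighbour only; interpolating resamplers
  for fractional-voxel registration are out of scope.
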