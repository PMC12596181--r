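---
title: "Curating cryoEM map-model datasets: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating cryoEM map-model datasets: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryocurate)
```

## The problem

Deep-learning tools that interpret cryoEM density maps — secondary-structure
segmenters, backbone tracers, nucleotide classifiers — are trained on voxel
datasets built from public archive depositions: density maps from the EMDB
paired with atomic models from the PDB. Raw depositions are a poor training
set as-is. Many entries depict the same macromolecule in slightly different
states (ribosomes are the extreme case), some fitted models disagree badly
with their maps, density scales vary wildly between microscopes and
reconstruction pipelines, and voxel sizes are inconsistent. `cryocurate`
implements an end-to-end curation pipeline that turns an EMDB search query
into a quality-filtered, labeled, subvolume dataset, with every filtering
decision recorded in an auditable report.

The pipeline has three stages, each independently rerunnable from its
on-disk artifacts:

1. **fetch** — retrieve entry metadata (or read it from an offline cache).
2. **curate** — metadata filters (completeness, Q-score, two-tier
   redundancy), then per-entry map conditioning (resample, adaptive
   normalize) and map-model fitness validation.
3. **build** — voxel labeling, subvolume partitioning, train/val/test
   splitting, NPY serialization.

## Metadata curation

**Completeness.** Entries missing a fitted PDB ID, a resolution, or a
recommended contour level cannot be processed and are removed. Within
groups sharing a title, only the best-resolution member survives.
"Best resolution" throughout the package means the numerically smallest
Angstrom value, with ties broken by lexicographically smallest EMDB
accession so that every filter is deterministic.

**Q-score filter.** The deposited Q-score summarizes atom-level
resolvability of the map-model pair (1 = perfect fit). Entries strictly
below the threshold (default 0.4) are discarded. Entries *without* a
Q-score are also discarded, under a distinct reason code, rather than
passing silently: an unscored pair gives no evidence of quality, and
letting it through would make the filter's guarantee vacuous.

**Two-tier redundancy filtering.** Redundancy is proxied by UniProtKB and
AlphaFold cross-references. We merge the two namespaces into one
deduplicated accession set per entry, because AlphaFold accessions are
UniProt-derived and the two therefore describe the same protein content;
per-namespace comparison is available via the `namespace` argument for
users who want it.

- *Uniqueness filtering* collapses groups with **identical** sets to their
  best-resolution member, and flags entries with no cross-references at all
  (they cannot be compared, so they are set aside for manual review rather
  than silently kept or dropped).
- *Similarity filtering* controls partial redundancy. Pairwise overlap is
  quantified by **containment**, |A∩B| / min(|A|, |B|), by default: a
  sub-complex whose references are a subset of a larger complex's scores
  1.0 and is treated as redundant with it, which is the behaviour one wants
  for, say, isolated ribosomal subunits versus full ribosomes. Jaccard
  (|A∩B| / |A∪B|) is selectable for users who consider a subset a genuinely
  different structure. The filter is a greedy sweep in best-resolution-first
  order: an entry is retained iff its overlap with every already-retained
  entry is at most the threshold (default 0.70). We chose the greedy sweep
  over connected-component clustering because it directly yields the
  guarantee that *every retained pair* respects the threshold, and it keeps
  the highest-resolution member of each redundant neighbourhood — both
  properties are asserted by brute force in the test suite. The same
  overlap computation, exposed as `pairwise_similarity_matrix()`, serves
  for dataset-level redundancy assessment over any identifier sets (e.g.
  InterPro domain annotations).

Every stage returns a `curation_report`; the invariant
`retained + discarded + flagged = input` holds per stage and is checked on
randomized tables.

## Map conditioning

**Resampling.** Maps are resampled to a uniform voxel size (default
1.0 Å) by separable per-axis interpolation: each axis is rescaled by
original voxel size / target, output dimensions are round-half-up of
dim × factor, and output index *i* reads input coordinate *i*/factor with
edge clamping. The default interpolant is a natural cubic spline per grid
line (order 3), which reproduces constants and linear ramps exactly;
order 1 (linear) is available when strictly range-bounded output matters.
The origin is preserved so the model's coordinate frame stays valid.

**Adaptive contour-anchored normalization.** Fixed-threshold denoising
(drop everything below zero, rescale the rest) ignores how differently
individual maps distribute their density. Instead we anchor denoising to
each deposition's *recommended contour level* c — the density at which the
molecular surface is meaningfully rendered. The denoise threshold t is
chosen so that c sits at the 85th percentile (configurable fraction p) of
the retained values {v : v ≥ t}. With nearest-rank percentiles
(ceiling convention on the ascending sort, "above contour" strict) this
has a closed form: if N voxels lie strictly above c, the retained set must
hold k = round(N / (1 − p)) values and t is the k-th largest voxel value.
We adopted nearest-rank precisely because it makes this closed form exact;
the test suite checks it against an exhaustive scan over all candidate
thresholds. Values below t are zeroed; values at or above map linearly
onto [0, 1] with t at 0 and the map maximum at 1.

Two degenerate inputs make normalization impossible and remove the entry
from the pipeline (tallied in the report): a contour at or above the map
maximum, and a contour below the map's own p-percentile (k would exceed
the voxel count). When both resampling and normalization apply, resampling
runs first, so the threshold is derived from the grid that the labels will
be built on.

## Map-model fitness: the Volume Overlap Fraction

The Q-score is residue-local; it misses global pathologies such as a model
covering only half the map, or substantial model regions with no
supporting density. Full 3-D correlation scoring is expensive, so global
coherence is checked on 2-D projections instead. The map (normalized) and
the model (voxelized: a voxel is 1 iff its center lies within a radius,
default 1.5 Å, of a heavy atom) are each projected along six directions —
the three principal axes and three diagonal line-sum orientations — by
summing voxel values along the projection lines. The diagonal projections
sum over discrete lines of constant (x−y, z), (x, y−z) and (x−z, y); we
chose exact integer-indexed line sums over interpolated rotations to keep
the operation exact and cheaply testable against a brute-force loop.
Each projection is binarized at ≥ 1 and each direction scored by IoU. The
**VOF** is the mean IoU over the five lowest-scoring directions — the best
direction is dropped to blunt directional bias (a model that looks good
only edge-on should not be rescued by that one view). Ties for the dropped
direction resolve to the first in the fixed order X, Y, Z, D_xy, D_yz,
D_xz. A direction where both projections are empty scores 1 (no mismatch
evidence); one-sided emptiness scores 0. A Dice-like coefficient
(overlap / summed mask sizes — Dice without the factor 2) is reported
alongside, averaged over the same five directions for symmetry with the
VOF. Pairs below the VOF threshold (default 0.82) are discarded.

The voxelization radius for fitness scoring defaults to the labeling
radius (1.5 Å) and is configurable; nothing in the scoring depends
critically on it as long as it is commensurate with the voxel size.

## Structural labels and dataset assembly

Atoms are selected by three conjunctive tiers — secondary-structure class,
residue type, atom name — mirroring how practitioners describe labeling
targets ("all Cα in helices"; "the Mg ion": `ss = "none"` targets
non-polymer atoms). Secondary structure comes from the deposited
HELIX/SHEET (or `struct_conf`/`struct_sheet_range`) annotations, not a
geometric assigner: depositions carry the authors' own assignment, and
recomputing it would silently disagree with the models users inspect.
Models without annotation blocks default all protein residues to coil (a
logged fallback). Multi-model files contribute their first model only, and
only first alternate locations are kept, which keeps atom order — the
package's universal tie-breaker — deterministic.

Each voxel whose center (grid-node convention: origin + index × voxel
size) lies within the labeling radius (default 1.5 Å) of a selected atom
receives the label of the **nearest** such atom; conflicts between rules
are resolved globally by distance, not rule priority, and exact ties go to
the atom earlier in file order. A triple-loop brute force reproduces the
operation exactly on small grids in the test suite; the canonical
single-atom case (radius 1.5 Å on a 1 Å grid) labels exactly 19 voxels.

Map and label volumes are cut into cubic patches (default 64³ voxels)
with corners at stride multiples and zero-padding at the far faces; with
stride = patch the patches tile the padded volume exactly and stitching
them back is bit-identical. Splitting into train/val/test uses a seeded
shuffle and largest-remainder apportionment, so realized counts are within
one unit of the requested ratios. The default granularity is **entry**:
whole entries go to a single split, preventing near-duplicate subvolumes
of one structure from leaking across the train/validation boundary.
Subvolume granularity (the classic 80:20 patch split) is available when
entry counts are too small to split meaningfully. Patches are serialized
as NPY arrays (float32 maps, int32 labels, C order) under `train/`,
`val/`, `test/`, with a manifest CSV tying every patch to its entry,
corner and split.

## Evaluating voxel-wise predictions

Predictions arrive as per-voxel probability vectors over N classes (class
0 = background). Discretization assigns the argmax among non-background
classes strictly exceeding the threshold (0.8 by convention for
secondary-structure U-Nets; 0.4 for nucleotide-group predictors), with
label 0 as fallback and exact ties to the lowest class index. Confusion
tables are one-vs-rest per label; accuracy, precision, recall and F1
follow the standard formulas, with zero-denominator cases reported as 0
plus an explicit `undefined` flag rather than NaN (a NaN in a summary
table tends to poison downstream aggregation silently). Aggregate
precision/recall/F1 micro-average the non-background labels — background
dominates voxel counts so including it would hide all signal — while
aggregate accuracy is the plain multi-class voxel agreement including
background, matching how the two kinds of summary are conventionally
reported side by side.

## The synthetic data generator

`synth_map_model()` renders pseudo-atom layouts (an ideal α-helix Cα
trace with a consistent HELIX annotation, a nucleic A/U/G/C ladder, or
random atoms) as sums of isotropic Gaussians (default σ = 1.5 Å) plus
i.i.d. Gaussian noise (default sd = 0.02), and reports a contour level
placed at the 95th density percentile so that normalization is anchorable
by construction. `synth_metadata()` builds entry tables whose
cross-reference sets realize a controlled redundancy structure (duplicate
groups, nested subset chains, no-reference entries, disjoint remainder)
with Q-scores uniform on (0.2, 0.6) and resolutions uniform on
(2.5, 4.0) Å — plausible ranges for a 3–4 Å resolution-banded archive
search. Everything is reproducible from a single seed.

What the generator deliberately does **not** emulate: CTF effects,
resolution-dependent noise spectra, B-factor falloff, masking artifacts,
or the long-tailed redundancy of real archive holdings. Passing tests on
these fixtures therefore demonstrates the correctness of the pipeline's
computations — filters, geometry, scores, accounting — not the
field-realism of any particular threshold. Thresholds shipped as defaults
(Q-score 0.4, overlap 0.70, VOF 0.82) are the conventional operating
points for ribosome-scale curation and should be grid-searched per
application.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run entirely on synthetic
fixtures at desk scale: metadata tables of up to 942 entries, maps up to
48³ voxels, oracle comparisons on grids ≤ 12³. These sizes were chosen so
that exhaustive brute-force oracles are exact and fast; all operations are
dimension-agnostic. Rounding of grid dimensions and rank arithmetic uses
half-up rounding (not banker's) so that closed forms match their
derivations. Interpolation uses natural cubic splines, which are exact on
linear ramps — the property the resampling tests pin down. MRC2014 I/O
writes 32-bit float mode 2 with voxel size encoded as cell length / grid
samples and the origin in the ORIGIN header words, reading NXSTART-based
offsets as a fallback; non-standard axis orders are permuted to x, y, z on
read.

## Known limitations

- Online retrieval (EMDB search API, map/model downloads) is implemented
  but thin; the offline cache path is the tested contract.
- mmCIF secondary-structure parsing covers the loop-format
  `struct_conf`/`struct_sheet_range` categories; exotic single-row or
  multi-datablock files may need preprocessing.
- The VOF, by construction, is insensitive to density *values* beyond the
  binarization — it validates envelope agreement, not local fit quality;
  it complements rather than replaces the Q-score filter.
- Voxelization and labeling are pure R; they are comfortable at curation
  scales (tens of thousands of atoms against ~300³ grids) but not tuned
  for interactive use on very large complexes.
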