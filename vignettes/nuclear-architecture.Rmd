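---
title: "Quantifying 3D nuclear architecture: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D nuclear architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucarch)
```

## The measurement problem

Nuclear-architecture phenotypes of aging stem cells — loss of the polarized
("epipolar") distribution of histone marks such as H4K16ac, separation of
chromosome-territory homolog pairs, growth and deformation of the nucleus,
redistribution of peripheral heterochromatin — are usually scored with
closed-source 3D image software and, for polarity, by visual inspection.
That makes the measurements hard to reproduce and impossible to unit-test.
`nucarch` re-expresses each phenotype as an explicit algorithm on voxel
data, and couples the suite to a generative model of the same scenes so
that every estimator can be exercised against known ground truth.

All arrays use axis order (z, y, x) with per-axis physical spacing in
micrometres. Confocal stacks are anisotropic as acquired (axial steps of
0.5 um against ~0.25 um lateral pixels are typical), so every geometric
quantity — distances, surface areas, shells — is computed in physical
coordinates, never in voxel counts, except where the voxel count itself is
the definition (voxel-coverage volume).

## Segmentation

The nuclear mask is built from the DAPI channel by Gaussian smoothing
(default sigma 0.25 um), a global Otsu threshold, a seeded 3D watershed that
splits touching objects (seeds are maxima of the smoothed distance
transform, thinned to a minimum separation of 0.5 um), morphological
closing (ball radius 0.3 um), hole filling, and retention of the largest
connected component. One nucleus per field is assumed — the cells are
sorted single cells — so multi-object fields resolve to the largest object,
with exact ties broken by the lowest (z, y, x) centroid. Otsu was chosen
because the upstream tools publish no threshold rule; it is parameter-free
and, being a histogram method, leaves the mask invariant under positive
rescaling of the intensities.

Chromosome territories are thresholded *within* the nucleus only (Otsu on
the within-mask intensities), labelled with 26-connectivity, filtered at a
minimum volume (default 0.5 um^3) and capped at the two largest objects.
Homolog pairs closer than roughly the PSF scale merge into one object; this
is deliberately treated as signal, not failure — a merged pair is the
defining case of *homolog proximity*.

## Morphometry

**Volume** is voxel coverage: foreground count times voxel volume.

**Nuclear shape factor** is 3D sphericity,
$\psi = \pi^{1/3}(6V)^{2/3}/A$, equal to 1 for a sphere and smaller for
irregular shapes. The surface area $A$ comes from an iso-surface mesh
(marching tetrahedra on the 6-tetrahedron cube decomposition) of a smoothed
indicator field, with vertices in physical coordinates. Two numerical
choices matter:

- *Why a mesh at all*: counting exposed voxel faces overestimates the area
  of a sphere by ~50% (the staircase never converges to the smooth surface),
  which would destroy the sphere-equals-1 anchor. Smoothing (isotropic
  physical sigma of one coarsest-axis step) removes the staircase.
- *Volume-matched iso level*: smoothing a convex body biases the 0.5-level
  set inward in proportion to curvature times sigma squared, which at
  coarse spacings inflates psi by several percent. The level is therefore
  chosen so that the enclosed voxel count equals the mask's count, which
  cancels the bias; digital spheres then score 1.00 within 0.02 from
  0.125 um up to 0.5 um spacing, and a prolate spheroid reproduces its
  closed-form sphericity within 3% (both assertions are tests).

**Solidity** is the mask's voxel count over the voxel count of its filled
convex hull, the standard discrete definition, guaranteeing values in
(0, 1]. The hull is built incrementally in compiled code; grid point sets
are maximally degenerate for hull algorithms, so input coordinates receive
a deterministic sub-voxel jitter (1e-4 of the bounding scale) and the face
planes are offset outward by 0.01 voxel before rasterization, so boundary
lattice points are never lost to roundoff. Only line-extremal voxels enter
the hull, which bounds the input size. A nucleus is called *invaginated*
when solidity falls below 0.92 — a free default, chosen against the
generator where unperturbed ellipsoids stay above 0.97 while single
pockets of depth >= 1 um fall measurably below them; the raw solidity is
always reported alongside the call. Planar masks are rejected as degenerate.

**Channel volume** (e.g. LaminA/C) Otsu-thresholds a stain within the mask
and reports the supra-threshold volume; an all-zero channel returns 0
rather than an error, since absent staining is a valid observation.

**Peripherality** is the fraction of within-mask intensity lying within a
shell (default depth 0.5 um) of the boundary, using the exact anisotropic
Euclidean distance transform (distance to the nearest background voxel
centre). With uniform intensity the index equals the shell volume fraction
exactly, which the tests exploit as an oracle. Note the shell rule has
measure-zero ties when the depth coincides exactly with an attainable
voxel-to-voxel distance (e.g. depth 0.5 with 0.3/0.4 spacings); the
definition uses `<=`.

## Epipolarity

The visual call "clearly asymmetric about a line through the middle of the
nucleus" is formalized as a half-space mass maximum: for each direction `d`
of a deterministic spherical lattice, take the fraction of total
within-mask mark intensity with nonnegative projection onto `d` about the
*binary mask* centroid (the geometric middle of the nucleus — using the
intensity centroid would partly cancel the very asymmetry being measured).
The score is the maximum over directions; ties resolve to the first
direction in lattice order.

The lattice is a Fibonacci point set closed under all 48 signed axis
permutations, plus the 6 axis directions (about 250 directions at the
default `n_directions = 200`). Closure has two exact consequences, both
tested: antipodal pairs force the score into [0.5, 1], and any 90-degree
scene rotation permutes the lattice onto itself, making the score exactly
rotation-invariant for such rotations. A 200-direction lattice tracks a
5000-direction search within 0.02. The score is invariant under positive
scaling of the intensities; additive offsets compress it toward 0.5 (an
offset adds isotropic mass), which is documented and tested rather than
corrected, because background subtraction is an acquisition-specific
decision upstream of this package.

A cell is *polar* when the score reaches `tau = 0.7`. Under the isotropic
null the score concentrates near 0.55-0.65 at realistic voxel counts (it is
a maximum over ~250 correlated half-space fractions, hence above 0.5), and
concentrated marks exceed 0.9, so 0.7 separates the regimes; `tau` is a
config knob and every report carries the raw score. Percent-polar is
computed per biological repeat and summarized as mean + 1 SEM across
repeats, the reporting unit being the repeat, not the cell; with a single
repeat the SEM is undefined and reported as 0 with a warning.

## Territories and co-localization

Centroids are unweighted means of voxel centres (an intensity-weighted
variant exists but is not the default, keeping the definition identical to
the published centroid-to-centroid convention). Homolog distance is the
Euclidean centroid distance in physical units — the package takes the
position that distances in anisotropic stacks must be physical, since voxel
units would understate axial separations by the anisotropy factor. A cell
is proximal when one merged object is detected or two objects lie within
`d_prox = 2.0` um (boundary inclusive). The default is the territory-radius
scale that separates the merged regime from the 3-4 um separated regime in
the generator; it is configurable. Zero detected objects leave proximity
undefined (`NA`), excluded from percentages. Co-localization reports the
volume of voxels both inside a territory and above the mark's Otsu
threshold, plus the fraction of the territory covered.

## Chromosomal enrichment

Expected counts distribute the peak total proportionally to positive
per-chromosome weights — sizes for the size null, gene counts for the
gene-density null. Gene counts (not genes per Mb) are used so that both
weight vectors are commensurate totals over the same chromosomes; the
alternative is one transformation away in the genome table. The fit is
Pearson's X^2 with df = k-1; since a 118-peak set over ~20 mouse
chromosomes yields expected counts below 5, the `auto` method switches to
an exact Monte-Carlo multinomial p-value,
`p = (1 + #{X2_sim >= X2_obs}) / (1 + n_sim)`, which is tested for type-I
calibration (5% +/- 1% over 2000 null simulations) and for agreement with
the chi-square p when all expected counts are >= 20. mm10 chromosome sizes
ship with the package; chrY is dropped by default (all-female designs), and
any chromosome subset can be supplied explicitly.

Differential-overlap logic counts an interval of set A as overlapping if it
shares at least `min_overlap_bp = 1` with any interval of B on the same
chromosome (computed via `GenomicRanges::findOverlaps`), pairs each A peak
with its first B partner in coordinate order, and counts
direction-concordant pairs. Annotation assigns each peak by its midpoint
with precedence TSS (+/- 100 bp of the strand-aware transcription start) >
promoter (1 kb upstream) > gene body > intergenic; no claim is made of
replicating any specific annotation tool's output.

## The synthetic generator

Scenes are generated, not downloaded: an ellipsoidal nucleus (radius,
per-axis ratios, smooth random radial roughness) with invaginations carved
as spherical pockets intersecting the boundary; a mark channel with von
Mises-Fisher angular weight `exp(kappa * cos(theta))` about a random unit
direction (`kappa = 0` is isotropic — the generator models polarity with a
single concentration dial precisely because the original scoring was
binary and visual); two Gaussian paint blobs at a set separation; isotropic
Gaussian PSF blur; Poisson-like photon noise (gain 4) plus Gaussian read
noise (sd 20 counts); 16-bit integer output. Every random draw flows from
an explicit seed, and identical (config, seed) pairs are bit-identical —
the determinism is itself a test.

The default two-group cohort encodes the aging contrast used throughout
the tests: young = radius 2.6 um, two pockets of depth 1.2 um, kappa 8,
homolog separation 1 um; aged = radius 3.2 um, no pockets but elongated
(axis ratios 1.45/1/0.8) with boundary roughness 0.05, kappa 0.5,
separation 4 um. The magnitudes are chosen for testability — group means
differing by several within-group standard deviations at n = 30 cells per
group — not fitted to any measured effect size, because no quantitative
young-versus-aged generator parameters are available; only the *directions*
of the five group differences (volume up, shape factor down, percent-polar
down, homolog distance up, percent-proximal down in aged) are treated as
recoverable claims. The aged group is made elongated and rough because an
aged nucleus is not a larger sphere but an odd-shaped one; without that,
removing invaginations alone would push the aged shape factor the wrong
way.

What the generator does *not* emulate: realistic optics (no OTF or
structured-illumination model, just Gaussian blur), chromatin texture
inside the nucleus (channels are smooth fields plus noise), multi-cell
fields, spectral bleed-through, or depth-dependent aberrations. Passing
recovery tests therefore demonstrates the correctness of the estimators on
well-posed inputs, not robustness to every artefact of real microscopy.

## Problem sizes and runtime choices

Validation cohorts run at 40 x 64 x 64 voxels per cell with 0.5 um axial
and 0.25 um lateral spacing (a 10 x 16 x 16 um field), 30 cells per group
in 3 repeats; the polarity-concentration sweep uses 18 x 28 x 28 scenes at
kappa in {0, 1, 2, 5, 10} with 20 cells per level; goodness-of-fit
calibration uses 2000 null datasets of 118 peaks with 2000 Monte-Carlo
draws each; the enrichment power study uses 1000 seeds. The shape-factor
anchor uses a radius-3 um sphere at 0.125 um isotropic spacing (~58,000
foreground voxels). These sizes were chosen so the full suite runs in a few
minutes on one core while keeping every statistical margin comfortable.

## Known limitations

- The shape factor is anchored to the sphere and to ordering, not to any
  proprietary software's absolute NSF values, whose formula is unpublished.
- Otsu thresholding assumes a bimodal intensity histogram; very dim or
  saturated channels should be inspected.
- The watershed seed-separation heuristic (0.5 um) is tuned for
  single-nucleus fields; dense fields are out of scope.
- Merged-homolog behaviour reproduces the *phenomenon* of unresolvable
  pairs at PSF scale; it does not replicate any specific commercial
  object-splitting rule.
- Proximity, polarity and invagination calls each depend on one threshold
  (`d_prox`, `tau`, solidity cutoff); all are reported alongside their raw
  continuous scores so downstream analyses can re-threshold.
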