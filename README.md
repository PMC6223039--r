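# nucarch

Quantification of 3D nuclear architecture from multi-channel fluorescence
z-stacks, and chromosome-level enrichment statistics for genomic interval
sets.

Aging hematopoietic stem cells (HSCs) change the architecture of their
nucleus: the polar ("epipolar") intranuclear distribution of histone marks
such as H4K16ac is lost, the two chromosome 11 territories drift apart,
nuclear volume grows while the nucleus loses its invaginated, near-spherical
young shape, and LaminA/C staining declines. Such phenotypes are typically
scored with commercial 3D image software and by eye. `nucarch` provides an
open, scriptable, and *tested* implementation of this measurement suite,
together with a synthetic-scene generator with known ground truth, so that
every stage of the pipeline can be validated without access to primary
microscopy data. A companion genomics component asks whether a set of
ChIP-seq peaks is distributed across chromosomes as expected from chromosome
size (or gene density) alone, or concentrates on particular chromosomes.

## What it computes

Per nucleus, from a DAPI-segmented binary mask `M` on a voxel grid with
physical spacing `(dz, dy, dx)` in micrometres:

- **Volume** by voxel coverage: `V = |M| * dz*dy*dx`.
- **Nuclear shape factor (NSF)** as 3D sphericity
  `psi = pi^(1/3) * (6V)^(2/3) / A`, with `A` the area of an iso-surface
  meshed in physical coordinates from a smoothed indicator field at a
  volume-matched level. `psi = 1` for a perfect sphere (calibrated to
  1.00 +/- 0.02 on digital spheres), lower for irregular shapes.
- **Solidity** `V / V_convex_hull` (filled 3D convex hull), and an
  *invaginated* call when solidity drops below a cutoff (default 0.92) —
  a reproducible stand-in for visual scoring of pocket-like invaginations.
- **Stain channel volume** (e.g. LaminA/C): Otsu-thresholded supra-threshold
  volume within the nucleus.
- **Peripherality index**: fraction of a mark's intensity within a shell
  (default 0.5 um, Euclidean distance transform in physical units) of the
  nuclear boundary — an imaging proxy for lamina-associated localization.
- **Epipolarity score**: over a deterministic spherical lattice of
  directions, the maximal fraction of within-mask mark intensity on one side
  of a plane through the mask centroid. 0.5 = isotropic, 1 = fully
  one-sided; a cell is called *polar* when the score exceeds `tau`
  (default 0.7). Percentages are summarized as mean + 1 SEM across
  biological repeats.
- **Chromosome territories**: paint channels are thresholded within the
  nucleus, connected components become territory objects with unweighted
  voxel-centre centroids; homolog distance is the centroid-to-centroid
  Euclidean distance, and a cell shows *homolog proximity* when the two
  paints merge into one object or lie within `d_prox` (default 2 um).
  Mark-territory co-localization volumes complete the per-cell record.

For a peak table with `n` intervals over chromosomes with weights `w_i`
(sizes or gene counts), expected counts are `e_i = n * w_i / sum(w)`,
per-chromosome enrichment is `o_i / e_i`, and the departure from the null is
tested with Pearson's `X^2 = sum (o_i - e_i)^2 / e_i` — chi-square
asymptotics when all `e_i >= 5`, otherwise an exact Monte-Carlo multinomial
p-value. Differential peak sets can be intersected with direction-of-change
concordance, and peaks annotated by midpoint (TSS > promoter > gene body >
intergenic).

The `synthetic_data` module renders parameterized scenes (ellipsoidal nuclei
with carved invagination pockets, von Mises-Fisher-concentrated mark
channels, Gaussian homolog blob pairs, PSF blur, Poisson-plus-read noise,
16-bit output) and samples peak tables with known per-chromosome fold
enrichment, so recovery of every generating parameter is testable.

## Worked example

```r
library(nucarch)

grid <- grid_spec(c(40, 64, 64), c(0.5, 0.25, 0.25))   # z-stack, 0.5 um steps
cfg <- scene_config(grid,
                    nucleus_shape_params(radius = 2.8, invagination_count = 2,
                                         invagination_depth = 1.2),
                    mark_polarity_kappa = 8, homolog_separation = 1.0)
scene <- render_scene(cfg, seed = 1)      # "young-like" synthetic HSC
rec <- quantify_cell(scene, cell_id = "young_demo")
as.data.frame(rec)[, c("volume_um3", "nsf", "solidity", "polarity_score",
                       "n_objects", "proximal")]
#>   volume_um3       nsf  solidity polarity_score n_objects proximal
#> 1     89.875 0.9873739 0.9788972       0.971964         1     TRUE
```

The young-like cell is small (90 um^3), nearly spherical (NSF 0.99) but
invaginated (solidity 0.98 on this render), strongly polar (score 0.97),
and its homolog blobs at 1 um separation merge into a single paint object —
a proximal cell.

```r
peaks <- sample_peak_table(118, mouse_chrom_sizes(),
                           fold_map = c(chr11 = 5), seed = 1)
chrom_enrichment(peaks, mouse_chrom_sizes(), seed = 1)
#> chromosomal enrichment (size null):
#>  chrom observed expected enrichment_score
#>  chr11       17 5.469613         3.108081
#>   chr3       10 7.170191         1.394663
#>   chr5        9 6.802586         1.323026
#>  chr14        7 5.595943         1.250906
#>  chr10        7 5.855473         1.195463
#> goodness of fit: X^2 = 35.717, df = 19, p = 0.012 (monte-carlo)
```

118 peaks drawn with a 5-fold excess on chromosome 11 put chr11 on top of
the enrichment ranking, and the goodness-of-fit test rejects the
size-proportional null (the Monte-Carlo method is selected automatically
because expected counts fall below 5).

Cohort-level runs (`run_cohort`) produce per-cell CSVs, per-group mean + SEM
summaries and paired-t / ANOVA comparisons with Bonferroni-gated post tests.

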