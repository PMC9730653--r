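---
title: "Methods: spatiotemporal analysis of post-hemorrhage brain inflammation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatiotemporal analysis of post-hemorrhage brain inflammation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

After an experimental intracerebral hemorrhage (whole blood injected
into the mouse striatum), the brain mounts a biphasic inflammatory
response: the choroid plexus (CP) — the intraventricular
epithelial–stromal organ producing cerebrospinal fluid — reacts within
hours, expressing cytokines and leukocyte adhesion molecules, while the
perilesional striatum mounts a delayed macrophage-dominated reaction
around four days. `cpwave` implements the quantitative machinery to
resolve this in space and time from two data modalities:

1. **Spot-based spatial transcriptomics** (Visium-style): each 55 µm
   barcoded spot yields a gene-count vector with a slide position.
   The pipeline annotates spots anatomically, then runs
   region-stratified differential expression over the post-injection
   time course.
2. **Multichannel immunofluorescence sections** with manually
   segmented compartment masks: the pipeline registers sections to a
   common template, averages intensities across animals, quantifies
   dextran extravasation (a blood–brain-barrier readout) and compares
   genotype groups (TLR4/MyD88 knockouts vs. wildtype vs. sham).

Because the raw animal data are not redistributable, the package ships
a first-class synthetic-data generator that plants the study's
structure with ground truth, so every stage of the analysis is
testable as a recovery problem.

# Anatomical annotation of spots

## Normalization

Counts are scaled per spot to the median total count and transformed
with `log(1 + x)` (`normalize_counts()`). Zero-count spots are dropped
with a warning; genes detected in fewer than 3 spots are flagged but
kept (the same threshold later defines the enrichment universe).
Samples are normalized jointly after concatenation; no batch
correction is applied — the synthetic cohorts have none, and the
analysis treats sections from one experiment as one batch.

## Gene-set scoring with expression-matched controls

`score_gene_set()` computes, per spot, the mean expression of a set
minus the mean of control genes matched on expression level: genes are
ranked by their mean expression and cut into `n_bins = 25`
equal-frequency bins; for each set gene, `n_ctrl = 50` controls are
sampled from its bin (excluding set genes, with replacement when the
bin is small). This is the standard control-gene scheme of the
single-cell scoring literature; it makes scores robust to the overall
expression level of a set and exactly shift-invariant (adding a
constant to the matrix cancels in the difference). Scoring is
deterministic given a seed.

## Clustering with a cluster-count constraint

`cluster_spots()` runs PCA (`n_pcs = 30`), builds an exact
`k = 15`-nearest-neighbor graph on the PC coordinates, and applies
Leiden community detection (modularity objective). Because the
analysis design fixes the number of main clusters (five: four single
regions plus the composite deep-brain cluster), the Leiden resolution
is not a free parameter: it is found by bisection on `[0.05, 2.0]`
until the community count equals the target, up to 60 steps. On
plateaus the smallest qualifying resolution is kept, for
reproducibility. The search assumes the community count is
non-decreasing in the resolution; the trace is checked and a violated
bracket triggers one restart with a fresh RNG stream. Labels are
returned ordered by decreasing cluster size.

## Cluster-to-region assignment: the dominance rule

Per cluster and candidate region (CTX, STR, TH, CP and the four
deep-brain constituents PAL, HY, MB, P), the mean anatomical score and
the fraction of score-positive spots are computed. With `S_max` the
cluster's largest positive mean score, every region scoring at least
`tau * S_max` (`tau = 0.75`) is assigned: one region gives a single
label, several give a composite label (this is how the
pallidum/hypothalamus/midbrain/pons cluster becomes "deep brain"), and
a cluster with no positive region is "unassigned". The positive
fraction is reported as QC only. The threshold rule is this package's
formalization of what is usually a judgement call; `tau` is exposed so
users can tighten or relax it.

# Temporal differential expression

Each post-injection time point is compared with the uninjected control
within each region (`rank_genes_wilcoxon()`), using a two-sided
Wilcoxon rank-sum test on log-normalized expression. A rank test was
chosen because spot-level counts have heavy-tailed, approximately
negative-binomial marginals; no distributional fit is required. For
group sizes up to 8 the p value is exact, by enumeration of all
assignments of the (tied) ranks — the permutation distribution of the
Mann–Whitney U statistic is symmetric about `n1 n2 / 2`, which the
enumeration exploits; larger groups use the normal approximation with
tie correction and no continuity correction. Fold changes are
`log2((mean expm1 + 1e-9) / (mean expm1 + 1e-9))` on the two groups;
the pseudocount only guards zero means. Benjamini–Hochberg adjustment
is applied per (region, time) test family.

Marker tables (`top_k_table()`) take the `k = 5` smallest adjusted p
among up-regulated genes per time point; ties break by decreasing
|log2FC|, then alphabetically — a deterministic rule so reruns are
identical. Enrichment (`enrich_hypergeometric()`) is the classical
upper-tail hypergeometric test against a user-supplied GMT catalog,
BH-adjusted across sets, with the universe set to genes detected in at
least 3 spots.

Pathway score time courses (`gene_set_time_course()`) summarise
per-spot scores per (region, time) with the median and a percentile
bootstrap CI; the loess curve is fitted to the per-time medians, not
to the replicated per-spot values, because replication at few distinct
times breaks the meaning of the span fraction (and makes local fits
singular).

# Histology quantification

## Section selection and registration

The standardized section rule (`select_standard_sections()`): starting
from the first section at or beyond 300 µm posterior to the anterior
commissure, every second section is taken until eight are selected;
stacks too short for the rule are a hard error naming the shortfall.

Registration to the template (`estimate_registration()`) is
moments-based: centroids give the translation, principal axes of the
section outline the rotation, and the square root of the outline area
ratio the isotropic scale. The 180° ambiguity of a principal axis is
resolved by requiring the ipsilateral ventricle/CP centroid to land on
the correct side. The residual — mean distance from warped section
boundary points to the nearest template boundary point — is attached
to the transform; above 3 px the fit is flagged low-confidence.
Moments registration is exact for similarity-transformed copies of
the same shape, which is the regime here (rigid sections, manual
masks); it is not a substitute for deformable registration and resolves
no nonlinear tissue distortion.

Warping (`warp_to_template()`) inverse-maps template pixels and
interpolates bilinearly (nearest neighbor for label images);
out-of-field pixels are `NA` and excluded from averaging, never
zero-filled, so maps are unbiased near the field edge.

## Average-intensity maps and normalization

Per group (marker x time x genotype), each section is divided by the
median intensity of its contralateral hemisphere — an internal
reference unaffected by the lesion — then registered, warped, and
averaged per pixel over contributing sections
(`average_intensity_map()`). A coverage image counts contributions;
the map is defined only where coverage is positive.

## Leakage quantification

`quantify_leakage()` automates the semi-automated procedure: the
threshold is the mean plus `k_sigma = 3` standard deviations of the
background (contralateral striatum); supra-threshold pixels are
labeled by 8-connected components; the leakage is the union of
components intersecting a 200 µm disc around the injection site. Area
is reported in mm², intensity as the mean over the component. The
area is non-increasing in `k_sigma` by construction. With no
component near the site, the area is 0 and the intensity missing —
not zero, which would bias group means.

# Temporal and group summaries

`bootstrap_ci()` is the percentile bootstrap of the mean
(`B = 10000` by default; the acceptance computations use `B = 2000`):
type-7 quantiles of the resample means at level 0.95. Percentile
rather than BCa keeps the procedure transparent and exactly matches
the exhaustive-resample oracle used in the tests.

`loess_fit()` is local-linear regression with tricube weights
(`stats::loess`, degree 1), fitted on `log2(time)` because the
sampling design is geometric (2, 12, 24, 36, 48, 96 h); the pointwise
band is `fit ± t(df) · SE` with df from the smoother's trace
approximation. The default span is 0.5: with only five or six distinct
time points, a span of 0.75 smooths so aggressively that even a
noise-free peak planted on one grid point is called at the neighboring
one; 0.5 is the largest span in our sweeps that resolves adjacent grid
points on both linear and log axes. A span below `4 / n_points` is
refused: with three points per neighborhood the symmetric outer points
get zero tricube weight and the local fit is singular.

`peak_time()` reports the observed time closest to the loess argmax
(ties to the earlier time), plus the local maxima of the discrete
per-time estimates — a six-point smooth cannot represent two bumps one
grid point apart, so biphasic structure (the 12 h / 48 h leakage
course) is read from the discrete sequence.

Group comparisons (`group_compare()`) summarise animal-level means
(sections averaged within animal first) with type-7 quartiles and
1.5·IQR whiskers, and test pairs with the exact rank-sum test,
BH-adjusted over the comparison family. The hypothesis tests are this
package's addition to the descriptive knockout comparison and are
labeled as such in the outputs.

# The synthetic-data generator

## What it emulates

- **Geometry**: a stylized elliptical coronal section on a 512 x 512
  template at 20 µm/px — cortex band, lateral striatal blocks (lesion
  in the ipsilateral one), central thalamus with the third ventricle,
  ventral deep-brain block, lateral ventricles each holding a choroid
  plexus. Masks are mutually disjoint; lesion and CP are carved out of
  their parent territories so containment and disjointness coexist.
  The ellipse is sized so a 100 µm spot grid yields roughly 500
  in-tissue spots per sample (about 3000 across the six-sample
  cohort). It is a statistical stand-in, not an atlas.
- **Counts**: negative binomial with dispersion 0.2 and log-normal
  library sizes (meanlog 9.2, sdlog 0.3); the mean is baseline
  abundance x anatomical marker fold (8x in the marker's region, 5x
  for each deep-brain constituent set in DEEP) x the product of active
  temporal-program folds.
- **Temporal programs**: multiplicative log-time Gaussian bumps
  (biphasic = sum of two): an erythrocyte-transcript pulse at 2 h in
  the blood-exposed compartments, the CP inflammatory wave peaking at
  12 h, a CP TLR/MyD88-signaling bump at 24 h, biphasic Ptprc (24 h /
  96 h), an early striatal cytokine wave (12 h), a mid-phase
  phagocytic program (48 h), and the late perilesional macrophage wave
  (96 h). The 48 h striatal program mirrors the gradual microglial
  activation between the two waves; without an intermediate program the
  late-wave genes would trivially dominate every late marker table.
- **Images**: compartment-specific mean intensities plus Poisson shot
  noise and Gaussian read noise (sd 30) over a constant offset; the
  dextran leakage blob is a plateau disc at the lesion centroid whose
  radius and intensity follow a biphasic curve peaking at 12 h and
  (higher) 48 h; CP CD45 peaks at 24 h, CP ICAM1 at 36 h, perilesional
  CD45/F4/80 rise only from 48 h. Knockouts silence inflammatory CP
  programs only; sham silences every program. Every animal gets a
  random pose jitter (rotation <= 10°, shift <= 8 px, scale 0.95–1.05)
  applied identically to image and masks, with a smaller per-section
  jitter on top; a 16-section stack is laid out at 60 µm spacing and
  only the 8 standard-rule sections are rendered.

## What it does not emulate

Spatial expression gradients within a region; spot-boundary mixing;
batch and slide effects; segmentation error in the masks (masks are
exact up to the planted pose); autofluorescence structure; nonlinear
tissue deformation. Passing recovery tests therefore demonstrates the
correctness of the statistical machinery under the planted model, not
robustness to every artifact of real sections.

## Cohort sizes

Defaults mirror the study design: transcriptomics, one animal per
time point at control, 2, 12, 24, 48, 96 h (six samples); histology,
three animals per time point at 2–96 h including 36 h (18 animals);
knockout series at 24 h with 6 wildtype, 4 per knockout and 4 sham.
These sizes keep a complete pipeline run on a single CPU in the
low minutes while preserving the power relations of the study (e.g.
the smallest exact rank-sum p at 4 vs 6 animals is 0.0095, so the
knockout contrast can reach significance and the sham equivalence
cannot be an artifact of zero power).

# Degenerate inputs and numerical conventions

- Zero-variance rank-sum pools return p = 1 (no evidence, not an
  error). NA/NaN p values propagate through BH unranked.
- `bootstrap_ci()` of a single value returns the degenerate interval
  with a warning; empty compartments yield `NA` means, logged.
- Quantiles are type 7 (R's default linear interpolation) everywhere.
- All randomness flows through explicit integer seeds; child streams
  are derived arithmetically, no global RNG state is consumed.
- 16-bit TIFF channels quantize intensities to unit steps; float maps
  are stored with a recorded scale because TIFF samples live on [0, 1].

# Known limitations

- The cluster-count bisection assumes quasi-monotonicity of the Leiden
  community count in the resolution; highly unstructured data can make
  the bracket unattainable, which is reported as an error with the
  achievable counts.
- Moments registration requires the hemisphere outline and an
  ipsilateral landmark in both masks and tolerates only similarity
  misalignment.
- The leakage rule attributes any supra-threshold component touching
  the site disc to the lesion; pathologies that disconnect the leakage
  from the site would be missed.
- The composite-label rule depends on `tau`; values near 1 fragment
  the deep-brain cluster, values near 0 over-merge.
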