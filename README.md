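# cpwave

Spatiotemporal analysis of brain inflammation after experimental
intracerebral hemorrhage (ICH), for researchers studying secondary
brain injury in the mouse whole-blood striatal injection model.

After a striatal blood injection, the brain reacts in two waves: the
choroid plexus (CP) — the CSF-producing organ inside the ventricles —
mounts an acute inflammatory response within 12–24 h (cytokines,
interferon response, leukocyte adhesion molecules, leukocyte
accumulation), while the perilesional striatum shows a delayed,
macrophage-dominated reaction peaking around 96 h, accompanied by a
biphasic opening of the blood–brain barrier. `cpwave` packages the
quantitative pipeline for resolving this sequence from spatial
transcriptomics and quantitative immunofluorescence, together with a
synthetic-data generator that plants the full spatiotemporal structure
with ground truth so that every stage is testable as a recovery
problem.

## What the package computes

**Anatomical annotation of spots.** Spot counts (10x-style MTX bundle)
are median-scaled and log-transformed; anatomical gene sets are scored
per spot as

    score(s) = mean_{g in set} x_gs − mean_{g in ctrl} x_gs,

with control genes drawn from expression-matched bins (25 bins, 50
controls per set gene). Spots are clustered by Leiden community
detection on a 15-NN graph over 30 PCs, with the resolution found by
bisection so that the number of clusters equals a target (five in the
study design). Each cluster is assigned every region whose mean score
is ≥ τ·S_max (τ = 0.75); multiple qualifying regions form a composite
label — this reproduces the "deep brain structures" cluster spanning
pallidum, hypothalamus, midbrain and pons.

**Region-stratified temporal differential expression.** Per region and
time point vs. the uninjected control: two-sided Wilcoxon rank-sum
(exact by enumeration for groups ≤ 8, tie-corrected normal
approximation otherwise), BH adjustment, top-5 up-regulated marker
tables, hypergeometric gene-set enrichment (`P[X ≥ k]`,
`X ~ Hypergeom(N, K, n)`) against a GMT catalog, and gene-set score
time courses with bootstrap CIs and loess peak calls.

**Histology quantification.** Standardized section selection (every
2nd section from 300 µm posterior to the anterior commissure, 8
sections), moments-based similarity registration to a template,
contralateral-hemisphere normalization, cross-animal average-intensity
maps, dextran leakage area/intensity (background mean + 3 SD
threshold, 8-connected components at the injection site), and
per-compartment mean intensities (CP ipsi/contra/third, perilesional
striatum).

**Temporal and group statistics.** Percentile bootstrap CIs of the
mean, loess curves (tricube, degree 1, on log2 time) with t-based
bands, peak times, IQR boxplot summaries with 1.5·IQR whiskers, and
exact rank-sum comparisons for the TLR4/MyD88 knockout series.

## Worked example

```r
library(cpwave)

layout <- default_layout()
cohort <- generate_spot_cohort(layout, default_spot_design(seed = 1))
cohort
#> spatial_dataset: 300 genes x 2766 spots, 6 sample(s)

ann <- annotate_spatial(cohort, seed = 1)
ann$assignment
#> region_assignment:
#>   cluster 0 -> CTX (n = 1416)
#>   cluster 1 -> STR (n = 450)
#>   cluster 2 -> TH (n = 444)
#>   cluster 3 -> PAL+HY+MB+P (n = 348)
#>   cluster 4 -> CP (n = 108)
```

The resolution search found exactly five clusters; four map to single
regions and one is the composite deep-brain cluster. Differential
expression in the CP against the control sample ranks the planted
acute-wave genes at their 12 h peak:

```r
dge <- dge_all_regions(ann$normalized, ann$spot_region_coarse,
                       ann$normalized$dataset$meta$time_h,
                       region_set = "CP")
subset(top_k_table(dge, 5), time_h == 12)
#>  region time_h rank  gene        p_adj   log2fc
#>      CP     12    1  Bst2 6.616903e-05 2.155315
#>      CP     12    2 Icam1 6.616903e-05 2.116644
#>      CP     12    3  Irf7 6.616903e-05 1.920016
#>      CP     12    4 Vcam1 6.616903e-05 1.873486
#>      CP     12    5  Lcn2 6.616903e-05 1.590515
```

The MyD88-dependent TLR-signaling score in the CP recovers its planted
24 h peak, with per-time medians, bootstrap CIs and the loess peak
call:

```r
tc <- gene_set_time_course(ann$normalized,
        default_marker_sets()$sets$MYD88_TLR_SIGNALING,
        ann$spot_region_coarse, ann$normalized$dataset$meta$time_h,
        "CP", B = 2000, seed = 1)
tc
#>   time_h  n    estimate      median         lo          hi reliable
#> 1      2 18 -0.14666174 -0.08160246 -0.2594017 -0.04175757     TRUE
#> 2     12 18  0.26329728  0.32593179  0.1687440  0.36063638     TRUE
#> 3     24 18  1.09788437  1.11401266  1.0151717  1.18723540     TRUE
#> 4     48 18  0.34480768  0.34525374  0.2695875  0.42463583     TRUE
#> 5     96 18 -0.03461869 -0.03268292 -0.1517040  0.07548848     TRUE
#> peak at 24 h; local maxima: 24 h
```

Scores near zero mean "no different from expression-matched control
genes"; the 24 h median of 1.11 log-units above control genes is the
planted CP signaling bump.

`run_pipeline("out", run_config(seed = 1))` executes every stage —
annotation, DGE, enrichment, score course, leakage and marker time
courses, average-intensity maps, knockout comparison — and writes
CSVs, PNG figures, map TIFFs and a flat-text manifest to `out/`. A
shell entry point with per-stage subcommands is installed at
`inst/scripts/cpwave` (see `cpwave_cli()`).

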