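# mirtemporal

Temporal miRNA expression profiles across the human lifespan, cluster
concordance, and case/control dysregulation.

## The scientific problem

MicroRNA abundance in human brain tissue changes sharply across
development: many miRNAs rise or fall around birth, infancy, or puberty,
and groups of miRNAs move together. Postmortem cohorts sample donors at
fixed ages, so a temporal profile must be reconstructed from a
cross-section: one measurement per donor, spread unevenly from the fetal
period to old age. This package implements that reconstruction and the
downstream questions that follow from it:

1. **Profiles** — How does each miRNA's expression change with age?
   Donors are placed on a log2 post-conception scale,
   `t = log2(age_days + 280)`, which stretches the fetal/infant period
   where change is fastest. Counts are filtered (≥ 10 reads in every
   sample), CPM-normalized, log2-transformed, smoothed over a ±0.3 window
   on the transformed scale, and z-scored per miRNA. Per developmental
   stage (fetal through senior), a mean-z test flags stages where a miRNA
   is significantly high or low (p < 0.05 and ≥ 2 donors in the stage).
2. **Clusters** — How many co-moving temporal groups are there? Profiles
   are clustered hierarchically (ward.D2) under two distances: `1 − r`
   (Pearson) and dynamic time warping. The gap statistic selects the
   cluster number; a weighted bipartite *Index of Agreement* (IoA =
   non-crossing / crossing edges after barycenter ordering) with a
   per-profile permutation null tests whether the two partitions agree
   beyond chance.
3. **Dysregulation** — Are miRNAs shifted in cases? A negative-binomial
   GLM (via edgeR) tests diagnosis with race, sex, age bin, and batch as
   covariates, BH-FDR across miRNAs, plus a dose sensitivity analysis
   splitting the antipsychotic dose range into thirds. Preranked GSEA of
   the temporal groups (running-sum ES, permutation NES) asks whether
   whole groups move concordantly.
4. **Targets** — Do group miRNAs co-regulate genes? Per-transcript
   binding-site enrichment (hypergeometric / Fisher tail), CoR genes
   (FDR < 0.05 and ≥ 2 distinct group miRNAs), KS and hypergeometric
   set-level tests, and donor-wise Pearson correlation of miRNA–target
   pairs (|r| > 0.49, FDR < 0.05) against a shuffled-label null.

Because real postmortem cohorts cannot be redistributed, the package
ships a synthetic cohort generator (`cohort_config()`,
`generate_cohort()`, `generate_mirna_counts()`, `generate_mrna_matrix()`,
`generate_target_map()`) whose defaults mirror the intended study design:
109 lifespan controls + 34 adult cases, nine temporal templates anchored
at developmental landmarks, NB counts with batch effects, plantable
case/control shifts, co-regulated genes, and miRNA→mRNA coupling. Every
stage of the pipeline is tested end to end against these planted truths.

## Worked example

```r
library(mirtemporal)

cfg <- cohort_config(n_control = 60, n_case = 0, n_mirna = 90, n_mrna = 60,
                     seed = 1)
cohort <- generate_cohort(cfg)
counts <- generate_mirna_counts(cohort, cfg)

prof <- build_profiles(counts, cohort)
print(prof)
#> temporal_profiles: 90 features x 60 samples, age -0.43..69.43 y

gs <- gap_statistic(prof$zscores, k_max = 12, B = 50, seed = 1)
gs$k_selected
#> [1] 9          # the nine planted temporal groups

conc <- ioa_permutation_test(prof$zscores, k_a = gs$k_selected,
                             k_b = gs$k_selected, n_perm = 200, seed = 1)
print(conc)
#> concordance: 16 edges, 7 non-crossing / 9 crossing, IoA = 0.778,
#> permutation p = 0.004975

calls <- stage_significance(prof)
head(calls[calls$significant, ], 3)
#>     feature_id   stage n_samples    mean_z direction          p significant
#> 47    miR-0047   fetal        10  2.012056         + 0.04421399        TRUE
#> 98    miR-0008  infant         9  2.061954         + 0.03921209        TRUE
#> 192   miR-0012 toddler         8 -2.125003         - 0.03358632        TRUE
```

The permutation arm re-clusters a DTW distance per permutation, so this
block takes a minute or two on one CPU.

## The full analysis workflow

`analysis/01_simulate.R` … `analysis/07_pair_correlations.R` run the
complete study on a simulated cohort (109 controls + 34 cases, 540
miRNAs, 2000 genes, planted effects at every stage), writing tables under
`results/`:

```sh
Rscript analysis/01_simulate.R          # cohort, counts, mRNA, target map
Rscript analysis/02_temporal_profiles.R # profiles + stage calls
Rscript analysis/03_clustering.R        # gap statistic, IoA (slowest, ~8 min)
Rscript analysis/04_differential_expression.R
Rscript analysis/05_gsea.R
Rscript analysis/06_cor_genes.R
Rscript analysis/07_pair_correlations.R
```

On the default seed this recovers the planted structure: the gap
statistic selects k = 9; the planted differentially expressed miRNAs are
the top two hits (miR-0137, log2FC 1.50, FDR 5×10⁻¹⁸; miR-0219, log2FC
−1.10); GSEA flags exactly the two shifted groups (NES +2.73 and −2.54,
FDR ≈ 0.01, all seven unshifted groups FDR ≥ 0.33); all 20 planted CoR
genes are recovered; and 1.03% of target pairs are significantly
negatively correlated versus 0.00% under the shuffled-label null.

## Vignette

`vignettes/temporal-mirna-workflow.Rmd` documents the model, every
numerical choice (age transform, smoothing window, gap reference
distribution, DTW step pattern, IoA conventions), the generator's design
and limits, and the problem sizes used throughout.
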