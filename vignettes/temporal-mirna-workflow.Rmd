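---
title: "Temporal miRNA profiles: model, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal miRNA profiles: model, methods, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtemporal)
```

This vignette documents the statistical model behind `mirtemporal`, the
rationale for every numerical choice, and the design of the synthetic
cohort generator that makes the pipeline testable end to end.

## 1. The temporal profile model

A postmortem cohort gives one expression measurement per donor at a fixed
age. The package reconstructs each miRNA's trajectory from this
cross-section in five steps (`build_profiles()`):

1. **Expression filter.** A miRNA is "expressed" only if it has at least
   10 reads in *every* sample. The all-samples rule (rather than a mean
   or quantile rule) guarantees that log-CPM values are bounded away from
   the zero-count floor in each donor, so smoothing never averages
   censored values.
2. **Normalization.** Counts per million per donor, then
   `log2(CPM + 1)`. The pseudo-count of 1 is conventional and immaterial
   after the filter (all retained values are well above it).
3. **Age scale.** Donors are placed at
   `t = log2(age_years * 365.25 + 280)`: chronological age converted to
   days post conception (a 280-day gestation) and log2-transformed.
   Development is roughly log-linear — the change between gestational
   week 20 and birth rivals the change between ages 20 and 60 — so equal
   distances on `t` are comparably "developmentally far". The transform
   is defined for fetal donors (negative ages) down to
   `age > -280/365.25` years.
4. **Smoothing.** Each value is replaced by the mean over all donors
   within ±0.3 on the `t` scale (window inclusive at both edges). 0.3 on
   a log2 scale is about a 23% change in post-conception days — wide
   enough to pool 3–10 donors in a typical 100-donor lifespan cohort,
   narrow enough not to blur the perinatal transition. A width of 0
   degenerates to the identity; a very large width to the row mean (both
   are tested properties).
5. **z-scores.** Each smoothed profile is centered and scaled; constant
   profiles are flagged `degenerate` rather than divided by zero.

**Stage significance** (`stage_significance()`): for each developmental
stage (fetal < 0, infant 0–1, toddler 1–3, preschool 3–6, prepuberty
6–12, adolescent 12–18, young adult 18–39, adult 40–60 inclusive, senior
> 60 years) the mean z of the stage's donors is converted to
`p = 2(1 − Φ(|z̄|))`; a call requires `p < 0.05` *and* at least two
donors in the stage. Treating `z̄` as standard normal ignores both the
shrinkage of a mean over `n` donors (anti-conservative correction would
be `z̄·√n`) and the positive correlation that smoothing induces between
neighbouring donors (conservative). The package exposes
`scale_by_sqrt_n` for the former but defaults to the plain mean-z rule;
the test suite verifies the realized null call rate stays at or below
α plus Monte-Carlo error on amplitude-zero cohorts.

## 2. Clustering and cluster-number selection

Profiles are clustered hierarchically with Ward's method (`ward.D2`)
under two distances:

- **Correlation distance** `d = 1 − r` (Pearson across donors): shape
  similarity, scale- and offset-free because profiles are z-scored.
- **Dynamic time warping** (`dtw_distance()`, Rcpp): the cheapest
  monotone alignment path through the `|x_i − y_j|` cost lattice, each
  visited cell counted once (the `symmetric1` step pattern:
  `D(i,j) = d(i,j) + min(D(i-1,j-1), D(i-1,j), D(i,j-1))`). This is the
  pattern whose result matches an exhaustive path-enumeration oracle,
  which is how the test suite verifies it exactly; `symmetric2`
  (diagonal counted twice) and a Sakoe–Chiba window are options. DTW
  tolerates the time-shifts that a correlation distance punishes — two
  identical bumps a year apart are close under DTW, far under `1 − r`.

**Gap statistic** (`gap_statistic()`):
`Gap(k) = E*[log W_k] − log W_k`, with `W_k` the sum over clusters of
mean within-cluster pairwise distance, and the one-SE rule (smallest `k`
with `Gap(k) ≥ Gap(k+1) − se(k+1)`). The reference distribution is
uniform *in the PCA basis* of the data, rotated back (`scaled_pca`,
default). The naive per-column uniform reference is also available
(`reference = "original"`), but smoothed profiles are strongly
autocorrelated across donors: a box that ignores this is far too
dispersed, its `log W_k` keeps falling past the true `k`, and the
statistic runs to `k_max`. The PCA-aligned box matches the data's
principal axes and restores a peak at the planted group number — on
default nine-template cohorts the selected `k` is 9 in 10/10 seeds.

**Index of Agreement** (`bipartite_concordance()`): the two clusterings
form a bipartite graph, nodes = clusters, edge weights = shared profile
counts. Node orders on both sides are relaxed by an iterated barycenter
pass (8 sweeps, ties broken by first occurrence). Two edges cross if
their endpoints interleave; an edge is "crossing" if it crosses at least
one other, and `IoA = n_noncrossing / max(n_crossing, 1)`. Identical
k-clusterings give a perfect matching: IoA = k. The permutation null
(`ioa_permutation_test()`) permutes each profile's values independently
across donors — destroying temporal shape while preserving each
profile's marginal distribution — re-clusters with the second method
against the fixed first clustering, and reports
`p = (1 + #{null ≥ obs}) / (n_perm + 1)`.

## 3. Case/control differential expression

`nb_glm_test()` fits a negative-binomial GLM per miRNA (edgeR:
`estimateDisp` → `glmFit` → `glmLRT`) with log library sizes as offsets,
the tested variable last in the design after race, sex, age bin, and
batch; control is the reference level, so positive log2FC means up in
cases. Constant covariates are dropped with a message rather than an
error, since subsets (e.g. a single-sex stratum) arise naturally in
sensitivity analyses. `dose_sensitivity()` bins a dose covariate by
equal thirds of its *range* (not terciles of its distribution — the
question is exposure magnitude, not donor ranking), then contrasts
high-vs-low and high-vs-medium on the corresponding subsets; an empty
middle bin skips that contrast with a warning. The suite verifies a
planted log2FC of 2 is recovered within ±0.3 with power ≥ 0.9 at 40
donors/arm, and that the type-I error is nominal on null cohorts.

## 4. Set-level enrichment

`preranked_gsea()` is the classic running-sum statistic: descending by
signed score (ties broken by id), set members step the sum up
proportionally to `|score|^weight` (normalized over members), non-members
step down by `1/(N − N_hit)`; ES is the signed extremum. The null draws
random same-size member sets from the ranked universe; NES divides ES by
the mean |null ES| of matching sign, p is one-sided among same-sign
nulls, FDR is BH across sets. The implementation is the package's own
(the running sum is the object under test); `fgsea::calcGseaStat` is
used in the test suite as an independent cross-check and agrees to
machine precision. Temporal-group GSEA uses `min_size = 51` (groups with
more than 50 members) and score `−log10(p) · sign(log2FC)`.

Target-side tests: `mre_enrichment_p()` is the hypergeometric
point/tail probability on the 2×2 site-count table (group vs non-group
sites, this transcript vs all others), computed via `dhyper`/`phyper`;
degenerate margins return 1. `cor_gene_test()` BH-adjusts the tail p
across all transcripts and calls a gene *co-regulated* (CoR) when its
best transcript has FDR < 0.05 and ≥ 2 distinct group miRNAs target the
gene — the second condition blocks single-miRNA site stacks from
masquerading as group-level regulation. `ks_set_enrichment()` (two-sample
KS on per-gene p-values) and `set_targeting_test()` (upper-tail
hypergeometric on targeted-gene overlap) give set-level summaries.

## 5. miRNA–target correlation

`pair_correlations()` computes Pearson r for every target-map pair
across shared donors (row-standardization followed by one cross-product,
so all pairs cost one matrix pass), t-test p-values, BH-FDR over all
tested pairs, and classes at the |r| > 0.49 / FDR < 0.05 thresholds.
`shuffled_null()` permutes the mRNA matrix's donor labels — one
permutation breaks every pairing simultaneously while preserving both
marginal correlation structures — and records the fraction of pairs
still meeting the class thresholds.

## 6. The synthetic cohort generator

The generator is first-class, tested code; its defaults *are* the study
conditions the pipeline is meant to face.

- **Cohort** (`generate_cohort()`): 109 controls spanning −0.44 to 73.3
  years, 34 adult cases (18.6–71.9). Ages are stratified-uniform on the
  transformed `t` scale (one draw per equal-width stratum), which
  guarantees every developmental stage is populated — an iid-uniform
  draw on chronological age would leave the fetal period almost empty.
  Sex, race, batch, pH, and PMI are drawn categorically/log-normally;
  antipsychotic dose (lifetime/daily/last chlorpromazine equivalents),
  antidepressant flags, and cotinine are populated for cases (cotinine
  also for a smoking fraction of fetal donors).
- **Counts** (`generate_mirna_counts()`): miRNA i in donor s is
  `NB(mean = L_s · q_is, size = 1/0.15)` with
  `log2 q ∝ baseline_i + 2 · template_g(i)(t_s) + batch + case effects`.
  The nine templates (Gaussian bumps and logistic steps anchored at
  birth, 1, 3, 6, and 12 years on the `t` scale) encode the qualitative
  trajectory families seen in developing brain: fetal-high decline,
  perinatal and infant peaks, toddler troughs, a preschool–prepuberty
  wave. Amplitude 2 (log2) and dispersion 0.15 put per-feature
  signal-to-noise in the range where clustering is solvable but not
  trivial; library sizes are log-normal around 10⁷ reads.
- **Planted effects**: per-miRNA `planted_de` log2FCs, concordant
  `group_shift`s (the GSEA target), `coupling` records
  (miRNA → gene, slope acting on the *standardized* miRNA log-CPM with
  `N(0, mrna_noise_sd)` residuals, so the expected pair correlation is
  exactly `slope/√(slope² + σ²)` — slope −1 with unit noise gives
  r ≈ −0.71), and planted CoR genes receiving extra binding sites from
  several group miRNAs.
- **Limits.** The generator is a caricature: templates are smooth and
  shared exactly within groups, dispersion is common across miRNAs,
  batch effects are additive log-normal, and the mRNA matrix is Gaussian
  rather than count-valued (it stands in for array-style expression).
  These simplifications are deliberate — every planted quantity has a
  closed-form expectation the tests can check — but absolute effect
  sizes in real cohorts will differ.

Seeds: every generator takes `seed` (default `config$seed`); the mRNA
and target-map draws use fixed internal offsets so the four artefacts
are mutually independent yet jointly reproducible.

## 7. Problem sizes and runtime

The analysis workflow (`analysis/01…07`) runs 540 miRNAs × 143 donors ×
2000 genes: large enough that each temporal group exceeds the GSEA
`min_size` of 51 and the target map holds ~20k pairs, small enough that
the full chain finishes in ~10 minutes on one CPU (the IoA permutation
null dominates — each permutation re-runs a DTW clustering, quadratic in
both profiles and donors, so that stage subsamples 120 miRNAs). The test
suite uses 36–180 miRNAs × 60–80 donors; `scripts/acceptance.R` finishes
in about a minute.

```{r example}
cfg <- cohort_config(n_control = 60, n_case = 0, n_mirna = 90, n_mrna = 60,
                     seed = 1)
cohort <- generate_cohort(cfg)
prof <- build_profiles(generate_mirna_counts(cohort, cfg), cohort)
gap_statistic(prof$zscores, k_max = 12, B = 50, seed = 1)$k_selected
```
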