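# adult-only config: case and control age ranges coincide, so diagnosis
# contrasts are not confounded with the temporal templates
adult_config <- function(seed = 1L, ...) {
  small_config(seed = seed, age_range_years = c(20, 70),
               case_age_range = c(20, 70), ...)
}

test_that("generators are bit-identical under a fixed seed", {
  cfg <- small_config(seed = 42, n_case = 10)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  coh <- generate_cohort(cfg)
  expect_identical(generate_mirna_counts(coh, cfg),
                   generate_mirna_counts(coh, cfg))
  expect_identical(generate_mrna_matrix(coh, cfg),
                   generate_mrna_matrix(coh, cfg))
  expect_identical(generate_target_map(cfg), generate_target_map(cfg))
  # a different seed changes the draw
  expect_false(identical(generate_cohort(cfg),
                         generate_cohort(cfg, seed = 43)))
})

test_that("the default cohort has the documented shape", {
  cfg <- cohort_config()
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh), 143L)
  expect_equal(sum(coh$diagnosis == "case"), 34L)
  ctrl <- coh[coh$diagnosis == "control", ]
  case <- coh[coh$diagnosis == "case", ]
  expect_true(all(ctrl$age_years >= -0.44 & ctrl$age_years <= 73.3))
  expect_true(all(case$age_years >= 18.6 & case$age_years <= 71.9))
  # stratified draw populates every developmental stage among controls
  expect_setequal(unique(as.character(developmental_stage(ctrl$age_years))),
                  c("fetal", "infant", "toddler", "preschool", "prepuberty",
                    "adolescent", "young_adult", "adult", "senior"))
  # medication fields: cases complete, non-fetal controls NA
  expect_true(all(!is.na(case$cpze_lifetime)))
  expect_true(all(!is.na(case$antidepressant)))
  expect_true(all(is.na(ctrl$cpze_lifetime)))
  expect_true(all(is.na(ctrl$cotinine[ctrl$age_years >= 0])))
})

test_that("a control-only cohort carries no medication data", {
  coh <- generate_cohort(small_config(seed = 2))
  expect_true(all(coh$diagnosis == "control"))
  expect_true(all(is.na(coh$cpze_lifetime)))
  expect_true(all(is.na(coh$cpze_daily)))
  expect_true(all(is.na(coh$antidepressant)))
})

test_that("counts are NB with the configured library scale and group attr", {
  cfg <- small_config(seed = 3)
  coh <- generate_cohort(cfg)
  cnt <- generate_mirna_counts(coh, cfg)
  expect_true(is.integer(cnt) || all(cnt == round(cnt)))
  expect_true(all(cnt >= 0))
  expect_equal(dim(cnt), c(72L, 60L))
  expect_equal(rownames(cnt), mirna_ids(cfg))
  expect_equal(colnames(cnt), coh$sample_id)
  grp <- attr(cnt, "group")
  expect_equal(sort(unique(grp)), 1:9)
  # realized depth tracks the drawn library sizes
  lib <- attr(cnt, "library_sizes")
  ratio <- unname(colSums(cnt)) / unname(lib)
  # per-sample depth is NB-noisy around the drawn library size
  expect_true(all(abs(ratio - 1) < 0.5))
  expect_equal(mean(ratio), 1, tolerance = 0.05)
})

test_that("zero amplitude removes the temporal signal", {
  coh <- generate_cohort(small_config(seed = 5))
  tage <- transform_age(coh$age_years)
  r_of <- function(amp) {
    cfg <- small_config(seed = 5, amplitude = amp)
    lcpm <- log2(cpm_normalize(generate_mirna_counts(coh, cfg)) + 1)
    mean(abs(apply(lcpm, 1, cor, y = tage)))
  }
  expect_lt(r_of(0), 0.15)       # null |r| scale at n = 60
  expect_gt(r_of(2), 2 * r_of(0))
})

test_that("planted per-miRNA effects appear with size and sign", {
  cfg <- adult_config(seed = 7, n_control = 40, n_case = 40,
                      planted_de = data.frame(mirna_id = c("miR-0001",
                                                           "miR-0002"),
                                              log2fc = c(2, -1.5)))
  coh <- generate_cohort(cfg)
  lcpm <- log2(cpm_normalize(generate_mirna_counts(coh, cfg)) + 1)
  d <- rowMeans(lcpm[, coh$diagnosis == "case"]) -
    rowMeans(lcpm[, coh$diagnosis == "control"])
  expect_equal(unname(d["miR-0001"]), 2, tolerance = 0.5)
  expect_equal(unname(d["miR-0002"]), -1.5, tolerance = 0.5)
  expect_lt(mean(abs(d[-(1:2)])), 0.3)
})

test_that("group shifts move the whole temporal group concordantly", {
  cfg <- adult_config(seed = 8, n_control = 40, n_case = 40,
                      group_shift = c("3" = 1.5))
  coh <- generate_cohort(cfg)
  cnt <- generate_mirna_counts(coh, cfg)
  lcpm <- log2(cpm_normalize(cnt) + 1)
  d <- rowMeans(lcpm[, coh$diagnosis == "case"]) -
    rowMeans(lcpm[, coh$diagnosis == "control"])
  grp <- attr(cnt, "group")
  expect_gt(mean(d[grp == 3] > 0.5), 0.9)
  expect_lt(mean(abs(d[grp != 3])), 0.3)
})

test_that("target map plants CoR genes and rejects degenerate configs", {
  cfg <- small_config(seed = 9, n_mirna = 90, n_mrna = 300, cor_group = 4,
                      n_cor_genes = 5, cor_n_mirnas = 3, cor_extra_sites = 6)
  tm <- generate_target_map(cfg)
  validate_target_map(tm)
  planted <- attr(tm, "planted_cor_genes")
  expect_length(planted, 5L)
  grp_mir <- names(mirna_groups(cfg))[mirna_groups(cfg) == 4]
  for (g in planted) {
    sub <- tm[tm$gene == g & tm$mirna %in% grp_mir, ]
    # at least 3 distinct group miRNAs each contribute the planted 6 sites
    # (background targeting may add more miRNAs with fewer sites)
    expect_gte(sum(tapply(sub$n_sites, sub$mirna, sum) >= 6), 3L)
  }
  # no duplicate (mirna, transcript) rows after collapsing
  expect_false(anyDuplicated(paste(tm$mirna, tm$transcript)) > 0)
  expect_error(generate_target_map(small_config(p_target = 0)),
               "empty target map")
})

test_that("coupling attains the documented correlation in both regimes", {
  pairs <- data.frame(mirna_id = sprintf("miR-%04d", 1:50),
                      gene_id = sprintf("GENE%05d", 1:50), slope = -1)
  r_at_noise <- function(noise_sd) {
    cfg <- cohort_config(n_control = 109, n_case = 0, n_mirna = 72,
                         n_mrna = 60, coupling = pairs,
                         mrna_noise_sd = noise_sd, seed = 11)
    coh <- generate_cohort(cfg)
    cnt <- generate_mirna_counts(coh, cfg)
    mrna <- generate_mrna_matrix(coh, cfg, mirna_counts = cnt)
    lcpm <- log2(cpm_normalize(cnt) + 1)
    mean(vapply(seq_len(nrow(pairs)),
                function(i) cor(lcpm[pairs$mirna_id[i], ],
                                mrna[pairs$gene_id[i], ]), 0))
  }
  # noise -> 0: perfect anticorrelation
  expect_equal(r_at_noise(1e-6), -1, tolerance = 1e-3)
  # unit noise: E[r] = -1/sqrt(2) ~ -0.707
  expect_equal(r_at_noise(1), -1 / sqrt(2), tolerance = 0.05)
})

test_that("uncoupled pair p-values are near-uniform", {
  cfg <- small_config(seed = 13, n_mirna = 36, n_mrna = 250)
  coh <- generate_cohort(cfg)
  cnt <- generate_mirna_counts(coh, cfg)
  mrna <- generate_mrna_matrix(coh, cfg)
  tm <- generate_target_map(cfg)
  res <- pair_correlations(log2(cpm_normalize(cnt) + 1), mrna, tm)
  expect_gt(suppressWarnings(ks.test(res$p, "punif"))$p.value, 0.001)
})
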