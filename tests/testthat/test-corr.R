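# tiny deterministic map over two pairs
toy_map <- function() {
  data.frame(mirna = c("m1", "m2"), gene = c("G1", "G2"),
             transcript = c("G1.T1", "G2.T1"), n_sites = 1L,
             stringsAsFactors = FALSE)
}

test_that("pair correlations match cor()/cor.test() on a hand example", {
  s <- paste0("s", 1:6)
  mi <- rbind(m1 = c(1, 2, 3, 4, 5, 6), m2 = c(2, 1, 4, 3, 6, 5))
  mr <- rbind(G1 = c(6, 5, 4, 3, 2, 1), G2 = c(1.2, 0.9, 2.5, 2.1, 3.3, 3.0))
  colnames(mi) <- colnames(mr) <- s
  res <- pair_correlations(mi, mr, toy_map())
  expect_equal(nrow(res), 2L)
  for (i in 1:2) {
    ct <- cor.test(mi[res$mirna_id[i], ], mr[res$gene_id[i], ])
    expect_equal(res$r[i], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p[i], ct$p.value, tolerance = 1e-12)
  }
  expect_equal(res$r[1], -1)
  expect_equal(res$fdr, bh_adjust(res$p))
  # random matrices against the cor() oracle
  set.seed(19)
  mi2 <- matrix(rnorm(8 * 12), 8, 12,
                dimnames = list(paste0("m", 1:8), paste0("s", 1:12)))
  mr2 <- matrix(rnorm(10 * 12), 10, 12,
                dimnames = list(paste0("G", 1:10), paste0("s", 1:12)))
  map2 <- expand.grid(mirna = rownames(mi2), gene = rownames(mr2),
                      stringsAsFactors = FALSE)
  map2$transcript <- paste0(map2$gene, ".T1")
  map2$n_sites <- 1L
  res2 <- pair_correlations(mi2, mr2, map2)
  want <- mapply(function(m, g) cor(mi2[m, ], mr2[g, ]),
                 res2$mirna_id, res2$gene_id)
  expect_equal(res2$r, unname(want), tolerance = 1e-12)
})

test_that("classification uses r > 0.49 (strict) and FDR < 0.05 jointly", {
  # strong pair well over threshold, weak pair under it, on many samples so
  # FDR separates them cleanly
  set.seed(23)
  n <- 120
  base <- rnorm(n)
  mi <- rbind(m1 = base, m2 = rnorm(n))
  mr <- rbind(G1 = 0.9 * base + rnorm(n, 0, sqrt(1 - 0.81)),
              G2 = rnorm(n))
  colnames(mi) <- colnames(mr) <- paste0("s", 1:n)
  res <- pair_correlations(mi, mr, toy_map())
  expect_equal(res$class[res$mirna_id == "m1"], "positive")
  expect_equal(res$class[res$mirna_id == "m2"], "none")
  # r exactly at the threshold is NOT positive; just above it is
  res_at <- pair_correlations(mi, mr, toy_map(), r_threshold = res$r[1])
  expect_equal(res_at$class[1], "none")
  res_below <- pair_correlations(mi, mr, toy_map(),
                                 r_threshold = res$r[1] - 1e-9)
  expect_equal(res_below$class[1], "positive")
  # significant r but FDR blocked by a high threshold
  res_fdr <- pair_correlations(mi, mr, toy_map(), fdr_threshold = 0)
  expect_true(all(res_fdr$class == "none"))
})

test_that("correlations are invariant to affine rescaling of either side", {
  set.seed(31)
  mi <- matrix(rnorm(4 * 20), 4, 20,
               dimnames = list(paste0("m", 1:4), paste0("s", 1:20)))
  mr <- matrix(rnorm(4 * 20), 4, 20,
               dimnames = list(paste0("G", 1:4), paste0("s", 1:20)))
  map <- data.frame(mirna = rownames(mi), gene = rownames(mr),
                    transcript = paste0(rownames(mr), ".T1"), n_sites = 1L,
                    stringsAsFactors = FALSE)
  r0 <- pair_correlations(mi, mr, map)
  r1 <- pair_correlations(3 * mi + 7, 0.5 * mr - 2, map)
  expect_equal(r1$r, r0$r, tolerance = 1e-12)
  expect_equal(r1$p, r0$p, tolerance = 1e-12)
})

test_that("zero-variance pairs are skipped and small cohorts rejected", {
  s <- paste0("s", 1:6)
  mi <- rbind(m1 = rep(5, 6), m2 = rnorm(6))
  mr <- rbind(G1 = rnorm(6), G2 = rnorm(6))
  colnames(mi) <- colnames(mr) <- s
  expect_warning(res <- pair_correlations(mi, mr, toy_map()),
                 "zero-variance")
  expect_equal(nrow(res), 1L)
  expect_equal(attr(res, "skipped")$mirna, "m1")
  expect_error(pair_correlations(mi[, 1:3], mr[, 1:3], toy_map()),
               ">= 4 shared samples")
})

test_that("planted negative coupling yields negative-class pairs and the
           shuffled null destroys them", {
  cfg0 <- small_config(seed = 6, n_control = 80, n_mirna = 36, n_mrna = 250,
                       mrna_noise_sd = 0.4)
  tm <- generate_target_map(cfg0)
  # couple the first 60 target pairs with slope -1
  pairs <- unique(tm[, c("mirna", "gene")])[1:60, ]
  cfg <- small_config(seed = 6, n_control = 80, n_mirna = 36, n_mrna = 250,
                      mrna_noise_sd = 0.4,
                      coupling = data.frame(mirna_id = pairs$mirna,
                                            gene_id = pairs$gene,
                                            slope = -1))
  coh <- generate_cohort(cfg)
  cnt <- generate_mirna_counts(coh, cfg)
  mrna <- generate_mrna_matrix(coh, cfg, mirna_counts = cnt)
  mi_log <- log2(cpm_normalize(cnt) + 1)
  res <- pair_correlations(mi_log, mrna, tm)
  coupled <- paste(res$mirna_id, res$gene_id) %in%
    paste(pairs$mirna, pairs$gene)
  frac_neg <- mean(res$class == "negative")
  # slope -1, noise 0.4 => E[r] = -1/sqrt(1.16) ~ -0.93, far past -0.49
  expect_gt(mean(res$class[coupled] == "negative"), 0.9)
  expect_lt(mean(res$r[coupled]), -0.8)
  null <- shuffled_null(mi_log, mrna, tm, n_shuffles = 10, seed = 2)
  expect_lt(null$mean_negative, frac_neg / 10)
  expect_lt(null$mean_positive, 0.01)
  # determinism
  null2 <- shuffled_null(mi_log, mrna, tm, n_shuffles = 10, seed = 2)
  expect_identical(null$fractions, null2$fractions)
  expect_error(shuffled_null(mi_log, mrna, tm, n_shuffles = 0), "n_shuffles")
})

test_that("without coupling the observed fractions match the null scale", {
  cfg <- small_config(seed = 10, n_control = 60, n_mirna = 36, n_mrna = 250)
  coh <- generate_cohort(cfg)
  cnt <- generate_mirna_counts(coh, cfg)
  mrna <- generate_mrna_matrix(coh, cfg)   # coupling NULL: mRNA pure noise
  tm <- generate_target_map(cfg)
  mi_log <- log2(cpm_normalize(cnt) + 1)
  res <- pair_correlations(mi_log, mrna, tm)
  expect_lt(mean(res$class != "none"), 0.02)
  expect_lt(abs(mean(res$r)), 0.1)
})
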