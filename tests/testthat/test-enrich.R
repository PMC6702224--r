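test_that("site-enrichment point probability equals the printed formula", {
  # C(4,4) C(4,0) / C(8,4) = 1/70
  expect_equal(mre_enrichment_p(4, 0, 0, 4, mode = "point"), 1 / 70)
  # degenerate margins
  expect_equal(mre_enrichment_p(0, 0, 5, 5), 1)
  expect_equal(mre_enrichment_p(0, 3, 0, 7), 1)   # no group sites anywhere
  expect_error(mre_enrichment_p(-1, 1, 1, 1), "negative")
  # point term never exceeds the tail
  set.seed(2)
  for (i in 1:50) {
    tb <- rpois(4, 3)
    expect_lte(mre_enrichment_p(tb[1], tb[2], tb[3], tb[4], "point"),
               mre_enrichment_p(tb[1], tb[2], tb[3], tb[4], "tail") + 1e-12)
  }
})

test_that("Fisher tail equals margin-fixed enumeration for all small tables", {
  # all margins with grand total <= 30, every feasible n11
  got <- want <- numeric(0)
  for (m in 1:15) for (nn in 1:15) for (k in 1:(m + nn - 1)) {
    xs <- max(0, k - nn):min(m, k)
    denom <- choose(m + nn, k)
    probs <- choose(m, xs) * choose(nn, k - xs) / denom
    for (x in xs) {
      got <- c(got, mre_enrichment_p(x, k - x, m - x, nn - (k - x), "tail"))
      want <- c(want, sum(probs[xs >= x]))
    }
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("GSEA running sum reproduces hand and fgsea enrichment scores", {
  ranked <- data.frame(feature_id = c("t", "a", "b"), score = c(2, 1, 1))
  res <- preranked_gsea(ranked, list(top = "t"), n_perm = 100, seed = 1)
  expect_equal(res$es, 1)   # hit step to 1 at position 1 before any miss
  # independent implementation cross-check on random rankings
  set.seed(12)
  scores <- sort(rnorm(60), decreasing = TRUE)
  ids <- sprintf("m%02d", 1:60)
  for (i in 1:5) {
    members <- sample(ids, 10)
    res <- preranked_gsea(data.frame(feature_id = ids, score = scores),
                          setNames(list(members), "s"), n_perm = 100,
                          seed = i)
    expect_equal(res$es,
                 fgsea::calcGseaStat(setNames(scores, ids),
                                     which(ids %in% members),
                                     gseaParam = 1),
                 tolerance = 1e-12)
  }
})

test_that("GSEA of the reversed ranking negates the enrichment score", {
  set.seed(3)
  ids <- sprintf("m%02d", 1:40)
  scores <- sort(rnorm(40), decreasing = TRUE)
  members <- sample(ids, 8)
  fwd <- preranked_gsea(data.frame(feature_id = ids, score = scores),
                        list(s = members), n_perm = 100, seed = 1)
  rev <- preranked_gsea(data.frame(feature_id = ids, score = -scores),
                        list(s = members), n_perm = 100, seed = 1)
  expect_equal(rev$es, -fwd$es, tolerance = 1e-12)
  expect_true(abs(fwd$es) <= 1)
  expect_equal(sign(fwd$nes), sign(fwd$es))
  expect_gte(fwd$p, 1 / 101)
})

test_that("GSEA null behaviour: random sets are unremarkable, planted shifts
           are found with the right sign", {
  set.seed(44)
  ids <- sprintf("m%03d", 1:200)
  scores <- sort(rnorm(200), decreasing = TRUE)
  ranked <- data.frame(feature_id = ids, score = scores)
  # random sets: |NES| near 1, p spread out
  res <- preranked_gsea(ranked,
                        setNames(lapply(1:10, function(i) sample(ids, 20)),
                                 paste0("r", 1:10)),
                        n_perm = 200, seed = 2)
  expect_lt(abs(mean(abs(res$nes)) - 1), 0.3)
  expect_gt(mean(res$p > 0.05), 0.5)
  # planted up-shift: members pushed to the top of the ranking
  up <- ids[rank(-scores) <= 60][sample(60, 25)]
  res_up <- preranked_gsea(ranked, list(up = up), n_perm = 200, seed = 3)
  expect_gt(res_up$nes, 0)
  expect_lt(res_up$fdr, 0.05)
  # members outside the universe are dropped with a warning
  expect_warning(
    preranked_gsea(ranked, list(s = c(ids[1:10], "absent")), n_perm = 100,
                   seed = 1),
    "outside the ranked universe")
})

test_that("CoR calls need site enrichment AND >= 2 distinct group miRNAs", {
  # gene G1: hugely enriched but targeted by a single group miRNA
  tm <- data.frame(
    mirna = c("g1", "g1", "o1", "o2", "o1", "o2", "o1"),
    gene = c("G1", "G2", "G2", "G2", "G3", "G3", "G4"),
    transcript = c("G1.T1", "G2.T1", "G2.T1", "G2.T2", "G3.T1", "G3.T2",
                   "G4.T1"),
    n_sites = c(20L, 1L, 3L, 2L, 4L, 2L, 6L),
    stringsAsFactors = FALSE)
  expect_error(cor_gene_test(tm, c("g1", "g2x")), "absent")
  res <- cor_gene_test(tm, "g1")
  g1 <- res[res$gene_id == "G1", ]
  expect_lt(g1$fdr, 0.05)               # enrichment is overwhelming
  expect_equal(g1$n_group_mirnas_targeting, 1L)
  expect_false(g1$is_cor)               # single targeting miRNA blocks the call
  # group = entire miRNA universe: no non-group sites, all p = 1
  res_all <- cor_gene_test(tm, c("g1", "o1", "o2"))
  expect_true(all(res_all$p == 1))
  expect_false(any(res_all$is_cor))
  expect_error(cor_gene_test(tm, character()), "empty")
})

test_that("planted co-regulated genes are recovered in the synthetic map", {
  hits <- sapply(1:3, function(s) {
    cfg <- small_config(seed = s, n_mirna = 90, n_mrna = 400,
                        cor_group = 6, n_cor_genes = 8)
    tm <- generate_target_map(cfg)
    planted <- attr(tm, "planted_cor_genes")
    groups <- mirna_groups(cfg)
    res <- cor_gene_test(tm, names(groups)[groups == 6])
    mean(res$is_cor[match(planted, res$gene_id)])
  })
  expect_gte(mean(hits), 0.9)
})

test_that("two-sample KS enrichment matches direct formula on 5 vs 5", {
  pg <- setNames(c(0.01, 0.02, 0.05, 0.30, 0.60,
                   0.10, 0.20, 0.40, 0.70, 0.90),
                 paste0("G", 1:10))
  set_g <- paste0("G", 1:5)
  bg <- paste0("G", 6:10)
  # direct D computation: max |ecdf difference| over the pooled values
  vals <- sort(unique(pg))
  D <- max(abs(vapply(vals, function(v)
    mean(pg[set_g] <= v) - mean(pg[bg] <= v), 0)))
  res <- ks_set_enrichment(pg, set_g, bg)
  expect_equal(res$D, D)
  expect_equal(res$direction, "enriched")
  # complete separation: D = 1
  pg2 <- setNames(c(0.001, 0.002, 0.003, 0.5, 0.6, 0.7), paste0("H", 1:6))
  res2 <- ks_set_enrichment(pg2, paste0("H", 1:3), paste0("H", 4:6))
  expect_equal(res2$D, 1)
  expect_equal(res2$direction, "enriched")
})

test_that("hypergeometric gene-set targeting matches enumeration", {
  tm <- data.frame(mirna = rep(c("g1", "g2"), each = 4),
                   gene = paste0("G", c(1:4, 1:2, 5:6)),
                   transcript = paste0("G", c(1:4, 1:2, 5:6), ".T1"),
                   n_sites = 1L, stringsAsFactors = FALSE)
  tm <- tm[!duplicated(paste(tm$mirna, tm$transcript)), ]
  universe <- paste0("G", 1:10)
  # draws = genes of g1 (G1..G4), set = G1..G4 + G9 => overlap 4
  res <- set_targeting_test(tm, "g1", c(paste0("G", 1:4), "G9"), universe)
  expect_equal(res$overlap, 4L)
  expect_equal(res$p, choose(5, 4) * choose(5, 0) / choose(10, 4))
  # zero overlap: p near 1
  res0 <- set_targeting_test(tm, "g1", c("G7", "G8"), universe)
  expect_gt(res0$p, 0.5)
  expect_error(set_targeting_test(tm, "g1", "ZZZ", universe), "disjoint")
  # brute-force oracle for small cases
  set.seed(9)
  for (i in 1:20) {
    N <- sample(8:20, 1); K <- sample(1:(N - 1), 1); n <- sample(1:(N - 1), 1)
    k <- sample(0:min(K, n), 1)
    xs <- 0:min(K, n)
    probs <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
    expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 sum(probs[xs >= k]), tolerance = 1e-12)
  }
})
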