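#' Preranked gene set enrichment analysis
#'
#' Classic running-sum GSEA on a ranked list: walking down the ranking, set
#' members increment the sum proportionally to |score|^weight (normalized to
#' sum to 1 over members), non-members decrement it by 1/(N - Nh). The
#' enrichment score ES is the extremum of the running sum; the null
#' distribution draws `n_perm` random member sets of the same size from the
#' ranked universe. NES = ES / mean(|null ES| of matching sign); the nominal
#' p is the one-sided permutation p among same-sign null ES; FDR is BH
#' across the tested sets.
#'
#' @param ranked data.frame with columns `feature_id`, `score`, ordered
#'   descending by score (ties broken by id; see [write_rank_file()]), or an
#'   unordered one which will be ordered the same way.
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#'   Members absent from the ranked universe are dropped with a warning.
#' @param n_perm Permutations (>= 100).
#' @param weight Exponent on |score| for hit increments (default 1;
#'   0 = classic Kolmogorov-Smirnov walk).
#' @param min_size,max_size Set-size bounds after intersection with the
#'   universe; the temporal-group analysis uses `min_size = 51` (groups with
#'   more than 50 members).
#' @param seed RNG seed.
#' @return data.frame: set, size, es, nes, p, fdr.
#' @export
preranked_gsea <- function(ranked, sets, n_perm = 1000, weight = 1,
                           min_size = 1, max_size = Inf, seed = NULL) {
  stopifnot(is.data.frame(ranked),
            all(c("feature_id", "score") %in% colnames(ranked)))
  if (n_perm < 100L) stopf("n_perm must be >= 100")
  if (anyDuplicated(ranked$feature_id)) stopf("duplicate features in ranking")
  o <- order(-ranked$score, ranked$feature_id)
  ids <- ranked$feature_id[o]
  scores <- ranked$score[o]
  n <- length(ids)
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(names(sets), function(nm) {
    members <- sets[[nm]]
    outside <- setdiff(members, ids)
    if (length(outside))
      warnf("set '%s': %d member(s) outside the ranked universe dropped",
            nm, length(outside))
    members <- intersect(members, ids)
    sz <- length(members)
    if (sz < min_size || sz > max_size || sz == 0L || sz >= n) return(NULL)
    hit <- ids %in% members
    es <- gsea_es(scores, hit, weight)
    null_es <- vapply(seq_len(n_perm), function(i) {
      h <- logical(n)
      h[sample.int(n, sz)] <- TRUE
      gsea_es(scores, h, weight)
    }, 0)
    same <- null_es[sign(null_es) == sign(es)]
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    data.frame(set = nm, size = sz, es = es, nes = nes, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res) || nrow(res) == 0L)
    return(data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), p = numeric(), fdr = numeric()))
  res$fdr <- bh_adjust(res$p)
  rownames(res) <- NULL
  res
}

gsea_es <- function(scores, hit, weight) {
  w <- abs(scores[hit])^weight
  if (sum(w) == 0) w <- rep(1, sum(hit))   # all-zero scores: flat hit steps
  inc <- numeric(length(scores))
  inc[hit] <- w / sum(w)
  inc[!hit] <- -1 / sum(!hit)
  run <- cumsum(inc)
  mx <- max(run); mn <- min(run)
  if (mx >= -mn) mx else mn
}

#' Site-count enrichment p-value for one transcript
#'
#' The contingency table counts miRNA binding sites: `n11` sites of
#' group miRNAs in the tested transcript, `n12` sites of non-group miRNAs in
#' it, `n21`/`n22` the corresponding site counts over all other transcripts.
#' `mode = "point"` returns the hypergeometric point probability
#' C(n11+n21, n11) C(n12+n22, n12) / C(n.., n11+n12); `mode = "tail"`
#' (default) the one-sided enrichment tail of Fisher's exact test, i.e. the
#' sum of point probabilities of tables at least as enriched. Computed in
#' log space. Degenerate margins give p = 1.
#'
#' @param n11,n12,n21,n22 Non-negative integer cell counts.
#' @param mode `"tail"` or `"point"`.
#' @export
mre_enrichment_p <- function(n11, n12, n21, n22, mode = c("tail", "point")) {
  mode <- match.arg(mode)
  if (any(c(n11, n12, n21, n22) < 0)) stopf("negative cell count")
  m <- n11 + n21          # total group sites
  nn <- n12 + n22         # total non-group sites
  k <- n11 + n12          # sites in the tested transcript
  if (m == 0 || nn == 0 || k == 0) return(1)
  if (mode == "point") dhyper(n11, m, nn, k)
  else phyper(n11 - 1, m, nn, k, lower.tail = FALSE)
}

#' Identify genes co-regulated by a miRNA group (CoR genes)
#'
#' Every transcript in the target map is tested for enrichment of binding
#' sites of the group's miRNAs relative to all other transcripts
#' ([mre_enrichment_p()], Fisher tail by default), with BH-FDR across all
#' tested transcripts in the run. A gene is a CoR gene when at least one of
#' its transcripts reaches FDR < `fdr_threshold` AND the gene is targeted by
#' at least `min_mirnas` (default 2) distinct miRNAs of the group.
#'
#' @param target_map data.frame from [read_target_map()] /
#'   [generate_target_map()].
#' @param group_mirnas Character vector of the group's miRNA ids (must be a
#'   subset of the map's miRNA universe).
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @param min_mirnas Minimum distinct group miRNAs targeting the gene.
#' @param mode p-value mode passed to [mre_enrichment_p()].
#' @return data.frame per gene: gene_id, best_transcript, p, fdr,
#'   n_group_mirnas_targeting, is_cor.
#' @export
cor_gene_test <- function(target_map, group_mirnas, fdr_threshold = 0.05,
                          min_mirnas = 2, mode = "tail") {
  validate_target_map(target_map)
  if (!length(group_mirnas)) stopf("empty miRNA group")
  if (!all(group_mirnas %in% target_map$mirna))
    stopf("group miRNA(s) absent from the target map universe")
  in_group <- target_map$mirna %in% group_mirnas
  grp_tx <- rowsum(target_map$n_sites * in_group, target_map$transcript)
  oth_tx <- rowsum(target_map$n_sites * !in_group, target_map$transcript)
  tx <- rownames(grp_tx)
  tot_grp <- sum(target_map$n_sites[in_group])
  tot_oth <- sum(target_map$n_sites[!in_group])
  n11 <- grp_tx[, 1L]
  n12 <- oth_tx[, 1L]
  p <- vapply(seq_along(tx), function(i)
    mre_enrichment_p(n11[i], n12[i], tot_grp - n11[i], tot_oth - n12[i],
                     mode = mode), 0)
  fdr <- bh_adjust(p)
  gene_of_tx <- target_map$gene[match(tx, target_map$transcript)]
  # distinct group miRNAs per gene
  sub <- unique(target_map[in_group, c("mirna", "gene")])
  n_grp_mir <- table(sub$gene)
  genes <- sort(unique(gene_of_tx))
  best <- vapply(genes, function(g) {
    idx <- which(gene_of_tx == g)
    idx[which.min(fdr[idx])]
  }, 0L)
  n_tgt <- as.integer(n_grp_mir[genes])
  n_tgt[is.na(n_tgt)] <- 0L
  data.frame(gene_id = genes,
             best_transcript = tx[best],
             p = p[best], fdr = fdr[best],
             n_group_mirnas_targeting = n_tgt,
             is_cor = fdr[best] < fdr_threshold & n_tgt >= min_mirnas,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Kolmogorov-Smirnov enrichment of a gene set's p-value distribution
#'
#' Two-sample KS test of the set's per-gene enrichment p-values against the
#' background's (all targeted genes). A leftward shift (smaller p in the
#' set) is reported as direction "enriched".
#'
#' @param p_gene Named numeric vector, gene -> enrichment p.
#' @param gene_set Character vector of set members.
#' @param background Character vector of background genes (default: all
#'   names of `p_gene`).
#' @return List: `D`, `p`, `direction`, `n_set`, `n_background`.
#' @export
ks_set_enrichment <- function(p_gene, gene_set, background = names(p_gene)) {
  set <- intersect(gene_set, names(p_gene))
  bg <- intersect(background, names(p_gene))
  if (!length(intersect(set, bg)) && !length(set))
    stopf("gene set does not intersect the scored universe")
  if (length(set) < 3L)
    warnf("gene set has < 3 scored members; exact small-sample KS p used")
  ks <- suppressWarnings(ks.test(p_gene[set], p_gene[bg]))
  list(D = unname(ks$statistic), p = ks$p.value,
       direction = if (stats::median(p_gene[set]) <
                       stats::median(p_gene[bg])) "enriched" else "depleted",
       n_set = length(set), n_background = length(bg))
}

#' Hypergeometric test of gene-set targeting by a miRNA group
#'
#' Population = `universe` (genes targeted by any expressed miRNA);
#' successes = gene-set members within the universe; draws = genes targeted
#' by at least one group miRNA; observed = overlap of draws with the set.
#' Returns the upper-tail probability P(X >= observed).
#'
#' @param target_map Target map data.frame.
#' @param group_mirnas The group's miRNA ids.
#' @param gene_set Character vector of gene ids.
#' @param universe Character vector of background genes (default: all genes
#'   in the map).
#' @return List: `p`, `overlap`, `n_drawn`, `n_set_in_universe`,
#'   `n_universe`.
#' @export
set_targeting_test <- function(target_map, group_mirnas, gene_set,
                               universe = unique(target_map$gene)) {
  validate_target_map(target_map)
  K_set <- intersect(gene_set, universe)
  if (!length(K_set)) stopf("gene set disjoint from the universe")
  drawn <- intersect(unique(target_map$gene[target_map$mirna %in%
                                              group_mirnas]), universe)
  k <- length(intersect(K_set, drawn))
  N <- length(universe); K <- length(K_set); n_draw <- length(drawn)
  list(p = phyper(k - 1, K, N - K, n_draw, lower.tail = FALSE),
       overlap = k, n_drawn = n_draw, n_set_in_universe = K,
       n_universe = N)
}
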