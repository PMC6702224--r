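#' Pearson correlation of miRNA-target mRNA pairs
#'
#' For every (miRNA, gene) pair in the target map present in both matrices,
#' the Pearson correlation across the shared samples is computed with a
#' two-sided t-test p-value and BH-FDR over all tested pairs. Pairs are
#' classified against the printed thresholds: positive (r > `r_threshold`
#' and FDR < `fdr_threshold`), negative (r < -`r_threshold` and FDR <
#' `fdr_threshold`), otherwise none. Zero-variance series make the pair
#' undefined; such pairs are skipped and flagged.
#'
#' @param mirna_expr miRNA expression matrix (log2 CPM recommended),
#'   features x samples.
#' @param mrna_expr mRNA expression matrix over the same samples.
#' @param target_map Target map restricting the tested pairs.
#' @param r_threshold Absolute correlation threshold (default 0.49).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @return data.frame: mirna_id, gene_id, r, p, fdr, class; skipped pairs in
#'   attribute `"skipped"`.
#' @export
pair_correlations <- function(mirna_expr, mrna_expr, target_map,
                              r_threshold = 0.49, fdr_threshold = 0.05) {
  shared <- intersect(colnames(mirna_expr), colnames(mrna_expr))
  if (length(shared) < 4L) stopf("need >= 4 shared samples")
  pairs <- unique(target_map[, c("mirna", "gene")])
  pairs <- pairs[pairs$mirna %in% rownames(mirna_expr) &
                   pairs$gene %in% rownames(mrna_expr), , drop = FALSE]
  if (!nrow(pairs)) stopf("no target-map pair present in both matrices")
  x <- mirna_expr[, shared, drop = FALSE]
  y <- mrna_expr[, shared, drop = FALSE]
  ok_x <- apply(x, 1L, sd) > 0
  ok_y <- apply(y, 1L, sd) > 0
  usable <- ok_x[pairs$mirna] & ok_y[pairs$gene]
  skipped <- pairs[!usable, , drop = FALSE]
  if (nrow(skipped)) warnf("%d pair(s) with zero-variance series skipped",
                           nrow(skipped))
  pairs <- pairs[usable, , drop = FALSE]
  n <- length(shared)
  # row-standardize once, then r is a scaled cross-product
  xs <- t(scale(t(x[unique(pairs$mirna), , drop = FALSE])))
  ys <- t(scale(t(y[unique(pairs$gene), , drop = FALSE])))
  r <- rowSums(xs[pairs$mirna, , drop = FALSE] *
                 ys[pairs$gene, , drop = FALSE]) / (n - 1)
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  fdr <- bh_adjust(p)
  cls <- ifelse(r > r_threshold & fdr < fdr_threshold, "positive",
                ifelse(r < -r_threshold & fdr < fdr_threshold, "negative",
                       "none"))
  structure(data.frame(mirna_id = pairs$mirna, gene_id = pairs$gene,
                       r = r, p = p, fdr = fdr, class = cls,
                       row.names = NULL, stringsAsFactors = FALSE),
            skipped = skipped)
}

#' Shuffled-label null for miRNA-mRNA pair correlations
#'
#' Per shuffle, the mRNA matrix's sample labels are permuted (breaking every
#' miRNA-mRNA pairing at once) and the pair-correlation analysis is re-run;
#' the fraction of pairs meeting the positive and negative class thresholds
#' is recorded.
#'
#' @inheritParams pair_correlations
#' @param n_shuffles Number of label shuffles (>= 1).
#' @param seed RNG seed.
#' @return List: `fractions` (data.frame shuffle, frac_positive,
#'   frac_negative), `mean_positive`, `sd_positive`, `mean_negative`,
#'   `sd_negative`.
#' @export
shuffled_null <- function(mirna_expr, mrna_expr, target_map, n_shuffles,
                          seed = NULL, r_threshold = 0.49,
                          fdr_threshold = 0.05) {
  if (n_shuffles < 1L) stopf("n_shuffles must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  shared <- intersect(colnames(mirna_expr), colnames(mrna_expr))
  fr <- t(vapply(seq_len(n_shuffles), function(i) {
    perm <- sample(shared)
    yp <- mrna_expr[, perm, drop = FALSE]
    colnames(yp) <- shared
    pc <- suppressWarnings(
      pair_correlations(mirna_expr, yp, target_map,
                        r_threshold = r_threshold,
                        fdr_threshold = fdr_threshold))
    c(frac_positive = mean(pc$class == "positive"),
      frac_negative = mean(pc$class == "negative"))
  }, c(frac_positive = 0, frac_negative = 0)))
  list(fractions = data.frame(shuffle = seq_len(n_shuffles), fr),
       mean_positive = mean(fr[, 1L]), sd_positive = sd(fr[, 1L]),
       mean_negative = mean(fr[, 2L]), sd_negative = sd(fr[, 2L]))
}
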