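#!/usr/bin/env Rscript
# Stage 7: do miRNA-target pairs covary across donors?
#
# Every target-map pair present in both matrices is tested (Pearson r
# across shared donors, BH-FDR over all pairs); pairs with |r| > 0.49 and
# FDR < 0.05 are classified positive/negative. A shuffled-label null
# (permuting the mRNA matrix's donor labels) calibrates the expected
# fraction of such pairs under independence.

suppressPackageStartupMessages(library(mirtemporal))

seed <- as.integer(Sys.getenv("ANALYSIS_SEED", "1"))
data_dir <- "results/data"
tab_dir <- "results/tables"
dir.create(tab_dir, showWarnings = FALSE, recursive = TRUE)

lcpm <- read_expression_matrix(file.path(data_dir, "profiles_log_cpm.tsv"),
                               kind = "log_cpm")
mrna <- read_expression_matrix(file.path(data_dir, "mrna_expression.tsv"),
                               kind = "continuous")
tm <- read_target_map(file.path(data_dir, "target_map.tsv"))
coupled <- read.delim(file.path(data_dir, "planted_coupled_pairs.tsv"))

pc <- pair_correlations(lcpm, mrna, tm)
pc <- pc[order(pc$fdr), ]
write.table(pc, file.path(tab_dir, "pair_correlations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
frac_neg <- mean(pc$class == "negative")
frac_pos <- mean(pc$class == "positive")
cat(sprintf("%d pairs tested: %.2f%% negative, %.2f%% positive\n",
            nrow(pc), 100 * frac_neg, 100 * frac_pos))
is_coupled <- paste(pc$mirna_id, pc$gene_id) %in%
  paste(coupled$mirna, coupled$gene)
cat(sprintf("planted coupled pairs called negative: %.1f%% (of %d)\n",
            100 * mean(pc$class[is_coupled] == "negative"),
            sum(is_coupled)))

null <- shuffled_null(lcpm, mrna, tm, n_shuffles = 20, seed = seed)
write.table(null$fractions, file.path(tab_dir, "pair_correlation_null.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("shuffled null: %.3f%% negative (sd %.3f), %.3f%% positive (sd %.3f)\n",
            100 * null$mean_negative, 100 * null$sd_negative,
            100 * null$mean_positive, 100 * null$sd_positive))
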