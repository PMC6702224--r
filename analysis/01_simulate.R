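#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort and write every downstream input.
#
# One lifespan control arm (109 donors, ~-0.4 to 73 years) plus an adult
# schizophrenia case arm (34 donors), 540 miRNAs in nine temporal groups,
# 2000 genes, and a synthetic target map. Planted truths -- two per-miRNA
# case effects, concordant shifts on groups 8 (up) and 6 (down), 20
# co-regulated genes for group 6, and 200 negatively coupled miRNA-mRNA
# pairs -- are saved so later stages can be read against ground truth.
# Feature counts are scaled down from transcriptome size for desk runtime;
# the cohort structure and all rate parameters are the package defaults.

suppressPackageStartupMessages(library(mirtemporal))

seed <- as.integer(Sys.getenv("ANALYSIS_SEED", "1"))
data_dir <- "results/data"
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)

base_args <- list(
  n_mirna = 540, n_mrna = 2000, seed = seed,
  planted_de = data.frame(mirna_id = c("miR-0137", "miR-0219"),
                          log2fc = c(1.2, -1.0)),
  group_shift = c("8" = 0.5, "6" = -0.5),
  cor_group = 6, n_cor_genes = 20)

# the target map fixes which pairs exist; couple the first 200 with slope -1
cfg0 <- do.call(cohort_config, base_args)
tm <- generate_target_map(cfg0)
pairs <- unique(tm[, c("mirna", "gene")])
coupled <- pairs[seq_len(min(200L, nrow(pairs))), ]
cfg <- do.call(cohort_config, c(base_args, list(
  coupling = data.frame(mirna_id = coupled$mirna, gene_id = coupled$gene,
                        slope = -1))))

cohort <- generate_cohort(cfg)
counts <- generate_mirna_counts(cohort, cfg)
mrna <- generate_mrna_matrix(cohort, cfg, mirna_counts = counts)

write_sample_table(cohort, file.path(data_dir, "cohort.tsv"))
write_expression_matrix(counts, file.path(data_dir, "mirna_counts.tsv"))
write_expression_matrix(mrna, file.path(data_dir, "mrna_expression.tsv"))
write_target_map(tm, file.path(data_dir, "target_map.tsv"))
groups <- mirna_groups(cfg)
write.table(data.frame(mirna_id = names(groups), group = unname(groups)),
            file.path(data_dir, "mirna_groups.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(attr(tm, "planted_cor_genes"),
           file.path(data_dir, "planted_cor_genes.txt"))
write.table(coupled, file.path(data_dir, "planted_coupled_pairs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("cohort: %d controls + %d cases; %d miRNAs, %d genes, %d target-map records\n",
            sum(cohort$diagnosis == "control"),
            sum(cohort$diagnosis == "case"), nrow(counts), nrow(mrna),
            nrow(tm)))
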