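#!/usr/bin/env Rscript
# Stage 5: are whole temporal groups shifted in cases?
#
# The differential-expression results are turned into a signed ranking
# (-log10 p * sign of log2FC), written as a .rnk file; the temporal groups
# with more than 50 members become gene sets in a GMT file. Preranked GSEA
# (running-sum ES, size-matched permutation null, NES, BH-FDR) then asks
# whether any group moves concordantly up or down in cases.

suppressPackageStartupMessages(library(mirtemporal))

seed <- as.integer(Sys.getenv("ANALYSIS_SEED", "1"))
data_dir <- "results/data"
tab_dir <- "results/tables"
dir.create(tab_dir, showWarnings = FALSE, recursive = TRUE)

de <- read.delim(file.path(tab_dir, "differential_expression.tsv"))
groups <- read.delim(file.path(data_dir, "mirna_groups.tsv"))

score <- -log10(de$p_value) * sign(de$log2_fold_change)
write_rank_file(de$feature_id, score,
                file.path(data_dir, "case_control.rnk"))
sets <- split(groups$mirna_id, paste0("group_", groups$group))
write_gmt(sets, file.path(data_dir, "temporal_groups.gmt"))

ranked <- read_rank_file(file.path(data_dir, "case_control.rnk"))
sets <- read_gmt(file.path(data_dir, "temporal_groups.gmt"))
res <- preranked_gsea(ranked, sets, n_perm = 1000, min_size = 51,
                      seed = seed)
res <- res[order(res$p), ]
write.table(res, file.path(tab_dir, "gsea_temporal_groups.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(res, row.names = FALSE)
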