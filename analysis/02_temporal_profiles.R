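#!/usr/bin/env Rscript
# Stage 2: temporal expression profiles of the control arm.
#
# Controls only (the lifespan axis must not be confounded with diagnosis):
# filter to miRNAs with >= 10 reads in every sample, CPM-normalize, log2,
# order donors by log2(post-conception days), smooth within a +/-0.3
# window on that scale, and z-score each miRNA. Stage-level significance
# calls (mean z, p < 0.05, >= 2 donors in stage) are written per
# (miRNA, developmental stage).

suppressPackageStartupMessages(library(mirtemporal))

data_dir <- "results/data"
tab_dir <- "results/tables"
dir.create(tab_dir, showWarnings = FALSE, recursive = TRUE)

cohort <- read_sample_table(file.path(data_dir, "cohort.tsv"))
counts <- read_expression_matrix(file.path(data_dir, "mirna_counts.tsv"),
                                 kind = "counts")
controls <- cohort[cohort$diagnosis == "control", ]
prof <- build_profiles(counts[, controls$sample_id], controls)
print(prof)

write_expression_matrix(prof$zscores,
                        file.path(data_dir, "profiles_zscores.tsv"))
write_expression_matrix(prof$log_cpm,
                        file.path(data_dir, "profiles_log_cpm.tsv"))

calls <- stage_significance(prof)
write.table(calls, file.path(tab_dir, "stage_significance.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
sig <- calls[calls$significant, ]
cat(sprintf("%d of %d profiled miRNAs significant in >= 1 stage; calls per stage:\n",
            length(unique(sig$feature_id)), length(prof$feature_ids)))
print(table(sig$stage))
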