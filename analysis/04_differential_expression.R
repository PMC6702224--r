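#!/usr/bin/env Rscript
# Stage 4: case/control differential expression and dose sensitivity.
#
# Cases are adults, so controls are restricted to the case age span before
# fitting the negative-binomial GLM (diagnosis tested last, adjusted for
# race, sex, age bin, and batch; BH-FDR across miRNAs). Antipsychotic
# exposure is probed by splitting the lifetime chlorpromazine-equivalent
# dose range into thirds among cases and contrasting the high bin against
# the low and medium bins.

suppressPackageStartupMessages(library(mirtemporal))

data_dir <- "results/data"
tab_dir <- "results/tables"
dir.create(tab_dir, showWarnings = FALSE, recursive = TRUE)

cohort <- read_sample_table(file.path(data_dir, "cohort.tsv"))
counts <- read_expression_matrix(file.path(data_dir, "mirna_counts.tsv"),
                                 kind = "counts")

case_ages <- range(cohort$age_years[cohort$diagnosis == "case"])
keep <- cohort$diagnosis == "case" |
  (cohort$age_years >= case_ages[1] & cohort$age_years <= case_ages[2])
sub <- cohort[keep, ]
cat(sprintf("GLM cohort: %d cases vs %d age-span-matched controls\n",
            sum(sub$diagnosis == "case"), sum(sub$diagnosis == "control")))

de <- nb_glm_test(counts[, sub$sample_id], sub)
de <- de[order(de$p_value), ]
write.table(de, file.path(tab_dir, "differential_expression.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("%d miRNAs at FDR < 0.05; top hits:\n", sum(de$fdr < 0.05)))
print(head(de, 5), row.names = FALSE)

cases <- sub[sub$diagnosis == "case", ]
dose <- dose_sensitivity(counts[, cases$sample_id], cases, "cpze_lifetime")
write.table(data.frame(sample_id = cases$sample_id, dose_bin = dose$bins),
            file.path(tab_dir, "dose_bins.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
for (ctr in c("high_vs_low", "high_vs_medium")) {
  if (is.null(dose[[ctr]])) next
  write.table(dose[[ctr]], file.path(tab_dir, paste0("dose_", ctr, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("dose %s: %d miRNAs at FDR < 0.05\n", ctr,
              sum(dose[[ctr]]$fdr < 0.05)))
}
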