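#!/usr/bin/env Rscript
# Stage 3: how many temporal groups, and do two distances agree?
#
# The gap statistic (ward.D2 on 1 - Pearson, PCA-rotated uniform reference,
# one-SE rule) selects the cluster number on the z-scored profiles. The
# profiles are then clustered both by correlation distance and by dynamic
# time warping, and the two partitions are compared with the weighted
# bipartite Index of Agreement plus a per-profile permutation null. The
# permutation arm runs on a 120-miRNA subsample: the null re-runs the DTW
# clustering once per permutation, which is quadratic in both profiles and
# donors.

suppressPackageStartupMessages(library(mirtemporal))

seed <- as.integer(Sys.getenv("ANALYSIS_SEED", "1"))
data_dir <- "results/data"
tab_dir <- "results/tables"
dir.create(tab_dir, showWarnings = FALSE, recursive = TRUE)

z <- read_expression_matrix(file.path(data_dir, "profiles_zscores.tsv"),
                            kind = "continuous")

gs <- gap_statistic(z, k_max = 12, B = 50, seed = seed)
write.table(gs$curve, file.path(tab_dir, "gap_curve.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
k <- gs$k_selected
cat(sprintf("gap statistic selects k = %d\n", k))

cl_cor <- hierarchical_clusters(correlation_distance(z), k)
cl_dtw <- hierarchical_clusters(dtw_distance(z), k)
write.table(data.frame(mirna_id = names(cl_cor),
                       cluster_correlation = unname(cl_cor),
                       cluster_dtw = unname(cl_dtw[names(cl_cor)])),
            file.path(tab_dir, "cluster_assignments.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

set.seed(seed)
sub <- sample(rownames(z), min(120L, nrow(z)))
conc <- ioa_permutation_test(z[sub, ], k_a = k, k_b = k, n_perm = 200,
                             seed = seed)
print(conc)
write.table(data.frame(index_of_agreement = conc$index_of_agreement,
                       n_crossing = conc$n_crossing,
                       n_noncrossing = conc$n_noncrossing,
                       p_value = conc$p_value, n_perm = conc$n_perm,
                       n_profiles = length(sub)),
            file.path(tab_dir, "concordance.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
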