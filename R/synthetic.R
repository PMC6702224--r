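#' Nine default temporal templates
#'
#' Smooth shapes of log2 relative expression over transformed
#' (post-conception, log2-days) age, paraphrasing the nine observed
#' temporal miRNA groups: (1) low in fetuses and preschoolers, (2) high in
#' fetuses, (3) low in toddlers, (4) low in fetuses and toddlers, (5) stably
#' high in fetuses and infants, (6) a wave peaking between preschool and
#' prepuberty, (7) a toddler peak, (8) an infant peak, (9) a late-toddler
#' peak. Landmarks on the transformed scale: birth ~8.13, 1 y ~9.33,
#' 3 y ~10.43, 6 y ~11.27, 12 y ~12.19.
#'
#' @param n Number of templates to return (first `n` of the nine; values
#'   above 9 recycle with shifted centers, for recovery experiments).
#' @return Named list of functions of transformed age, each bounded in
#'   \[-1, 1\].
#' @export
temporal_templates <- function(n = 9) {
  bump <- function(center, width) {
    force(center); force(width)
    function(t) exp(-0.5 * ((t - center) / width)^2)
  }
  step_down <- function(center, slope) {
    force(center); force(slope)
    function(t) plogis((center - t) / slope)
  }
  base <- list(
    fetal_preschool_low = function(t)
      -(bump(7.4, 0.55)(t) + bump(10.85, 0.40)(t)) / 1,
    fetal_high = step_down(8.13, 0.25),
    toddler_low = function(t) -bump(9.9, 0.45)(t),
    fetal_toddler_low = function(t)
      -(step_down(8.13, 0.25)(t) + bump(9.9, 0.45)(t)),
    fetal_infant_high = step_down(9.5, 0.45),
    preschool_prepuberty_wave = bump(11.4, 0.75),
    toddler_peak = bump(9.9, 0.38),
    infant_peak = bump(8.7, 0.38),
    late_toddler_peak = bump(10.5, 0.32)
  )
  # clamp every template into [-1, 1]
  base <- lapply(base, function(f) function(t) pmax(pmin(f(t), 1), -1))
  if (n <= 9L) return(base[seq_len(n)])
  extra <- lapply(seq_len(n - 9L), function(i) bump(6.9 + 0.6 * i, 0.30))
  names(extra) <- paste0("extra_bump_", seq_along(extra))
  c(base, extra)
}

#' Cohort / simulation configuration
#'
#' Defaults describe a postmortem DLPFC study design of the kind this
#' pipeline targets:
#' 109 controls spanning the second trimester (-0.44 y) to 73.3 y, 34
#' schizophrenia cases aged 18.6-71.9 y, 1074 expressed miRNAs in nine
#' temporal groups, negative-binomial counts with log-normal library sizes
#' around 1e7 mapped reads, two library-preparation batches, and an mRNA
#' panel optionally coupled to miRNAs.
#'
#' @param n_control,n_case Arm sizes.
#' @param age_range_years Control age range (years; negative = fetal).
#' @param case_age_range Case age range (adults).
#' @param n_mirna,n_mrna Feature counts.
#' @param templates List of temporal template functions; `n_groups` must
#'   equal its length.
#' @param n_groups Number of temporal groups.
#' @param amplitude Template amplitude in log2 units (peak effect on
#'   expression).
#' @param baseline_log2_mean,baseline_log2_sd Per-miRNA baseline abundance
#'   (log2 relative scale).
#' @param library_size_log_mean,library_size_log_sd Log-normal library-size
#'   parameters (natural log).
#' @param dispersion NB dispersion shared across miRNAs (> 0).
#' @param n_batches,batch_effect_sd Batch count and per-(batch, miRNA)
#'   log2-normal offset sd.
#' @param planted_de data.frame (mirna_id, log2fc) of per-miRNA case/control
#'   effects, or NULL.
#' @param group_shift Named numeric: temporal group -> concordant log2fc in
#'   cases (names are group indices), or NULL.
#' @param coupling data.frame (mirna_id, gene_id, slope) of miRNA->mRNA
#'   couplings, or NULL. Slopes act on the standardized miRNA log2 CPM with
#'   unit-sd Gaussian noise, so the expected Pearson r is
#'   slope / sqrt(slope^2 + mrna_noise_sd^2) (slope -1 gives r ~ -0.71).
#' @param mrna_noise_sd Residual sd of the mRNA values.
#' @param p_target Probability that a given (miRNA, gene) pair is a
#'   predicted target in the synthetic target map.
#' @param cor_group,n_cor_genes,cor_n_mirnas,cor_extra_sites Planted
#'   co-regulated genes: `n_cor_genes` genes receive `cor_extra_sites`
#'   binding sites from each of `cor_n_mirnas` distinct miRNAs of group
#'   `cor_group`.
#' @param seed Default RNG seed used by the generators.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 109, n_case = 34,
                          age_range_years = c(-0.44, 73.3),
                          case_age_range = c(18.6, 71.9),
                          n_mirna = 1074, n_mrna = 20000,
                          templates = temporal_templates(),
                          n_groups = length(templates),
                          amplitude = 2,
                          baseline_log2_mean = 5, baseline_log2_sd = 1.5,
                          library_size_log_mean = log(1e7),
                          library_size_log_sd = 0.35,
                          dispersion = 0.15,
                          n_batches = 2, batch_effect_sd = 0.15,
                          planted_de = NULL, group_shift = NULL,
                          coupling = NULL, mrna_noise_sd = 1,
                          p_target = 0.02,
                          cor_group = NULL, n_cor_genes = 0,
                          cor_n_mirnas = 4, cor_extra_sites = 4,
                          seed = 1L) {
  if (n_control <= 0L) stopf("n_control must be > 0")
  if (n_case < 0L) stopf("n_case must be >= 0")
  if (diff(range(age_range_years)) <= 0) stopf("empty age range")
  if (n_groups != length(templates))
    stopf("n_groups (%d) != number of templates (%d)", n_groups,
          length(templates))
  if (dispersion <= 0) stopf("dispersion must be > 0")
  cfg <- list(n_control = n_control, n_case = n_case,
              age_range_years = age_range_years,
              case_age_range = case_age_range,
              n_mirna = n_mirna, n_mrna = n_mrna,
              templates = templates, n_groups = n_groups,
              amplitude = amplitude,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              library_size_log_mean = library_size_log_mean,
              library_size_log_sd = library_size_log_sd,
              dispersion = dispersion,
              n_batches = n_batches, batch_effect_sd = batch_effect_sd,
              planted_de = planted_de, group_shift = group_shift,
              coupling = coupling, mrna_noise_sd = mrna_noise_sd,
              p_target = p_target,
              cor_group = cor_group, n_cor_genes = n_cor_genes,
              cor_n_mirnas = cor_n_mirnas,
              cor_extra_sites = cor_extra_sites,
              seed = as.integer(seed))
  ids <- mirna_ids(cfg)
  if (!is.null(planted_de) && !all(planted_de$mirna_id %in% ids))
    stopf("planted_de references unknown miRNA id(s)")
  if (n_cor_genes > n_mrna) stopf("planted CoR gene count > n_mrna")
  structure(cfg, class = "cohort_config")
}

#' Feature identifiers of a synthetic configuration
#'
#' @param config A `cohort_config`.
#' @return Character vector of miRNA / gene ids.
#' @export
mirna_ids <- function(config) sprintf("miR-%04d", seq_len(config$n_mirna))

#' @rdname mirna_ids
#' @export
gene_ids <- function(config) sprintf("GENE%05d", seq_len(config$n_mrna))

#' Temporal group of each synthetic miRNA
#'
#' miRNAs are assigned to the `n_groups` templates cyclically by index, so
#' group sizes differ by at most one.
#'
#' @param config A `cohort_config`.
#' @return Named integer vector miRNA id -> group.
#' @export
mirna_groups <- function(config) {
  setNames(rep_len(seq_len(config$n_groups), config$n_mirna),
           mirna_ids(config))
}

#' Generate a synthetic cohort table
#'
#' Control ages are stratified-uniform on the transformed log2(days + 280)
#' scale so every developmental stage is populated (one draw per
#' equal-width stratum); case ages cover the adult case range the same way.
#' Sex, race and batch are drawn categorically; chlorpromazine-equivalent
#' doses, antidepressant flags and cotinine are populated for cases only
#' (cotinine also for a smoking fraction of fetal controls).
#'
#' @param config A `cohort_config`.
#' @param seed Overrides `config$seed`.
#' @return Sample table data.frame (see [read_sample_table()]).
#' @export
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed %||% config$seed)
  t_ctrl <- stratified_uniform(transform_age(config$age_range_years[1L]),
                               transform_age(config$age_range_years[2L]),
                               config$n_control)
  age_ctrl <- (2^t_ctrl - 280) / 365.25
  n <- config$n_control + config$n_case
  age_case <- if (config$n_case > 0L) {
    t_case <- stratified_uniform(transform_age(config$case_age_range[1L]),
                                 transform_age(config$case_age_range[2L]),
                                 config$n_case)
    (2^t_case - 280) / 365.25
  } else numeric()
  df <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    age_years = c(age_ctrl, age_case),
    diagnosis = rep(c("control", "case"),
                    c(config$n_control, config$n_case)),
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.57, 0.43)),
    race = sample(c("AA", "CAUC"), n, replace = TRUE, prob = c(0.58, 0.42)),
    batch = sample(paste0("B", seq_len(config$n_batches)), n,
                   replace = TRUE),
    ph = round(runif(n, 5.9, 7.1), 2),
    pmi_hours = round(rlnorm(n, log(26), 0.55), 1),
    stringsAsFactors = FALSE)
  df$cpze_lifetime <- df$cpze_daily <- df$cpze_last <- NA_real_
  df$antidepressant <- NA
  df$cotinine <- NA_real_
  if (config$n_case > 0L) {
    case <- df$diagnosis == "case"
    df$cpze_lifetime[case] <- round(rlnorm(config$n_case, log(4e5), 0.9))
    df$cpze_daily[case] <- round(rlnorm(config$n_case, log(400), 0.7))
    df$cpze_last[case] <- round(rlnorm(config$n_case, log(300), 0.8))
    df$antidepressant[case] <- runif(config$n_case) < 0.5
    df$cotinine[case] <- ifelse(runif(config$n_case) < 0.6,
                                round(rlnorm(config$n_case, log(40), 1)), 0)
  }
  fetal <- df$age_years < 0
  if (any(fetal))
    df$cotinine[fetal] <- ifelse(runif(sum(fetal)) < 0.3,
                                 round(rlnorm(sum(fetal), log(30), 1)), 0)
  df
}

stratified_uniform <- function(lo, hi, n) {
  edges <- seq(lo, hi, length.out = n + 1L)
  runif(n, edges[-(n + 1L)], edges[-1L])
}

#' Generate a synthetic miRNA count matrix
#'
#' Counts for miRNA i in sample s are NB(mean = L_s * q_is, size =
#' 1/dispersion), where q_is is the sample-normalized relative abundance
#' 2^(baseline_i + amplitude * template_g(i)(t_s) + batch offset +
#' case effects) and L_s the log-normal library size. Planted per-miRNA
#' effects (`planted_de`) and concordant group shifts (`group_shift`) apply
#' to case samples only.
#'
#' @param cohort Sample table from [generate_cohort()].
#' @param config A `cohort_config`.
#' @param seed Overrides `config$seed`.
#' @return Integer count matrix (kind `"counts"`) with attributes `group`
#'   (miRNA -> temporal group) and `library_sizes`.
#' @export
generate_mirna_counts <- function(cohort, config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (nrow(cohort) != config$n_control + config$n_case)
    stopf("cohort/config mismatch: %d samples vs %d expected",
          nrow(cohort), config$n_control + config$n_case)
  set.seed(seed %||% config$seed)
  ids <- mirna_ids(config)
  groups <- mirna_groups(config)
  tage <- transform_age(cohort$age_years)
  baseline <- rnorm(config$n_mirna, config$baseline_log2_mean,
                    config$baseline_log2_sd)
  # template value per miRNA x sample
  shape <- matrix(0, config$n_mirna, nrow(cohort))
  for (g in seq_len(config$n_groups)) {
    rows <- which(groups == g)
    shape[rows, ] <- matrix(config$templates[[g]](tage),
                            length(rows), nrow(cohort), byrow = TRUE)
  }
  log2_rel <- baseline + config$amplitude * shape
  batches <- unique(cohort$batch)
  batch_off <- matrix(rnorm(config$n_mirna * length(batches),
                            0, config$batch_effect_sd),
                      config$n_mirna, length(batches))
  log2_rel <- log2_rel + batch_off[, match(cohort$batch, batches)]
  case <- cohort$diagnosis == "case"
  if (any(case)) {
    eff <- numeric(config$n_mirna)
    if (!is.null(config$group_shift)) {
      gs <- config$group_shift
      eff <- eff + ifelse(as.character(groups) %in% names(gs),
                          unlist(gs)[as.character(groups)], 0)
    }
    if (!is.null(config$planted_de)) {
      idx <- match(config$planted_de$mirna_id, ids)
      eff[idx] <- eff[idx] + config$planted_de$log2fc
    }
    log2_rel[, case] <- log2_rel[, case] + eff
  }
  rel <- 2^log2_rel
  q <- sweep(rel, 2L, colSums(rel), "/")
  lib <- rlnorm(nrow(cohort), config$library_size_log_mean,
                config$library_size_log_sd)
  mu <- sweep(q, 2L, lib, "*")
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
                   nrow(mu), ncol(mu),
                   dimnames = list(ids, cohort$sample_id))
  structure(counts, kind = "counts", group = groups,
            library_sizes = setNames(lib, cohort$sample_id))
}

#' Generate a synthetic mRNA expression matrix
#'
#' Continuous (array-like) values: each gene has a Gaussian baseline plus
#' unit-free noise of sd `mrna_noise_sd`; genes listed in
#' `config$coupling` additionally receive slope * standardized miRNA log2
#' CPM of their coupled miRNA, so the expected Pearson correlation of a
#' coupled pair is slope / sqrt(slope^2 + mrna_noise_sd^2). Uncoupled genes
#' are independent of all miRNAs.
#'
#' @param cohort Sample table.
#' @param config A `cohort_config`.
#' @param mirna_counts Optional miRNA count matrix (regenerated from the
#'   config seed when NULL and coupling is requested).
#' @param seed Overrides `config$seed` (offset internally so mRNA noise is
#'   independent of the count draw).
#' @return Numeric matrix genes x samples (kind `"continuous"`).
#' @export
generate_mrna_matrix <- function(cohort, config, mirna_counts = NULL,
                                 seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  genes <- gene_ids(config)
  coupling <- config$coupling
  if (!is.null(coupling)) {
    if (!all(coupling$gene_id %in% genes) ||
        !all(coupling$mirna_id %in% mirna_ids(config)))
      stopf("coupling references unknown miRNA/gene id(s)")
    if (is.null(mirna_counts))
      mirna_counts <- generate_mirna_counts(cohort, config, seed = seed)
  }
  set.seed((seed %||% config$seed) + 77003L)
  base <- rnorm(config$n_mrna, 8, 1.2)
  vals <- base + matrix(rnorm(config$n_mrna * nrow(cohort),
                              0, config$mrna_noise_sd),
                        config$n_mrna, nrow(cohort))
  dimnames(vals) <- list(genes, cohort$sample_id)
  if (!is.null(coupling)) {
    lcpm <- log2(cpm_normalize(mirna_counts) + 1)
    for (i in seq_len(nrow(coupling))) {
      z <- as.numeric(scale(lcpm[coupling$mirna_id[i], ]))
      vals[coupling$gene_id[i], ] <-
        vals[coupling$gene_id[i], ] + coupling$slope[i] * z
    }
  }
  structure(vals, kind = "continuous")
}

#' Generate a synthetic miRNA-target map
#'
#' A random bipartite site-count table: each (miRNA, gene) pair is a target
#' with probability `p_target`, carrying 1 + Poisson(0.4) sites on one or
#' two transcripts of the gene. When `config$cor_group` is set,
#' `n_cor_genes` designated genes additionally receive `cor_extra_sites`
#' sites from each of `cor_n_mirnas` distinct miRNAs of that temporal group
#' (planted co-regulated genes).
#'
#' @param config A `cohort_config`.
#' @param seed Overrides `config$seed`.
#' @return Target map data.frame with attribute `planted_cor_genes`.
#' @export
generate_target_map <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_mirna <= 0L || config$n_mrna <= 0L)
    stopf("n_mirna and n_mrna must be > 0")
  set.seed((seed %||% config$seed) + 140009L)
  ids <- mirna_ids(config)
  genes <- gene_ids(config)
  n_pair <- rbinom(1L, config$n_mirna * config$n_mrna, config$p_target)
  pick <- sample.int(config$n_mirna * config$n_mrna, n_pair)
  mir <- ids[(pick - 1L) %% config$n_mirna + 1L]
  gen <- genes[(pick - 1L) %/% config$n_mirna + 1L]
  tx_no <- sample(1:2, n_pair, replace = TRUE)
  tm <- data.frame(mirna = mir, gene = gen,
                   transcript = if (n_pair) paste0(gen, ".T", tx_no)
                                else character(),
                   n_sites = 1L + rpois(n_pair, 0.4),
                   stringsAsFactors = FALSE)
  planted <- character()
  if (!is.null(config$cor_group) && config$n_cor_genes > 0L) {
    groups <- mirna_groups(config)
    gm <- names(groups)[groups == config$cor_group]
    if (length(gm) < config$cor_n_mirnas)
      stopf("group %s has fewer than %d miRNAs", config$cor_group,
            config$cor_n_mirnas)
    use <- gm[seq_len(config$cor_n_mirnas)]
    planted <- genes[sample.int(config$n_mrna, config$n_cor_genes)]
    add <- expand.grid(mirna = use, gene = planted,
                       stringsAsFactors = FALSE)
    add$transcript <- paste0(add$gene, ".T1")
    add$n_sites <- config$cor_extra_sites
    tm <- rbind(tm, add)
  }
  # collapse duplicate (mirna, transcript) records by summing sites
  key <- paste(tm$mirna, tm$transcript, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- rowsum(tm$n_sites, key, reorder = FALSE)
    first <- !duplicated(key)
    tm <- tm[first, , drop = FALSE]
    tm$n_sites <- as.integer(agg[match(key[first], rownames(agg)), 1L])
  }
  if (nrow(tm) == 0L) stopf("degenerate configuration: empty target map")
  rownames(tm) <- NULL
  structure(validate_target_map(tm), planted_cor_genes = planted)
}
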