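#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, clipped at 1 and monotone in the rank order.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (no NaN/NA).
#' @export
bh_adjust <- function(p) {
  if (anyNA(p)) stopf("NaN/NA p-value passed to bh_adjust")
  if (any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Negative-binomial GLM differential expression
#'
#' Per-feature NB log-linear model with log library-size offset, moderated
#' dispersion (per-feature estimates shrunk toward a trended mean-dispersion
#' fit), and a likelihood-ratio test on the coefficient of interest, as
#' implemented by edgeR's glmFit/glmLRT machinery. Fold changes are reported
#' on the log2 scale, case minus control (positive = up in cases).
#'
#' @param counts Count matrix (features x samples), already filtered.
#' @param samples Sample table; must contain `test_var` and the requested
#'   covariates (an `age_bin` covariate is derived from `age_years` when
#'   absent).
#' @param test_var Variable tested (default `"diagnosis"`; may be a
#'   continuous covariate such as `cotinine`).
#' @param covariates Adjustment variables (default race, sex, age_bin,
#'   batch). Covariates constant across samples are dropped with a message.
#' @param prior_df Optional prior degrees of freedom for dispersion
#'   shrinkage (edgeR's default when NULL).
#' @return data.frame: feature_id, log2_fold_change, p_value, fdr.
#' @export
nb_glm_test <- function(counts, samples,
                        test_var = "diagnosis",
                        covariates = c("race", "sex", "age_bin", "batch"),
                        prior_df = NULL) {
  validate_kind(counts, "counts")
  stopifnot(identical(colnames(counts), samples$sample_id))
  dat <- samples
  if ("age_bin" %in% covariates && is.null(dat$age_bin))
    dat$age_bin <- age_bin(dat$age_years)
  if (identical(test_var, "diagnosis")) {
    dat$diagnosis <- factor(dat$diagnosis, levels = c("control", "case"))
    if (any(table(dat$diagnosis) < 2L))
      stopf("need >= 2 samples per diagnosis arm")
  }
  keep <- vapply(covariates, function(v) {
    ok <- length(unique(dat[[v]])) > 1L
    if (!ok) message("dropping constant covariate '", v, "'")
    ok
  }, logical(1L))
  covariates <- covariates[keep]
  form <- stats::reformulate(c(covariates, test_var))
  design <- model.matrix(form, data = dat)
  coef_idx <- grep(paste0("^", test_var), colnames(design))
  if (!length(coef_idx)) stopf("test variable '%s' absent from design",
                               test_var)
  fit <- nb_fit(counts, design, prior_df)
  lrt <- edgeR::glmLRT(fit, coef = coef_idx)
  tab <- lrt$table
  lfc <- if (length(coef_idx) == 1L) tab$logFC else NA_real_
  data.frame(feature_id = rownames(counts),
             log2_fold_change = lfc,
             p_value = tab$PValue,
             fdr = bh_adjust(tab$PValue),
             row.names = NULL, stringsAsFactors = FALSE)
}

nb_fit <- function(counts, design, prior_df = NULL) {
  y <- edgeR::DGEList(counts = counts)
  y <- if (is.null(prior_df)) edgeR::estimateDisp(y, design)
       else edgeR::estimateDisp(y, design, prior.df = prior_df)
  edgeR::glmFit(y, design)
}

#' Medication-dose sensitivity analysis
#'
#' Cases are divided into three groups by thirds of the dose RANGE (not
#' tertiles of subjects): low = bottom third of the range, medium = middle,
#' high = top. An NB GLM with the dose bin as a factor yields the
#' high-vs-low and high-vs-medium contrasts. Range-based bins can be empty,
#' in which case the affected contrast is skipped with a warning.
#'
#' @param counts Count matrix over the included cases.
#' @param samples Case-only sample table containing `dose_field`.
#' @param dose_field Column holding the dose (e.g. `"cpze_lifetime"`).
#' @param covariates Additional adjustment variables (default none).
#' @param n_bins Number of equal-width dose bins (default 3).
#' @return List with `bins` (per-sample factor) and one result data.frame
#'   per contrast (`high_vs_low`, `high_vs_medium`), each with feature_id,
#'   log2_fold_change, p_value, fdr.
#' @export
dose_sensitivity <- function(counts, samples, dose_field,
                             covariates = character(), n_bins = 3) {
  validate_kind(counts, "counts")
  stopifnot(identical(colnames(counts), samples$sample_id))
  dose <- samples[[dose_field]]
  if (is.null(dose) || anyNA(dose))
    stopf("dose field '%s' must be present for all included cases",
          dose_field)
  if (any(samples$diagnosis != "case"))
    stopf("dose sensitivity runs on cases only")
  breaks <- seq(min(dose), max(dose), length.out = n_bins + 1L)
  labels <- c("low", "medium", "high")[seq_len(n_bins)]
  bins <- cut(dose, breaks = breaks, labels = labels, include.lowest = TRUE)
  counts_bin <- table(factor(bins, levels = labels))
  out <- list(bins = setNames(bins, samples$sample_id))
  dat <- samples
  dat$dose_bin <- bins
  empty <- names(counts_bin)[counts_bin == 0L]
  for (contrast in list(c("high", "low"), c("high", "medium"))) {
    nm <- paste0(contrast[1L], "_vs_", contrast[2L])
    if (any(contrast %in% empty)) {
      warnf("empty dose bin (%s): contrast %s skipped",
            paste(intersect(contrast, empty), collapse = ", "), nm)
      out[[nm]] <- NULL
      next
    }
    sel <- bins %in% contrast
    dsub <- droplevels(dat[sel, , drop = FALSE])
    dsub$dose_bin <- factor(dsub$dose_bin, levels = rev(contrast))
    keep <- covariates[vapply(covariates, function(v)
      length(unique(dsub[[v]])) > 1L, logical(1L))]
    design <- model.matrix(stats::reformulate(c(keep, "dose_bin")),
                           data = dsub)
    fit <- nb_fit(counts[, sel, drop = FALSE], design)
    lrt <- edgeR::glmLRT(fit, coef = ncol(design))
    out[[nm]] <- data.frame(feature_id = rownames(counts),
                            log2_fold_change = lrt$table$logFC,
                            p_value = lrt$table$PValue,
                            fdr = bh_adjust(lrt$table$PValue),
                            row.names = NULL, stringsAsFactors = FALSE)
  }
  out
}
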