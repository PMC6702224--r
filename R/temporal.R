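#' Post-conception age transform
#'
#' Chronological age in years (negative = gestational) is converted to
#' log2(age in days + 280), i.e. roughly log2 days post conception. 280 days
#' is the length of a full-term pregnancy, so the transform stays defined for
#' second-trimester fetal samples.
#'
#' @param age_years Numeric vector of ages in years.
#' @param days_per_year Conversion factor, default 365.25.
#' @return log2(age_years * days_per_year + 280).
#' @export
transform_age <- function(age_years, days_per_year = 365.25) {
  days <- age_years * days_per_year + 280
  if (any(days <= 0))
    stopf("age %.3g years gives non-positive post-conception days",
          age_years[which(days <= 0)[1L]])
  log2(days)
}

#' Counts-per-million normalization
#'
#' @param counts Non-negative integer matrix (features x samples).
#' @return Matrix of the same shape, each column scaled to sum to 1e6, with
#'   `kind` attribute `"cpm"`.
#' @export
cpm_normalize <- function(counts) {
  validate_kind(counts, "counts")
  lib <- colSums(counts)
  if (any(lib == 0))
    stopf("zero library size in sample '%s'",
          colnames(counts)[which(lib == 0)[1L]] %||% which(lib == 0)[1L])
  structure(sweep(counts, 2L, lib, "/") * 1e6, kind = "cpm")
}

#' Expression filter: minimum reads in every sample
#'
#' A feature is called expressed only when it has at least `min_reads` mapped
#' reads in each and every sample.
#'
#' @param counts Count matrix.
#' @param min_reads Minimum count required in every sample (default 10).
#' @export
filter_expressed <- function(counts, min_reads = 10) {
  validate_kind(counts, "counts")
  keep <- apply(counts >= min_reads, 1L, all)
  if (!any(keep)) warnf("no features pass the >=%g-in-every-sample filter",
                        min_reads)
  structure(counts[keep, , drop = FALSE], kind = "counts")
}

#' Window smoothing over transformed age
#'
#' Each sample's value is replaced by the mean over all samples whose
#' transformed age lies within `window` (inclusive) of its own — the sample
#' itself included. `window = 0` with distinct ages is the identity.
#' The result does not depend on the input column order.
#'
#' @param x Numeric matrix features x samples.
#' @param transformed_ages Numeric vector aligned with columns of `x`.
#' @param window Half-width of the smoothing window on the transformed-age
#'   scale (default 0.3).
#' @export
smooth_profiles <- function(x, transformed_ages, window = 0.3) {
  stopifnot(is.matrix(x), length(transformed_ages) == ncol(x))
  if (window < 0) stopf("window must be >= 0")
  # membership matrix: W[t, s] = 1 if sample t is inside sample s's window
  W <- abs(outer(transformed_ages, transformed_ages, "-")) <= window
  out <- x %*% W
  out <- sweep(out, 2L, colSums(W), "/")
  dimnames(out) <- dimnames(x)
  out
}

#' Row-wise z-scores
#'
#' @param x Numeric matrix with >= 2 columns.
#' @return Matrix of per-feature z-scores (sample sd); zero-variance rows are
#'   set to all zeros and flagged in the logical `"degenerate"` attribute.
#' @export
zscore_profiles <- function(x) {
  stopifnot(is.matrix(x))
  if (ncol(x) < 2L) stopf("z-scoring needs >= 2 samples")
  mu <- rowMeans(x)
  s <- apply(x, 1L, sd)
  degen <- s == 0 | !is.finite(s)
  s[degen] <- 1
  z <- (x - mu) / s
  z[degen, ] <- 0
  structure(z, degenerate = setNames(degen, rownames(x)))
}

#' Developmental stage of an age
#'
#' Default boundaries: fetal < 0, infant 0-1, toddler 1-3, preschool 3-6,
#' prepuberty 6-12, adolescent 12-18, young adult 18-39, adult 40-60,
#' senior > 60 (adult bins as used for covariate adjustment). Interior
#' boundaries are right-open; exactly 60 years is "adult".
#'
#' @param age_years Numeric vector.
#' @param breaks Named numeric vector of right-open upper bounds for all
#'   stages but the last.
#' @return Factor of stage names.
#' @export
developmental_stage <- function(age_years,
                                breaks = c(fetal = 0, infant = 1, toddler = 3,
                                           preschool = 6, prepuberty = 12,
                                           adolescent = 18, young_adult = 40,
                                           adult = 60)) {
  labs <- c(names(breaks), "senior")
  idx <- findInterval(age_years, breaks, left.open = FALSE) + 1L
  # age exactly at the top interior boundary belongs to the lower stage
  idx[age_years == breaks[length(breaks)]] <- length(breaks)
  factor(labs[idx], levels = labs)
}

#' Adult age bin (young adult / adult / senior)
#'
#' @param age_years Numeric vector of adult ages (>= 18).
#' @export
age_bin <- function(age_years) {
  if (any(age_years < 18)) stopf("age_bin is defined for adults (>= 18 y)")
  factor(ifelse(age_years > 60, "senior",
                ifelse(age_years >= 40, "adult", "young_adult")),
         levels = c("young_adult", "adult", "senior"))
}

#' Build temporal profiles from counts and metadata
#'
#' The full profile pipeline: expression filter, CPM, log2(CPM + 1),
#' age-ordering of samples (transformed age, ties broken by sample id),
#' window smoothing, z-scoring.
#'
#' @param counts Count matrix (features x samples).
#' @param samples Sample table with `sample_id` and `age_years`.
#' @param min_reads Expression filter threshold (default 10).
#' @param window Smoothing half-width on the log2 age scale (default 0.3).
#' @param pseudocount Added to CPM before log2 (default 1).
#' @return An object of class `temporal_profiles`: list with `feature_ids`,
#'   `sample_ids` (age order), `transformed_ages`, `log_cpm`, `smoothed`,
#'   `zscores`, `degenerate`.
#' @export
build_profiles <- function(counts, samples, min_reads = 10, window = 0.3,
                           pseudocount = 1) {
  stopifnot(all(colnames(counts) %in% samples$sample_id))
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  kept <- filter_expressed(counts, min_reads)
  if (nrow(kept) == 0L) stopf("no expressed features")
  lcpm <- log2(cpm_normalize(kept) + pseudocount)
  tage <- transform_age(samples$age_years)
  o <- order(tage, samples$sample_id)
  lcpm <- lcpm[, o, drop = FALSE]
  tage <- tage[o]
  sm <- smooth_profiles(lcpm, tage, window)
  z <- zscore_profiles(sm)
  structure(list(feature_ids = rownames(kept),
                 sample_ids = samples$sample_id[o],
                 age_years = samples$age_years[o],
                 transformed_ages = tage,
                 log_cpm = lcpm, smoothed = sm, zscores = z,
                 degenerate = attr(z, "degenerate")),
            class = "temporal_profiles")
}

#' @export
print.temporal_profiles <- function(x, ...) {
  cat(sprintf("temporal_profiles: %d features x %d samples, age %.2f..%.2f y\n",
              length(x$feature_ids), length(x$sample_ids),
              min(x$age_years), max(x$age_years)))
  invisible(x)
}

#' Per-stage significance calls from z-score profiles
#'
#' For each feature and developmental stage, the mean z over the stage's
#' samples is converted to a two-sided normal p-value, p = 2(1 - Phi(|z|)).
#' A stage is called significant only when p < `alpha` and the stage holds at
#' least `min_samples` samples. With `scale_by_sqrt_n = TRUE` the mean z is
#' multiplied by sqrt(n) before conversion (a z-test on the stage mean);
#' the default treats the mean z itself as the test statistic.
#'
#' @param profiles A `temporal_profiles` object.
#' @param stages Optional factor/character of stage labels per sample (in
#'   profile order); defaults to `developmental_stage(profiles$age_years)`.
#' @param alpha Significance level (default 0.05).
#' @param min_samples Minimum samples a stage needs (default 2).
#' @param scale_by_sqrt_n Scale mean z by sqrt(n) before conversion.
#' @return data.frame: feature_id, stage, n_samples, mean_z, direction, p,
#'   significant.
#' @export
stage_significance <- function(profiles, stages = NULL, alpha = 0.05,
                               min_samples = 2, scale_by_sqrt_n = FALSE) {
  z <- profiles$zscores
  stages <- stages %||% developmental_stage(profiles$age_years)
  if (length(stages) != ncol(z)) stopf("one stage label per sample required")
  if (all(is.na(stages)) || length(stages) == 0L) stopf("empty stage map")
  stages <- factor(stages)
  lev <- levels(droplevels(stages))
  res <- lapply(lev, function(st) {
    idx <- which(stages == st)
    zbar <- rowMeans(z[, idx, drop = FALSE])
    stat <- if (scale_by_sqrt_n) zbar * sqrt(length(idx)) else zbar
    p <- 2 * pnorm(-abs(stat))
    data.frame(feature_id = rownames(z), stage = st,
               n_samples = length(idx), mean_z = zbar,
               direction = ifelse(zbar >= 0, "+", "-"), p = p,
               significant = p < alpha & length(idx) >= min_samples,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
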