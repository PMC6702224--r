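#' Read an expression matrix from TSV
#'
#' Reads a features-by-samples matrix in the tab-separated layout used
#' throughout the pipeline: first column holds feature identifiers, the header
#' row holds sample identifiers, all remaining cells are numeric. The `kind`
#' tag records the measurement scale and is validated: `"counts"` matrices
#' must be non-negative integers.
#'
#' @param path Path to a TSV file.
#' @param kind One of `"counts"`, `"cpm"`, `"log_cpm"`, `"continuous"`.
#' @return A numeric matrix with feature row names, sample column names and a
#'   `"kind"` attribute.
#' @export
read_expression_matrix <- function(path,
                                   kind = c("counts", "cpm", "log_cpm",
                                            "continuous")) {
  kind <- match.arg(kind)
  nf <- count.fields(path, sep = "\t", quote = "")
  if (length(nf) == 0L) stopf("no features: '%s' is empty", path)
  if (length(unique(nf)) != 1L)
    stopf("ragged rows in '%s' (field counts %s)", path,
          paste(unique(nf), collapse = ", "))
  df <- read.delim(path, check.names = FALSE, colClasses = "character",
                   quote = "")
  if (nrow(df) == 0L) stopf("no features in '%s'", path)
  feat <- df[[1L]]
  if (anyDuplicated(feat)) stopf("duplicate feature ids in '%s'", path)
  samp <- colnames(df)[-1L]
  if (anyDuplicated(samp)) stopf("duplicate sample ids in '%s'", path)
  vals <- suppressWarnings(vapply(df[-1L], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(feat, samp))
  if (anyNA(vals)) stopf("non-numeric cell(s) in '%s'", path)
  validate_kind(vals, kind)
  structure(vals, kind = kind)
}

validate_kind <- function(x, kind) {
  if (kind == "counts") {
    if (any(x < 0) || any(x != round(x)))
      stopf("kind 'counts' requires non-negative integers")
  }
  invisible(x)
}

#' Write an expression matrix to TSV
#'
#' Numbers are serialized with full (`%.17g`) precision so that
#' `read_expression_matrix()` recovers the matrix bit-exactly.
#'
#' @param x Numeric matrix with row and column names.
#' @param path Output path.
#' @param feature_col Header for the identifier column.
#' @export
write_expression_matrix <- function(x, path, feature_col = "feature_id") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  body <- apply(x, 2L, fmt_num)
  if (is.null(dim(body))) body <- matrix(body, nrow = nrow(x))
  lines <- c(paste(c(feature_col, colnames(x)), collapse = "\t"),
             paste(rownames(x), apply(body, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

fmt_num <- function(v) {
  out <- ifelse(is.finite(v) & v == round(v) & abs(v) < 2^53,
                sprintf("%.0f", v), sprintf("%.17g", v))
  out[is.na(v)] <- "NA"
  out
}

#' Read / write a sample metadata table
#'
#' One row per brain donor: `sample_id`, `age_years` (negative for fetal,
#' post-conception age must stay positive so `age_years > -0.75`),
#' `diagnosis` (`control`/`case`), `sex`, `race`, `batch`, `ph`, `pmi_hours`,
#' chlorpromazine-equivalent doses (`cpze_lifetime`, `cpze_daily`,
#' `cpze_last`), `antidepressant`, `cotinine`. Missing values are empty
#' fields.
#'
#' @param path TSV path.
#' @return A data.frame with one row per sample.
#' @export
read_sample_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, quote = "",
                   na.strings = c("NA", ""))
  need <- c("sample_id", "age_years", "diagnosis")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stopf("sample table missing column(s): %s", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample_ids")
  if (any(df$age_years <= -0.75))
    stopf("age_years <= -0.75: post-conception age must be positive")
  if (!all(df$diagnosis %in% c("control", "case")))
    stopf("diagnosis must be 'control' or 'case'")
  df
}

#' @rdname read_sample_table
#' @param samples Sample table data.frame.
#' @export
write_sample_table <- function(samples, path) {
  num <- vapply(samples, is.numeric, logical(1L))
  out <- samples
  out[num] <- lapply(out[num], fmt_num)
  out[] <- lapply(out, function(v) ifelse(is.na(v), "", as.character(v)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a miRNA-to-target site-count table
#'
#' TargetScan-style TSV with columns `mirna`, `gene`, `transcript`,
#' and a site-count column (default `n_sites`; some exports carry both total
#' and conserved site counts, so the column is selectable). Duplicate
#' (mirna, transcript) rows are summed with a warning.
#'
#' @param path TSV path.
#' @param site_col Name of the site-count column to use.
#' @return data.frame with columns mirna, gene, transcript, n_sites.
#' @export
read_target_map <- function(path, site_col = "n_sites") {
  df <- read.delim(path, check.names = FALSE, quote = "")
  need <- c("mirna", "gene", "transcript", site_col)
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stopf("target map missing column(s): %s", paste(miss, collapse = ", "))
  tm <- data.frame(mirna = as.character(df$mirna),
                   gene = as.character(df$gene),
                   transcript = as.character(df$transcript),
                   n_sites = as.integer(df[[site_col]]),
                   stringsAsFactors = FALSE)
  if (any(is.na(tm$n_sites)) || any(tm$n_sites < 1L))
    stopf("n_sites must be integers >= 1")
  key <- paste(tm$mirna, tm$transcript, sep = "\r")
  if (anyDuplicated(key)) {
    warnf("duplicate (mirna, transcript) rows: site counts summed")
    agg <- rowsum(tm$n_sites, key, reorder = FALSE)
    first <- !duplicated(key)
    tm <- tm[first, , drop = FALSE]
    tm$n_sites <- as.integer(agg[match(key[first], rownames(agg)), 1L])
  }
  validate_target_map(tm)
}

#' Validate a miRNA target map
#'
#' Checks the required columns (`mirna`, `gene`, `transcript`, `n_sites`),
#' positive site counts, and duplicate (mirna, transcript) records;
#' returns the map unchanged on success.
#'
#' @param tm Target map data.frame.
#' @export
validate_target_map <- function(tm) {
  stopifnot(is.data.frame(tm),
            all(c("mirna", "gene", "transcript", "n_sites") %in% colnames(tm)))
  if (nrow(tm) == 0L) stopf("empty target map")
  if (any(tm$n_sites < 1L)) stopf("n_sites must be >= 1")
  if (anyDuplicated(paste(tm$mirna, tm$transcript, sep = "\r")))
    stopf("duplicate (mirna, transcript) records")
  tm
}

#' @rdname read_target_map
#' @param tm Target map data.frame.
#' @export
write_target_map <- function(tm, path) {
  validate_target_map(tm)
  write.table(tm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' GMT lines are `name TAB description TAB member1 TAB member2 ...`.
#' Duplicate members within a set are dropped with a warning; empty sets are
#' rejected.
#'
#' @param path GMT path.
#' @return Named list of character vectors; the `"description"` attribute
#'   holds the per-set description strings.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("empty GMT file '%s'", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stopf("GMT set with 0 members at line %d", which(bad)[1L])
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm)) stopf("duplicate set names in '%s'", path)
  desc <- vapply(parts, `[[`, "", 2L)
  sets <- lapply(parts, function(p) p[-(1:2)])
  dup <- vapply(sets, anyDuplicated, 0L) > 0L
  if (any(dup)) {
    warnf("duplicate members in set(s) %s: deduplicated",
          paste(nm[dup], collapse = ", "))
    sets <- lapply(sets, unique)
  }
  names(sets) <- nm
  attr(sets, "description") <- setNames(desc, nm)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param description Optional named character vector of descriptions.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (any(lengths(sets) == 0L)) stopf("cannot write empty gene set")
  desc <- description %||% attr(sets, "description") %||%
    setNames(rep(".", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% ".", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a rank file (feature TAB score), descending by score
#'
#' Ties on the score are broken by feature id, ascending, so downstream
#' enrichment runs are deterministic.
#'
#' @param ids Character feature ids.
#' @param scores Numeric scores (no NaN/NA).
#' @param path Output path.
#' @export
write_rank_file <- function(ids, scores, path) {
  stopifnot(length(ids) == length(scores))
  if (anyDuplicated(ids)) stopf("duplicate feature ids in ranking")
  if (any(!is.finite(scores))) stopf("NaN/NA score in ranking")
  o <- order(-scores, ids)
  writeLines(paste(ids[o], fmt_num(scores[o]), sep = "\t"), path)
  invisible(path)
}

#' @rdname write_rank_file
#' @export
read_rank_file <- function(path) {
  df <- read.delim(path, header = FALSE, quote = "",
                   col.names = c("feature_id", "score"))
  df$feature_id <- as.character(df$feature_id)
  if (any(!is.finite(df$score))) stopf("NaN score in '%s'", path)
  df
}
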