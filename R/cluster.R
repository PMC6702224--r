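#' Correlation distance between temporal profiles
#'
#' d(i, j) = 1 - Pearson r between the two features' age-ordered values.
#' Zero-variance rows have no defined correlation and are dropped with a
#' warning.
#'
#' @param x Numeric matrix, features x samples (>= 3 samples), or a
#'   `temporal_profiles` object (its z-scores are used).
#' @return Symmetric distance matrix with `metric` attribute
#'   `"one_minus_pearson"`.
#' @export
correlation_distance <- function(x) {
  x <- as_profile_matrix(x)
  if (ncol(x) < 3L) stopf("correlation distance needs >= 3 samples")
  v <- apply(x, 1L, sd)
  if (any(v == 0)) {
    warnf("excluding %d zero-variance feature(s)", sum(v == 0))
    x <- x[v > 0, , drop = FALSE]
  }
  d <- 1 - cor(t(x))
  d[abs(d) < 1e-15] <- 0
  diag(d) <- 0
  structure(d, metric = "one_minus_pearson")
}

as_profile_matrix <- function(x) {
  if (inherits(x, "temporal_profiles")) x$zscores else {
    stopifnot(is.matrix(x)); x
  }
}

#' Dynamic-time-warping distance matrix
#'
#' Classic dynamic-programming alignment cost with |a - b| local cost over
#' the shared (age-ordered) sample grid. The default step pattern charges
#' each visited cell once, which equals the cheapest monotone lattice path
#' through the cost matrix; `"symmetric2"` weights diagonal steps twice.
#'
#' @param x Matrix or `temporal_profiles`.
#' @param step `"symmetric1"` (default) or `"symmetric2"`.
#' @param window Optional Sakoe-Chiba band half-width in samples
#'   (NULL = unconstrained).
#' @return Symmetric distance matrix with `metric` attribute `"dtw"`.
#' @export
dtw_distance <- function(x, step = c("symmetric1", "symmetric2"),
                         window = NULL) {
  x <- as_profile_matrix(x)
  step <- match.arg(step)
  if (ncol(x) < 2L) stopf("DTW needs series of length >= 2")
  w <- if (is.null(window)) -1L else as.integer(window)
  d <- .dtw_pairwise(x, if (step == "symmetric2") 2L else 1L, w)
  dimnames(d) <- list(rownames(x), rownames(x))
  structure(d, metric = "dtw")
}

#' Cut a hierarchical clustering of a distance matrix into k groups
#'
#' Agglomerative clustering with the Ward-2 criterion (`hclust` method
#' "ward.D2") on the provided distances. For non-Euclidean distances (1 - r,
#' DTW) this applies the Ward-2 Lance-Williams update to the raw distances,
#' the standard practice for correlation-based expression clustering.
#'
#' @param d Symmetric distance matrix (e.g. from [correlation_distance()]).
#' @param k Number of clusters, 1 <= k <= n.
#' @param linkage `hclust` agglomeration method (default "ward.D2").
#' @return Named integer vector of labels in 1..k with attributes `k`,
#'   `method` and `tree` (the hclust object).
#' @export
hierarchical_clusters <- function(d, k, linkage = "ward.D2") {
  n <- nrow(d)
  if (k < 1L || k > n) stopf("k must be in 1..%d", n)
  tree <- hclust(stats::as.dist(d), method = linkage)
  labels <- cutree(tree, k = k)
  structure(labels, k = k, method = attr(d, "metric") %||% "unknown",
            tree = tree)
}

#' Gap statistic for selecting the number of clusters
#'
#' Gap(k) = E*\[log W_k\] - log W_k, where W_k is the sum over clusters of
#' within-cluster pairwise distances divided by twice the cluster size, and
#' the reference expectation is over `B` null data sets clustered
#' identically. The default reference (`"scaled_pca"`) draws uniformly over
#' the per-component value ranges in the data's principal-component basis
#' and rotates back — the reference then shares the data's dominant
#' covariance directions, which matters for smoothed profiles whose
#' neighbouring samples are strongly correlated. `"original"` draws
#' uniformly over each sample's observed value range (the simplest
#' reference; too loose for smoothed profiles, kept for comparison). The
#' selected k is the smallest k with Gap(k) >= Gap(k+1) - s_{k+1} (one-SE
#' rule), where s_k = sd*(log W_k) * sqrt(1 + 1/B).
#'
#' @param x Matrix or `temporal_profiles`.
#' @param k_max Largest k to consider (>= 2).
#' @param B Number of reference draws (default 50).
#' @param seed RNG seed for the reference draws.
#' @param distance `"one_minus_pearson"` (default) or `"dtw"`.
#' @param reference Null reference space, `"scaled_pca"` (default) or
#'   `"original"`.
#' @param linkage hclust method.
#' @return List with `k_selected`, and a data.frame `curve` holding k,
#'   log_w, e_log_w, gap, se.
#' @export
gap_statistic <- function(x, k_max, B = 50, seed = NULL,
                          distance = c("one_minus_pearson", "dtw"),
                          reference = c("scaled_pca", "original"),
                          linkage = "ward.D2") {
  x <- as_profile_matrix(x)
  distance <- match.arg(distance)
  reference <- match.arg(reference)
  if (k_max < 2L) stopf("k_max must be >= 2")
  if (B < 10L) stopf("B must be >= 10")
  if (all(apply(x, 2L, function(col) length(unique(col))) == 1L) ||
      nrow(unique(x)) == 1L)
    stopf("degenerate data: all rows identical")
  if (!is.null(seed)) set.seed(seed)
  distfun <- switch(distance,
                    one_minus_pearson = correlation_distance,
                    dtw = dtw_distance)
  log_w <- log_wk_curve(x, k_max, distfun, linkage)
  if (reference == "scaled_pca") {
    ctr <- colMeans(x)
    xc <- sweep(x, 2L, ctr)
    V <- svd(xc, nu = 0)$v
    xr <- xc %*% V
  } else {
    xr <- x
    V <- NULL
  }
  lo <- apply(xr, 2L, min)
  hi <- apply(xr, 2L, max)
  ref <- matrix(0, B, k_max)
  for (b in seq_len(B)) {
    xb <- sapply(seq_len(ncol(xr)),
                 function(j) runif(nrow(x), lo[j], hi[j]))
    if (!is.null(V)) xb <- xb %*% t(V)
    rownames(xb) <- rownames(x)
    ref[b, ] <- log_wk_curve(xb, k_max, distfun, linkage)
  }
  e_log_w <- colMeans(ref)
  se <- apply(ref, 2L, sd) * sqrt(1 + 1 / B)
  gap <- e_log_w - log_w
  k_sel <- k_max
  for (k in seq_len(k_max - 1L)) {
    if (gap[k] >= gap[k + 1L] - se[k + 1L]) { k_sel <- k; break }
  }
  list(k_selected = k_sel,
       curve = data.frame(k = seq_len(k_max), log_w = log_w,
                          e_log_w = e_log_w, gap = gap, se = se))
}

log_wk_curve <- function(x, k_max, distfun, linkage) {
  d <- suppressWarnings(distfun(x))
  tree <- hclust(stats::as.dist(d), method = linkage)
  vapply(seq_len(k_max), function(k) {
    lab <- cutree(tree, k = k)
    w <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      if (length(idx) > 1L)
        w <- w + sum(d[idx, idx]) / (2 * length(idx))
    }
    log(max(w, .Machine$double.xmin))
  }, 0)
}

#' Weighted-bipartite comparison of two clusterings
#'
#' Clusters of `a` and `b` become the two node layers; edge weights count the
#' shared features. Layer orders are chosen by an iterated barycenter
#' heuristic that minimizes edge crossings. Two edges (i, j), (k, l) cross
#' iff (pos(i) - pos(k)) * (pos(j) - pos(l)) < 0; an edge is "crossing" when
#' it participates in at least one crossing pair. The Index of Agreement is
#' the ratio of non-crossing to crossing edges, with the denominator clamped
#' to 1 so perfect agreement stays finite (IoA = k for identical
#' k-clusterings).
#'
#' @param a,b Integer cluster label vectors named by feature (same feature
#'   universe).
#' @return List of class `concordance`: `edges` (data.frame left, right,
#'   weight), `order_left`, `order_right`, `n_noncrossing`, `n_crossing`,
#'   `index_of_agreement`.
#' @export
bipartite_concordance <- function(a, b) {
  if (is.null(names(a)) || is.null(names(b)))
    stopf("cluster assignments must be named by feature")
  shared <- intersect(names(a), names(b))
  if (!length(shared)) stopf("disjoint feature sets")
  a <- a[shared]; b <- b[shared]
  tab <- table(a, b)
  ed <- which(tab > 0, arr.ind = TRUE)
  edges <- data.frame(left = as.integer(rownames(tab))[ed[, 1L]],
                      right = as.integer(colnames(tab))[ed[, 2L]],
                      weight = tab[ed])
  ord <- barycenter_orders(edges, sort(unique(edges$left)),
                           sort(unique(edges$right)))
  pl <- ord$left_pos[match(edges$left, ord$left)]
  pr <- ord$right_pos[match(edges$right, ord$right)]
  ne <- nrow(edges)
  crossing <- logical(ne)
  if (ne > 1L) {
    for (i in seq_len(ne - 1L)) for (j in (i + 1L):ne) {
      if ((pl[i] - pl[j]) * (pr[i] - pr[j]) < 0) {
        crossing[i] <- TRUE; crossing[j] <- TRUE
      }
    }
  }
  n_cross <- sum(crossing)
  n_non <- ne - n_cross
  structure(list(edges = edges,
                 order_left = ord$left[order(ord$left_pos)],
                 order_right = ord$right[order(ord$right_pos)],
                 n_noncrossing = n_non, n_crossing = n_cross,
                 index_of_agreement = n_non / max(n_cross, 1L)),
            class = "concordance")
}

barycenter_orders <- function(edges, left, right, n_iter = 8L) {
  lp <- setNames(seq_along(left), left)
  rp <- setNames(seq_along(right), right)
  for (it in seq_len(n_iter)) {
    bc_r <- vapply(right, function(r) {
      e <- edges[edges$right == r, ]
      sum(e$weight * lp[as.character(e$left)]) / sum(e$weight)
    }, 0)
    rp <- setNames(rank(bc_r, ties.method = "first"), right)
    bc_l <- vapply(left, function(l) {
      e <- edges[edges$left == l, ]
      sum(e$weight * rp[as.character(e$right)]) / sum(e$weight)
    }, 0)
    lp <- setNames(rank(bc_l, ties.method = "first"), left)
  }
  list(left = left, left_pos = unname(lp),
       right = right, right_pos = unname(rp))
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf(paste0("concordance: %d edges, %d non-crossing / %d crossing, ",
                     "IoA = %.3g"),
              nrow(x$edges), x$n_noncrossing, x$n_crossing,
              x$index_of_agreement))
  if (!is.null(x$p_value)) cat(sprintf(", permutation p = %.4g", x$p_value))
  cat("\n")
  invisible(x)
}

#' Permutation test of clustering concordance (Index of Agreement)
#'
#' The observed IoA compares the method-a clustering (fixed) with the
#' method-b clustering of the same profiles. The null reorders each
#' feature's values independently across the age-ordered samples, re-runs
#' method-b clustering on the permuted data, and recomputes the IoA against
#' the fixed method-a clustering; p = (1 + #\{null >= observed\}) /
#' (n_perm + 1).
#'
#' @param x Matrix or `temporal_profiles`.
#' @param k_a,k_b Cluster numbers for the two methods (fixed across
#'   permutations).
#' @param n_perm Number of permutations (>= 100; the full-scale analysis
#'   uses 5000).
#' @param seed RNG seed.
#' @param method_a,method_b Distance metrics for the two clusterings.
#' @return `concordance` object with extra fields `p_value`, `null_ioa`,
#'   `n_perm`.
#' @export
ioa_permutation_test <- function(x, k_a, k_b, n_perm = 5000, seed = NULL,
                                 method_a = "one_minus_pearson",
                                 method_b = "dtw") {
  x <- as_profile_matrix(x)
  if (n_perm < 100L) stopf("n_perm must be >= 100 for usable p resolution")
  if (!is.null(seed)) set.seed(seed)
  distfun_a <- if (method_a == "dtw") dtw_distance else correlation_distance
  distfun_b <- if (method_b == "dtw") dtw_distance else correlation_distance
  ca <- hierarchical_clusters(distfun_a(x), k_a)
  cb <- hierarchical_clusters(distfun_b(x), k_b)
  obs <- bipartite_concordance(ca, cb)
  m <- ncol(x)
  null_ioa <- vapply(seq_len(n_perm), function(i) {
    xp <- t(apply(x, 1L, function(row) row[sample.int(m)]))
    rownames(xp) <- rownames(x)
    cbp <- hierarchical_clusters(distfun_b(xp), k_b)
    bipartite_concordance(ca, cbp)$index_of_agreement
  }, 0)
  obs$p_value <- (1 + sum(null_ioa >= obs$index_of_agreement)) / (n_perm + 1)
  obs$null_ioa <- null_ioa
  obs$n_perm <- n_perm
  obs$assignment_a <- ca
  obs$assignment_b <- cb
  obs
}
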