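# Small simulation configs shared across tests. Feature counts are scaled
# down from the full cohort so the suite stays fast; the cohort structure
# (age span, arms, nine templates) is the default one.

small_config <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(n_control = 60, n_case = 0, n_mirna = 72, n_mrna = 60,
                   seed = seed)
  do.call(cohort_config, utils::modifyList(defaults, args))
}

small_profiles <- function(seed = 1L, ...) {
  cfg <- small_config(seed = seed, ...)
  coh <- generate_cohort(cfg)
  cnt <- generate_mirna_counts(coh, cfg)
  list(config = cfg, cohort = coh, counts = cnt,
       profiles = build_profiles(cnt, coh))
}

# exhaustive-path DTW oracle: cheapest monotone lattice path through the
# |a - b| cost matrix, each visited cell's cost counted once
dtw_oracle <- function(x, y) {
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + abs(x[i] - y[j])
    if (acc >= best) return(invisible())
    if (i == length(x) && j == length(y)) {
      best <<- acc
      return(invisible())
    }
    if (i < length(x) && j < length(y)) walk(i + 1, j + 1, acc)
    if (i < length(x)) walk(i + 1, j, acc)
    if (j < length(y)) walk(i, j + 1, acc)
    invisible()
  }
  walk(1L, 1L, 0)
  best
}

# O(m^2) step-up FDR oracle
bh_oracle <- function(p) {
  m <- length(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- sum(p <= p[i])
    adj[i] <- min(1, min(vapply(seq_len(m), function(j) {
      rank_j <- sum(p <= p[j])
      if (p[j] >= p[i]) p[j] * m / rank_j else Inf
    }, 0)))
  }
  adj
}
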