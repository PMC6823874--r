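# Independent oracles and small fixtures used across tests.

# Permutation-null overlap sampler: draws the s2 "category" samples one at a
# time from the shuffled cohort of st samples of which s1 are mutated, and
# counts how many drawn samples are mutated. Exactly the label-permutation
# null, vectorized over B draws.
perm_overlap <- function(st, s1, s2, B) {
  rem_succ <- rep(s1, B)
  overlap <- integer(B)
  for (j in seq_len(s2)) {
    take <- stats::runif(B) < rem_succ / (st - j + 1)
    rem_succ <- rem_succ - take
    overlap <- overlap + take
  }
  overlap
}

# Direct double-precision summation of the co-occurrence tail from binomial
# coefficients -- the printed formula evaluated term by term, no log-space.
direct_tail_sum <- function(st, s1, s2, s12) {
  i <- seq.int(s12, min(s1, s2))
  sum(choose(s1, i) * choose(st - s1, s2 - i)) / choose(st, s2)
}

# Random valid contingency counts with s_total <= st_max
random_counts <- function(st_max = 50) {
  st <- sample(5:st_max, 1)
  s1 <- sample.int(st, 1)
  s2 <- sample.int(st, 1)
  lo <- max(0, s1 + s2 - st)
  hi <- min(s1, s2)
  s12 <- if (lo == hi) lo else sample(seq(lo, hi), 1)
  contingency_counts(st, s1, s2, s12)
}

# Adjusted Rand Index between two labelings (independent of any package)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# Minimal clinical table builder
make_clinical <- function(times, events, ids = sprintf("s%03d", seq_along(times))) {
  data.frame(sample = ids, dfs_months = times, dfs_event = as.integer(events),
             stringsAsFactors = FALSE)
}

# Exemplar-scale configuration for validation-cascade and network properties:
# a handful of planted pairs with a survival effect strong enough that each
# pair's KM filter has >99% power in the mutated stratum.
validation_config <- function(seed) {
  sim_config(seed = seed, samples_per_type = 200, n_sl_pairs = 3,
             sl_survival_hr = 6, base_hazard = 0.04)
}
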