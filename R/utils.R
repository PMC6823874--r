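# internal numerics shared across modules

# log(sum(exp(x))) without overflow; -Inf terms drop out
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Mann-Whitney AUROC of `score` for binary `label` (TRUE = positive).
# Ties handled by midranks.
auroc <- function(score, label) {
  label <- as.logical(label)
  stopifnot(length(score) == length(label), !anyNA(score), !anyNA(label))
  n_pos <- sum(label)
  n_neg <- sum(!label)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUROC needs both positive and negative labels")
  }
  r <- rank(score, ties.method = "average")
  (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
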