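#' Single-sample gene set enrichment score (ssGSEA) for one sample
#'
#' Rank-based weighted ECDF-difference statistic. Genes are ranked by
#' decreasing expression; with absolute ranks \eqn{r_i = N - position + 1}
#' (so the top gene carries rank N) the score walks the ranking accumulating
#' \deqn{ECDF_{in}(j) = \sum_{i \le j, i \in S} r_i^\alpha /
#'       \sum_{i \in S} r_i^\alpha, \quad
#'       ECDF_{out}(j) = |\{i \le j, i \notin S\}| / (N - |S|)}
#' and returns \eqn{\sum_j (ECDF_{in}(j) - ECDF_{out}(j))}. The score depends
#' on expression only through ranks, so any strictly increasing per-sample
#' transform leaves it unchanged. Ties get average rank weights and are
#' walked in lexicographic gene-name order, making the result independent of
#' input gene order.
#'
#' @param expr Named numeric expression vector for one sample (>= 2 genes,
#'   no NA).
#' @param geneset Character vector of member genes.
#' @param alpha Rank-weighting exponent (default 0.25).
#' @return Numeric enrichment score.
#' @export
ssgsea_sample <- function(expr, geneset, alpha = 0.25) {
  if (is.null(names(expr)) || length(expr) < 2L) {
    stop("expr must be a named vector with >= 2 genes")
  }
  if (anyNA(expr)) stop("expr contains NA")
  n <- length(expr)
  in_universe <- names(expr) %in% geneset
  m <- sum(in_universe)
  if (m == 0L) stop("geneset does not intersect the expression universe")
  if (m == n) stop("geneset equals the expression universe; ECDF_out undefined")
  w <- rank(expr, ties.method = "average")  # top gene gets weight N
  ord <- order(-expr, names(expr))
  in_set <- in_universe[ord]
  wts <- ifelse(in_set, w[ord]^alpha, 0)
  ecdf_in <- cumsum(wts) / sum(wts)
  ecdf_out <- cumsum(!in_set) / (n - m)
  sum(ecdf_in - ecdf_out)
}

#' ssGSEA scores for a geneset collection over an expression matrix
#'
#' Applies \code{\link{ssgsea_sample}} per (geneset, sample). With
#' \code{normalize = TRUE} (the conventional behavior) all scores are divided
#' by the global score range (max - min over the whole matrix).
#'
#' @param expr Gene x sample numeric matrix with dimnames.
#' @param genesets Named list of character vectors.
#' @param alpha Rank-weighting exponent.
#' @param normalize Divide by the global score range.
#' @return Pathway x sample matrix with attributes \code{alpha} and
#'   \code{normalized}.
#' @export
ssgsea_matrix <- function(expr, genesets, alpha = 0.25, normalize = TRUE) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  scores <- matrix(NA_real_, nrow = length(genesets), ncol = ncol(expr),
                   dimnames = list(names(genesets), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    ex <- expr[, j]
    names(ex) <- rownames(expr)
    for (s in seq_along(genesets)) {
      scores[s, j] <- tryCatch(
        ssgsea_sample(ex, genesets[[s]], alpha),
        error = function(e) stop(sprintf(
          "ssGSEA failed for pathway '%s', sample '%s': %s",
          names(genesets)[[s]], colnames(expr)[[j]], conditionMessage(e)))
      )
    }
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  attr(scores, "alpha") <- alpha
  attr(scores, "normalized") <- normalize
  scores
}
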