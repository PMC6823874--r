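#' Contingency counts for co-occurrence tests
#'
#' The four counts behind the hypergeometric co-occurrence test: total samples
#' \code{s_total}, samples mutated in gene 1 \code{s1_mut}, samples in the
#' second category \code{s2} (a DDR cluster, or samples mutated in gene 2 for
#' the pairwise test), and the overlap \code{s12_mut}.
#'
#' @param s_total Total number of samples.
#' @param s1_mut Samples with a mutation in gene 1.
#' @param s2 Samples in the second category (cluster membership or gene-2
#'   mutation).
#' @param s12_mut Samples in both categories.
#' @return Object of class \code{contingency_counts}.
#' @export
contingency_counts <- function(s_total, s1_mut, s2, s12_mut) {
  vals <- c(s_total = s_total, s1_mut = s1_mut, s2 = s2, s12_mut = s12_mut)
  if (any(vals != round(vals)) || any(vals < 0)) {
    stop("contingency counts must be non-negative integers")
  }
  if (s_total == 0) stop("s_total must be positive")
  if (s1_mut > s_total || s2 > s_total) {
    stop("marginal counts cannot exceed s_total")
  }
  if (s12_mut > min(s1_mut, s2)) {
    stop("overlap s12_mut cannot exceed min(s1_mut, s2)")
  }
  if (s12_mut < max(0, s1_mut + s2 - s_total)) {
    stop("overlap s12_mut below the feasible minimum for these margins")
  }
  structure(as.list(vals), class = "contingency_counts")
}

#' Hypergeometric co-occurrence p-value
#'
#' Upper-tail hypergeometric probability of observing at least the given
#' overlap between two sample categories:
#' \deqn{P = \sum_{i=s_{12}}^{\min(s_1, s_2)}
#'   \binom{s_1}{i} \binom{s_T - s_1}{s_2 - i} / \binom{s_T}{s_2}.}
#' Small P means the two categories overlap more than chance, i.e. the gene
#' mutation co-occurs with the cluster (or with the second gene's mutation).
#' Terms are accumulated in log-space via \code{lchoose} and log-sum-exp, so
#' large cohorts do not overflow. The statistic is symmetric in the two
#' categories.
#'
#' @param counts A \code{contingency_counts} object.
#' @return Co-occurrence p-value in (0, 1].
#' @export
hypergeom_cooccurrence <- function(counts) {
  stopifnot(inherits(counts, "contingency_counts"))
  s_t <- counts$s_total
  s1 <- counts$s1_mut
  s2 <- counts$s2
  s12 <- counts$s12_mut
  i <- seq.int(s12, min(s1, s2))
  log_terms <- lchoose(s1, i) + lchoose(s_t - s1, s2 - i) - lchoose(s_t, s2)
  p <- exp(logsumexp(log_terms))
  min(p, 1)
}

#' Mutation mutual exclusivity
#'
#' The mutual-exclusivity p-value is the complement of the co-occurrence
#' tail: \code{mutex_p = 1 - p_cooccur}. Under the null the two genes are
#' mutated in the same samples; \code{mutex_p} below \code{alpha} rejects it,
#' i.e. the genes are mutated in disjoint sample sets more than chance.
#'
#' @param counts A \code{contingency_counts} with gene-2 mutation counts in
#'   the \code{s2} slot.
#' @param alpha Significance level for the direction tag (default 0.05).
#' @return List with \code{p_cooccur}, \code{mutex_p} (= 1 - p_cooccur) and a
#'   \code{direction} tag in \{"exclusive", "cooccurring", "neither"\}.
#' @export
mutual_exclusivity <- function(counts, alpha = 0.05) {
  p_co <- hypergeom_cooccurrence(counts)
  mutex_p <- 1 - p_co
  direction <- if (mutex_p < alpha) {
    "exclusive"
  } else if (p_co < alpha) {
    "cooccurring"
  } else {
    "neither"
  }
  list(p_cooccur = p_co, mutex_p = mutex_p, direction = direction)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Standard step-up adjustment with enforced monotonicity, capped at 1; the
#' output order matches the input order.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))
  adj[order(o)]
}

#' Filter genes by per-cancer mutation recurrence
#'
#' Keeps a gene iff its mutation fraction reaches \code{min_fraction} in at
#' least \code{min_cancers} cancer types (the study's "at least 1\% of samples
#' in two or more cancers" filter).
#'
#' @param mutation Binary sample x gene matrix.
#' @param cancer_type Named cancer-type label per sample.
#' @param min_fraction Minimum per-cancer mutated fraction (in (0, 1]).
#' @param min_cancers Minimum number of cancer types meeting the fraction.
#' @return Character vector of retained gene names.
#' @export
recurrent_gene_filter <- function(mutation, cancer_type,
                                  min_fraction = 0.01, min_cancers = 2) {
  if (min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must lie in (0, 1]")
  }
  if (!all(rownames(mutation) %in% names(cancer_type))) {
    stop("every sample must carry a cancer-type label")
  }
  labels <- cancer_type[rownames(mutation)]
  frac <- rowsum(mutation, labels) / as.vector(table(labels)[sort(unique(labels))])
  keep <- colSums(frac >= min_fraction) >= min_cancers
  colnames(mutation)[keep]
}

#' Cluster-gene mutation co-occurrence scan
#'
#' Tests every (gene, cluster) combination for co-occurrence of the gene's
#' non-silent mutations with cluster membership, with BH adjustment across
#' the whole scan as one family.
#'
#' @param mutation Binary sample x gene matrix.
#' @param clusters Named integer cluster label per sample (or a
#'   \code{cluster_assignment}).
#' @param fdr_threshold FDR cutoff for the \code{kept} flag (default 0.3).
#' @return Data frame with columns gene, cluster, s1_mut, s2, s12_mut,
#'   p_cooccur, fdr, kept.
#' @export
cluster_gene_cooccurrence <- function(mutation, clusters, fdr_threshold = 0.3) {
  if (inherits(clusters, "cluster_assignment")) clusters <- clusters$labels
  if (!all(rownames(mutation) %in% names(clusters))) {
    stop("cluster assignment must cover every sample")
  }
  labels <- clusters[rownames(mutation)]
  ks <- sort(unique(labels))
  genes <- colnames(mutation)
  if (length(genes) == 0L) {
    return(data.frame(gene = character(0), cluster = integer(0),
                      s1_mut = integer(0), s2 = integer(0),
                      s12_mut = integer(0), p_cooccur = numeric(0),
                      fdr = numeric(0), kept = logical(0)))
  }
  s_t <- nrow(mutation)
  rows <- expand.grid(gene = genes, cluster = ks,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gene_tot <- colSums(mutation)
  clust_tot <- table(labels)
  overlap <- rowsum(mutation, labels)  # cluster x gene mutated counts
  rows$s1_mut <- gene_tot[rows$gene]
  rows$s2 <- as.integer(clust_tot[as.character(rows$cluster)])
  rows$s12_mut <- overlap[cbind(as.character(rows$cluster), rows$gene)]
  rows$p_cooccur <- vapply(seq_len(nrow(rows)), function(i) {
    hypergeom_cooccurrence(contingency_counts(
      s_t, rows$s1_mut[[i]], rows$s2[[i]], rows$s12_mut[[i]]))
  }, numeric(1))
  rows$fdr <- bh_fdr(rows$p_cooccur)
  rows$kept <- rows$fdr < fdr_threshold
  rownames(rows) <- NULL
  rows
}

#' Pairwise mutation mutual exclusivity across gene pairs
#'
#' Computes the mutual-exclusivity statistic for each (gene1, gene2) pair,
#' either within each cancer type (default, matching per-cancer analysis) or
#' pooled across the cohort. BH adjustment is applied per cancer-type family.
#'
#' @param mutation Binary sample x gene matrix.
#' @param pairs Data frame with columns \code{gene1}, \code{gene2}.
#' @param cancer_type Optional named label per sample; \code{NULL} pools.
#' @param alpha Direction-tag significance level.
#' @return Data frame with per-pair (and per-cancer) counts, p_cooccur,
#'   mutex_p, fdr (BH on p_cooccur within family) and direction.
#' @export
pairwise_mutex <- function(mutation, pairs, cancer_type = NULL, alpha = 0.05) {
  strata <- if (is.null(cancer_type)) {
    list(pooled = rownames(mutation))
  } else {
    split(rownames(mutation), cancer_type[rownames(mutation)])
  }
  out <- lapply(names(strata), function(ct) {
    sel <- mutation[strata[[ct]], , drop = FALSE]
    res <- lapply(seq_len(nrow(pairs)), function(i) {
      g1 <- pairs$gene1[[i]]
      g2 <- pairs$gene2[[i]]
      counts <- contingency_counts(
        nrow(sel), sum(sel[, g1]), sum(sel[, g2]),
        sum(sel[, g1] & sel[, g2]))
      me <- mutual_exclusivity(counts, alpha)
      data.frame(gene1 = g1, gene2 = g2, cancer_type = ct,
                 s1_mut = counts$s1_mut, s2_mut = counts$s2,
                 s12_mut = counts$s12_mut,
                 p_cooccur = me$p_cooccur, mutex_p = me$mutex_p,
                 direction = me$direction, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$fdr <- bh_fdr(res$p_cooccur)
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
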