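#' Spearman correlation distance matrix
#'
#' \eqn{d(a, b) = 1 - \rho_{spearman}(a, b)} between item profiles, the
#' similarity metric used for clustering tumor samples on their pathway
#' enrichment profiles. Symmetric, zero diagonal, range [0, 2].
#'
#' @param m Numeric matrix (e.g. pathway x sample enrichment scores).
#' @param axis Cluster \code{"columns"} (samples; default) or \code{"rows"}.
#' @return Full symmetric distance matrix.
#' @export
spearman_distance <- function(m, axis = c("columns", "rows")) {
  axis <- match.arg(axis)
  if (axis == "rows") m <- t(m)
  if (ncol(m) < 3L) stop("need >= 3 items to cluster")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant profile(s), correlation undefined: ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  }
  d <- 1 - stats::cor(m, method = "spearman")
  diag(d) <- 0
  d
}

#' Cut an agglomerative tree into k clusters
#'
#' Average linkage by default (robust for correlation distances); labels are
#' contiguous integers 1..k in order of first appearance along the sample
#' ordering. Deterministic given the input ordering: ties in merge heights
#' follow \code{hclust}'s fixed lowest-index rule.
#'
#' @param d Distance matrix (full symmetric matrix or \code{dist}).
#' @param k Number of clusters (2 <= k <= n - 1).
#' @param linkage One of \code{"average"}, \code{"complete"}, \code{"ward.D2"}.
#' @return Object of class \code{cluster_assignment}: named integer labels,
#'   the \code{hclust} tree, linkage and k.
#' @export
hierarchical_clusters <- function(d, k, linkage = c("average", "complete", "ward.D2")) {
  linkage <- match.arg(linkage)
  dd <- if (inherits(d, "dist")) d else stats::as.dist(d)
  n <- attr(dd, "Size")
  if (k < 2 || k > n - 1) stop("k must satisfy 2 <= k <= n - 1")
  tree <- stats::hclust(dd, method = linkage)
  raw <- stats::cutree(tree, k = k)
  relabel <- match(raw, unique(raw))  # contiguous 1..k by first appearance
  labels <- stats::setNames(as.integer(relabel), names(raw))
  structure(list(labels = labels, tree = tree, linkage = linkage, k = k),
            class = "cluster_assignment")
}

#' Pathway-pathway correlation of enrichment profiles
#'
#' @param enrichment Pathway x sample score matrix (>= 3 samples).
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pathway_correlation <- function(enrichment, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (ncol(enrichment) < 3L) stop("need >= 3 samples")
  sds <- apply(enrichment, 1, stats::sd)
  if (any(sds == 0)) {
    stop("constant pathway profile(s): ",
         paste(rownames(enrichment)[sds == 0], collapse = ", "))
  }
  stats::cor(t(enrichment), method = method)
}

#' Per-cancer cluster composition
#'
#' Fraction of each cancer type's samples falling in each cluster; rows sum
#' to 1 per cancer type.
#'
#' @param assignment A \code{cluster_assignment} or named label vector.
#' @param cancer_type Named cancer-type label per sample.
#' @return Matrix cancer type x cluster of fractions.
#' @export
cluster_composition <- function(assignment, cancer_type) {
  labels <- if (inherits(assignment, "cluster_assignment")) assignment$labels else assignment
  if (!all(names(labels) %in% names(cancer_type))) {
    stop("cancer-type labels must cover all clustered samples")
  }
  tab <- table(cancer_type[names(labels)], labels)
  frac <- tab / rowSums(tab)
  m <- matrix(as.numeric(frac), nrow = nrow(tab), ncol = ncol(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m
}
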