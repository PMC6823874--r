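#' Differential expression p-value of a partner gene by mutation status
#'
#' Two-group comparison of the partner gene's expression in samples with vs
#' without a non-silent mutation in the primary gene. Counts are
#' library-size normalized to CPM, log2(CPM + 1) transformed, and compared
#' with a Welch t-test.
#'
#' @param counts Non-negative integer counts of the partner gene across
#'   samples.
#' @param mutant Logical mask: primary-gene mutation status per sample.
#' @param lib_sizes Per-sample library sizes (total counts); defaults to
#'   treating each sample's library as equal.
#' @return Two-sided p-value.
#' @export
diffexp_pvalue <- function(counts, mutant, lib_sizes = NULL) {
  mutant <- as.logical(mutant)
  stopifnot(length(counts) == length(mutant), all(counts >= 0))
  if (sum(mutant) < 2L || sum(!mutant) < 2L) {
    stop("each group needs >= 2 samples")
  }
  if (is.null(lib_sizes)) lib_sizes <- rep(1e6, length(counts))
  cpm <- counts / lib_sizes * 1e6
  y <- log2(cpm + 1)
  stats::t.test(y[mutant], y[!mutant])$p.value
}

#' Pearson expression correlation of two genes
#'
#' @param x,y Paired numeric expression values (>= 3 finite observations,
#'   non-zero variance in both).
#' @return List with \code{r} (Pearson correlation) and \code{p} (two-sided,
#'   t transform with n - 2 df).
#' @export
expression_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 paired finite observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Shared-pathway p-value for a gene pair
#'
#' Upper-tail hypergeometric probability that two genes share at least the
#' observed number of pathways: with N total pathways, K containing gene 1,
#' n containing gene 2 and k containing both, \eqn{P(X \ge k)}. Zero shared
#' pathways gives p = 1.
#'
#' @param gene1,gene2 Gene symbols.
#' @param genesets Named list of pathway member vectors.
#' @return Upper-tail p-value.
#' @export
shared_pathway_pvalue <- function(gene1, gene2, genesets) {
  if (length(genesets) == 0L) stop("empty pathway collection")
  has1 <- vapply(genesets, function(g) gene1 %in% g, logical(1))
  has2 <- vapply(genesets, function(g) gene2 %in% g, logical(1))
  n_total <- length(genesets)
  k <- sum(has1 & has2)
  if (k == 0L) return(1)
  hypergeom_cooccurrence(contingency_counts(n_total, sum(has1), sum(has2), k))
}

#' Assemble the four SL features for candidate gene pairs
#'
#' For each (primary, partner) pair and context (per cancer type by default,
#' or pooled), computes the four p-value features: differential expression of
#' the partner by primary-mutation status, Pearson expression correlation,
#' mutation mutual exclusivity, and shared-pathway membership. Pairs whose
#' genes are missing from the cohort matrices, or whose mutant/wild-type
#' split lacks two samples per group, are skipped with a warning.
#'
#' @param cohort A \code{cohort_bundle}.
#' @param pairs Data frame with columns \code{gene1} (primary),
#'   \code{gene2} (partner).
#' @param genesets Pathway collection for the shared-pathway feature.
#' @param context \code{"per_cancer"} (default) or \code{"pooled"}.
#' @return Data frame with pair identity, context and the feature columns
#'   \code{diffexp_p}, \code{corr_r}, \code{corr_p}, \code{mutex_p},
#'   \code{sharedpath_p}.
#' @export
build_features <- function(cohort, pairs, genesets,
                           context = c("per_cancer", "pooled")) {
  context <- match.arg(context)
  empty <- data.frame(gene1 = character(0), gene2 = character(0),
                      cancer_type = character(0), diffexp_p = numeric(0),
                      corr_r = numeric(0), corr_p = numeric(0),
                      mutex_p = numeric(0), sharedpath_p = numeric(0))
  if (nrow(pairs) == 0L) return(empty)
  known <- pairs$gene1 %in% colnames(cohort$mutation) &
    pairs$gene1 %in% rownames(cohort$counts) &
    pairs$gene2 %in% rownames(cohort$counts) &
    pairs$gene2 %in% colnames(cohort$mutation)
  if (any(!known)) {
    warning(sprintf("%d pair(s) skipped: gene absent from cohort matrices",
                    sum(!known)))
    pairs <- pairs[known, , drop = FALSE]
  }
  if (nrow(pairs) == 0L) return(empty)
  strata <- if (context == "pooled") {
    list(pooled = rownames(cohort$mutation))
  } else {
    split(names(cohort$cancer_type), cohort$cancer_type)
  }
  lib <- colSums(cohort$counts)
  rows <- list()
  n_skipped <- 0L
  for (ct in names(strata)) {
    ss <- strata[[ct]]
    mut <- cohort$mutation[ss, , drop = FALSE]
    for (i in seq_len(nrow(pairs))) {
      g1 <- pairs$gene1[[i]]
      g2 <- pairs$gene2[[i]]
      mask <- mut[, g1] == 1L
      if (sum(mask) < 2L || sum(!mask) < 2L) {
        n_skipped <- n_skipped + 1L
        next
      }
      de_p <- diffexp_pvalue(cohort$counts[g2, ss], mask, lib[ss])
      co <- expression_correlation(cohort$zscore[g1, ss], cohort$zscore[g2, ss])
      me <- mutual_exclusivity(contingency_counts(
        length(ss), sum(mask), sum(mut[, g2]), sum(mask & mut[, g2] == 1L)))
      rows[[length(rows) + 1L]] <- data.frame(
        gene1 = g1, gene2 = g2, cancer_type = ct,
        diffexp_p = de_p, corr_r = co$r, corr_p = co$p,
        mutex_p = me$mutex_p,
        sharedpath_p = shared_pathway_pvalue(g1, g2, genesets),
        stringsAsFactors = FALSE)
    }
  }
  if (n_skipped > 0L) {
    warning(sprintf("%d pair-context combination(s) skipped: fewer than 2 samples per mutation group",
                    n_skipped))
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

sl_feature_cols <- c("diffexp_p", "corr_p", "mutex_p", "sharedpath_p")

#' Train the SL Random Forest classifier
#'
#' Fits a Random Forest on the four p-value features with user-supplied
#' binary labels (1 = synthetic lethal). Deterministic under the given seed;
#' the returned model carries its out-of-bag class probabilities and OOB
#' AUROC as an honest training-performance summary, plus a fingerprint of the
#' training run.
#'
#' @param features Feature data frame from \code{\link{build_features}}.
#' @param labels Binary vector (0/1), one per feature row.
#' @param ntree Number of trees (default 500).
#' @param mtry Features tried per split (default floor(sqrt(p))).
#' @param seed RNG seed.
#' @return Object of class \code{sl_model}.
#' @export
train_sl_model <- function(features, labels, ntree = 500, mtry = NULL,
                           seed = 1) {
  x <- as.matrix(features[, sl_feature_cols])
  if (anyNA(x)) stop("NaN/NA feature values; drop incomplete rows first")
  y <- factor(as.integer(labels), levels = c(0L, 1L))
  if (length(unique(y)) < 2L) stop("training labels must contain both classes")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  set.seed(seed)
  fit <- randomForest::randomForest(x, y, ntree = ntree, mtry = mtry)
  oob <- fit$votes[, "1"]
  structure(list(
    forest = fit,
    oob_prob = oob,
    oob_auroc = auroc(oob, y == "1"),
    fingerprint = sprintf("rf_ntree%d_mtry%d_seed%d_n%d",
                          ntree, mtry, seed, nrow(x))
  ), class = "sl_model")
}

#' Cross-validated ranking AUROC of the SL Random Forest
#'
#' k-fold cross-validation: the forest is refit on each training split and
#' the held-out pairs are scored; the pooled held-out probabilities are
#' summarized as a ranking AUROC against the labels. Fold membership is
#' stratified by class and fixed by the seed.
#'
#' @param features Feature data frame from \code{\link{build_features}}.
#' @param labels Binary vector (0/1).
#' @param folds Number of folds (default 5).
#' @param ntree Trees per fold model.
#' @param seed RNG seed fixing folds and forests.
#' @return List with \code{auroc} and the pooled \code{prob} vector.
#' @export
sl_cv_auroc <- function(features, labels, folds = 5, ntree = 500, seed = 1) {
  x <- as.matrix(features[, sl_feature_cols])
  y <- factor(as.integer(labels), levels = c(0L, 1L))
  if (length(unique(y)) < 2L) stop("labels must contain both classes")
  set.seed(seed)
  fold <- integer(nrow(x))
  for (cls in levels(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  prob <- numeric(nrow(x))
  for (f in seq_len(folds)) {
    test <- fold == f
    fit <- randomForest::randomForest(x[!test, , drop = FALSE], y[!test],
                                      ntree = ntree)
    prob[test] <- stats::predict(fit, x[test, , drop = FALSE],
                                 type = "prob")[, "1"]
  }
  list(auroc = auroc(prob, y == "1"), prob = prob)
}

#' Score candidate pairs with a trained SL model
#'
#' @param model An \code{sl_model}.
#' @param features Feature data frame with the same columns as at training.
#' @param threshold Probability cutoff for the predicted label (default 0.5).
#' @return The feature frame with added \code{sl_prob}, \code{sl_label} and
#'   \code{model_fingerprint} columns.
#' @export
predict_sl <- function(model, features, threshold = 0.5) {
  stopifnot(inherits(model, "sl_model"))
  if (nrow(features) == 0L) {
    out <- features
    out$sl_prob <- numeric(0)
    out$sl_label <- logical(0)
    return(out)
  }
  missing <- setdiff(sl_feature_cols, colnames(features))
  if (length(missing) > 0L) {
    stop("feature schema mismatch; missing: ", paste(missing, collapse = ", "))
  }
  x <- as.matrix(features[, sl_feature_cols])
  prob <- stats::predict(model$forest, x, type = "prob")[, "1"]
  out <- features
  out$sl_prob <- unname(prob)
  out$sl_label <- out$sl_prob >= threshold
  out$model_fingerprint <- model$fingerprint
  out
}
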