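#' Conditional essentiality test (PvalRNAi)
#'
#' Welch two-sample t-test of a partner gene's RNAi essentiality scores in
#' primary-mutant vs wild-type cell lines. More negative scores mean more
#' essential, so conditional essentiality shows as a lower mutant mean; the
#' one-sided p-value tests that direction.
#'
#' @param scores RNAi essentiality scores of the partner gene across cell
#'   lines.
#' @param mutant Logical mask: primary-gene mutation status per line.
#' @return List with \code{p} (two-sided), \code{p_one_sided} (mutant mean
#'   lower), \code{direction} ("essential_in_mutants" or "not_essential"),
#'   \code{t}, \code{df}.
#' @export
conditional_essentiality <- function(scores, mutant) {
  mutant <- as.logical(mutant)
  stopifnot(length(scores) == length(mutant))
  if (sum(mutant) < 2L || sum(!mutant) < 2L) {
    stop("each group needs >= 2 cell lines")
  }
  tt <- stats::t.test(scores[mutant], scores[!mutant])
  one <- stats::t.test(scores[mutant], scores[!mutant], alternative = "less")
  list(p = tt$p.value,
       p_one_sided = one$p.value,
       direction = if (mean(scores[mutant]) < mean(scores[!mutant]))
         "essential_in_mutants" else "not_essential",
       t = unname(tt$statistic), df = unname(tt$parameter))
}

#' Disease-free survival benefit of partner downregulation (Kaplan-Meier)
#'
#' Within the primary-gene-mutated stratum, samples are split at the median
#' of the partner gene's expression (at-median samples go to the "down" arm),
#' Kaplan-Meier curves are fit per arm, and the arms are compared by the
#' log-rank test. Direction is "benefit" when the low-expression arm has the
#' longer restricted mean disease-free survival.
#'
#' @param clinical Data frame with \code{sample}, \code{dfs_months},
#'   \code{dfs_event}.
#' @param expr Named expression values of the partner gene (per sample).
#' @param mutant Named logical mask: primary-gene mutation per sample.
#' @param min_group Minimum samples required in each arm (default 5).
#' @param median_from \code{"stratum"} (median over mutated samples; default)
#'   or \code{"cohort"} (median over all samples).
#' @return List with \code{status} ("ok" or "insufficient"), \code{p}
#'   (log-rank), \code{chisq}, \code{direction} ("benefit"/"harm"/"none"),
#'   \code{n_down}, \code{n_up}, and restricted means \code{rmean_down},
#'   \code{rmean_up}.
#' @export
km_survival_benefit <- function(clinical, expr, mutant, min_group = 5,
                                median_from = c("stratum", "cohort")) {
  median_from <- match.arg(median_from)
  mutant <- stats::setNames(as.logical(mutant), names(mutant))
  ids <- clinical$sample[mutant[clinical$sample]]
  ids <- ids[!is.na(ids)]
  cut <- if (median_from == "stratum") {
    stats::median(expr[ids])
  } else {
    stats::median(expr)
  }
  down <- expr[ids] <= cut
  if (sum(down) < min_group || sum(!down) < min_group) {
    return(list(status = "insufficient", p = NA_real_, chisq = NA_real_,
                direction = "none", n_down = sum(down), n_up = sum(!down),
                rmean_down = NA_real_, rmean_up = NA_real_))
  }
  sel <- clinical[match(ids, clinical$sample), , drop = FALSE]
  arm <- factor(ifelse(down, "down", "up"), levels = c("down", "up"))
  surv <- survival::Surv(sel$dfs_months, sel$dfs_event)
  sd_ <- survival::survdiff(surv ~ arm)
  chisq <- sd_$chisq
  # identical arms give a 0/0 statistic: no evidence against the null
  if (!is.finite(chisq)) chisq <- 0
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  fit <- survival::survfit(surv ~ arm)
  tab <- summary(fit, rmean = max(sel$dfs_months))$table
  rmean <- tab[, "rmean"]
  direction <- if (abs(rmean[[1]] - rmean[[2]]) < .Machine$double.eps^0.5) {
    "none"
  } else if (rmean[[1]] > rmean[[2]]) "benefit" else "harm"
  list(status = "ok", p = p, chisq = chisq, direction = direction,
       n_down = sum(down), n_up = sum(!down),
       rmean_down = unname(rmean[[1]]), rmean_up = unname(rmean[[2]]))
}

#' Drug sensitivity test on LN-IC50 by mutation status
#'
#' One-sided Welch t-test with alternative "mutant mean LN-IC50 below
#' wild-type mean" (lower IC50 = more sensitive).
#'
#' @param ic50 LN-IC50 values of one drug across cell lines.
#' @param mutant Logical mask: primary-gene mutation status per line.
#' @param threshold Sensitivity call cutoff on the one-sided p (default 0.1).
#' @return List with \code{p_one_sided}, \code{direction}
#'   ("sensitive_in_mutants"/"not_sensitive") and \code{sensitive} flag.
#' @export
drug_sensitivity <- function(ic50, mutant, threshold = 0.1) {
  mutant <- as.logical(mutant)
  stopifnot(length(ic50) == length(mutant))
  if (sum(mutant) < 2L || sum(!mutant) < 2L) {
    stop("each group needs >= 2 cell lines")
  }
  one <- stats::t.test(ic50[mutant], ic50[!mutant], alternative = "less")
  dir <- if (mean(ic50[mutant]) < mean(ic50[!mutant]))
    "sensitive_in_mutants" else "not_sensitive"
  list(p_one_sided = one$p.value, direction = dir,
       sensitive = one$p.value < threshold)
}

#' Apply the in-silico validation cascade to predicted SL pairs
#'
#' For each predicted pair: (1) conditional essentiality of the partner in
#' primary-mutant cell lines (one-sided t-test), (2) Kaplan-Meier
#' disease-free survival comparison of partner-low vs partner-high expression
#' within primary-mutated tumors, and (3) drug sensitivity (one-sided t-test
#' on LN-IC50) for every drug targeting the partner. The final-list flag
#' requires the essentiality and survival filters to pass in the beneficial
#' direction; drug sensitivity annotates candidate therapies but does not
#' gate the final list.
#'
#' @param predictions Data frame from \code{\link{predict_sl}} (needs
#'   \code{gene1}, \code{gene2}; rows with \code{sl_label = FALSE} are kept
#'   but marked).
#' @param screens A \code{screen_bundle}.
#' @param cohort A \code{cohort_bundle}.
#' @param alpha_rnai One-sided essentiality threshold (default 0.05).
#' @param alpha_km Log-rank threshold (default 0.05).
#' @param alpha_drug One-sided drug-sensitivity threshold (default 0.1).
#' @param min_km_group Minimum samples per survival arm.
#' @return Data frame of validation records, one row per predicted pair,
#'   with per-filter p-values, directions, pass flags, the best sensitive
#'   drug (if any) and the \code{final_list} flag.
#' @export
validate_pairs <- function(predictions, screens, cohort,
                           alpha_rnai = 0.05, alpha_km = 0.05,
                           alpha_drug = 0.1, min_km_group = 5) {
  empty <- data.frame(
    gene1 = character(0), gene2 = character(0), sl_prob = numeric(0),
    rnai_p = numeric(0), rnai_direction = character(0), rnai_pass = logical(0),
    km_p = numeric(0), km_direction = character(0), km_pass = logical(0),
    drug = character(0), drug_p = numeric(0), drug_sensitive = logical(0),
    final_list = logical(0))
  if (nrow(predictions) == 0L) return(empty)
  pairs <- unique(predictions[, c("gene1", "gene2")])
  mut_expr <- cohort$zscore
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    g1 <- pairs$gene1[[i]]
    g2 <- pairs$gene2[[i]]
    if (!(g1 %in% colnames(screens$mutation)) ||
        !(g2 %in% rownames(screens$essentiality)) ||
        !(g1 %in% colnames(cohort$mutation)) ||
        !(g2 %in% rownames(mut_expr))) {
      warning(sprintf("pair %s-%s skipped: gene missing from screens or cohort",
                      g1, g2))
      next
    }
    cl_mask <- screens$mutation[, g1] == 1L
    rn <- conditional_essentiality(screens$essentiality[g2, ], cl_mask)
    rnai_pass <- rn$p_one_sided < alpha_rnai &&
      rn$direction == "essential_in_mutants"
    tum_mask <- stats::setNames(cohort$mutation[, g1] == 1L,
                                rownames(cohort$mutation))
    km <- km_survival_benefit(cohort$clinical, mut_expr[g2, ], tum_mask,
                              min_group = min_km_group)
    km_pass <- km$status == "ok" && !is.na(km$p) && km$p < alpha_km &&
      km$direction == "benefit"
    drugs <- screens$drug_targets$drug[screens$drug_targets$target == g2]
    drugs <- intersect(drugs, rownames(screens$ic50))
    best_drug <- NA_character_
    best_p <- NA_real_
    best_sens <- FALSE
    for (d in drugs) {
      ds <- drug_sensitivity(screens$ic50[d, ], cl_mask, alpha_drug)
      if (is.na(best_p) || ds$p_one_sided < best_p) {
        best_drug <- d
        best_p <- ds$p_one_sided
        best_sens <- ds$sensitive
      }
    }
    prob <- predictions$sl_prob[predictions$gene1 == g1 &
                                  predictions$gene2 == g2]
    rows[[length(rows) + 1L]] <- data.frame(
      gene1 = g1, gene2 = g2, sl_prob = max(prob),
      rnai_p = rn$p_one_sided, rnai_direction = rn$direction,
      rnai_pass = rnai_pass,
      km_p = km$p, km_direction = km$direction, km_pass = km_pass,
      drug = best_drug, drug_p = best_p, drug_sensitive = best_sens,
      final_list = rnai_pass && km_pass,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
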