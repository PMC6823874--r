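#' Build a candidate SL pair list from cohort truth
#'
#' Planted pairs plus seed-determined decoy pairs (primary genes cycled over
#' the cluster signature genes, decoy partners drawn from genes with no
#' planted role), with the ground-truth label attached. This is the
#' benchmark pair universe used by the end-to-end pipeline.
#'
#' @param cfg A \code{sim_config}.
#' @param truth Ground truth from \code{\link{generate_cohort}}.
#' @param n_total Total candidate pairs including the planted ones.
#' @return Data frame with \code{gene1}, \code{gene2}, \code{planted}.
#' @export
candidate_pairs <- function(cfg, truth, n_total = 400) {
  planted <- truth$sl_pairs
  n_decoy <- max(0L, n_total - nrow(planted))
  genes <- sim_gene_names(cfg$n_genes)
  free <- setdiff(genes, c(unlist(truth$signature), planted$gene2))
  set.seed(cfg$seed + 104729L)
  primaries <- rep(unlist(truth$signature), length.out = n_decoy)
  decoy_partners <- sample(free, n_decoy, replace = n_decoy > length(free))
  decoys <- data.frame(gene1 = primaries, gene2 = decoy_partners,
                       stringsAsFactors = FALSE)
  decoys <- decoys[decoys$gene1 != decoys$gene2, , drop = FALSE]
  out <- rbind(cbind(planted, planted = TRUE),
               cbind(decoys, planted = FALSE))
  out <- out[!duplicated(paste(out$gene1, out$gene2)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full DDR-SL pipeline on a synthetic cohort
#'
#' End-to-end driver: simulate cohort and screens, score DDR pathway
#' enrichment per sample (ssGSEA on z-scores), cluster samples, run the
#' recurrence filter and cluster-gene co-occurrence scan, assemble the four
#' SL features for the candidate pairs, train the Random Forest on the
#' planted labels, predict, validate through the essentiality / survival /
#' drug-sensitivity cascade, and assemble the SL-drug network. All stage
#' outputs are written as TSV files under \code{outdir} when given. Fully
#' deterministic under \code{cfg$seed}.
#'
#' @param cfg A \code{sim_config}.
#' @param outdir Optional output directory.
#' @param n_candidate_pairs Candidate pair universe size (default 400).
#' @param context Feature context passed to \code{\link{build_features}};
#'   the pooled default gives each pair one feature vector over the whole
#'   cohort.
#' @return List with every intermediate object (cohort, screens, enrichment,
#'   clusters, mutex tables, features, model, predictions, validation
#'   records, network).
#' @export
run_pipeline <- function(cfg, outdir = NULL, n_candidate_pairs = 400,
                         context = "pooled") {
  sim <- generate_cohort(cfg)
  cohort <- sim$cohort
  screens <- generate_screens(cfg, sim$truth)
  ddr_sets <- sim$genesets[seq_len(cfg$n_ddr_pathways)]

  enr <- ssgsea_matrix(cohort$zscore, ddr_sets)
  clusters <- hierarchical_clusters(spearman_distance(enr),
                                    k = cfg$n_clusters)
  pw_cor <- pathway_correlation(enr)
  composition <- cluster_composition(clusters, cohort$cancer_type)

  recurrent <- recurrent_gene_filter(cohort$mutation, cohort$cancer_type,
                                     min_fraction = 0.01, min_cancers = 2)
  cg <- cluster_gene_cooccurrence(
    cohort$mutation[, recurrent, drop = FALSE], clusters, fdr_threshold = 0.3)
  kept <- cg[cg$kept, , drop = FALSE]
  cluster_annot <- if (nrow(kept) > 0) {
    best <- kept[order(kept$fdr), ]
    best <- best[!duplicated(best$gene), ]
    stats::setNames(best$cluster, best$gene)
  } else NULL

  pairs <- candidate_pairs(cfg, sim$truth, n_candidate_pairs)
  features <- build_features(cohort, pairs, sim$genesets, context = context)
  key <- paste(features$gene1, features$gene2)
  labels <- pairs$planted[match(key, paste(pairs$gene1, pairs$gene2))]
  model <- train_sl_model(features, as.integer(labels), seed = cfg$seed)
  predictions <- predict_sl(model, features)

  positive <- predictions[predictions$sl_label, , drop = FALSE]
  validated <- validate_pairs(positive, screens, cohort)
  network <- assemble_network(validated, screens$drug_targets, cluster_annot)

  result <- list(cohort = cohort, screens = screens, genesets = sim$genesets,
                 truth = sim$truth, enrichment = enr, clusters = clusters,
                 pathway_correlation = pw_cor, composition = composition,
                 recurrent_genes = recurrent, cluster_gene = cg,
                 pairs = pairs, features = features, model = model,
                 predictions = predictions, validated = validated,
                 network = network)
  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  invisible(result)
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(result$cohort, file.path(outdir, "cohort"))
  write_screens(result$screens, file.path(outdir, "screens"))
  write_gmt(result$genesets, file.path(outdir, "pathways.gmt"))
  write_matrix_tsv(result$enrichment, file.path(outdir, "enrichment.tsv"),
                   "pathway")
  cl <- data.frame(sample = names(result$clusters$labels),
                   cluster = unname(result$clusters$labels))
  utils::write.table(cl, file.path(outdir, "clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$cluster_gene,
                     file.path(outdir, "cluster_gene_cooccurrence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$predictions, file.path(outdir, "sl_predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$validated, file.path(outdir, "sl_validated.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_network(result$network, file.path(outdir, "network.tsv"))
  invisible(outdir)
}
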