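#' Simulation configuration for synthetic cohorts and screens
#'
#' Builds and validates the configuration driving
#' \code{\link{generate_cohort}} and \code{\link{generate_screens}}. Defaults
#' emulate a multi-cancer tumor cohort with three latent DDR clusters, each
#' enriched for a disjoint subset of ten DDR pathways, cluster-specific
#' mutation signature genes producing mutual exclusivity across clusters, and
#' planted synthetic-lethal pairs carrying differential-expression,
#' co-expression, exclusivity, shared-pathway, essentiality, survival and
#' drug-sensitivity signals.
#'
#' @param n_cancer_types Number of cancer-type labels.
#' @param samples_per_type Samples simulated per cancer type.
#' @param n_genes Gene universe size.
#' @param n_clusters Number of latent DDR clusters (>= 2).
#' @param n_ddr_pathways DDR pathways driving cluster enrichment.
#' @param n_background_pathways Extra pathways for shared-pathway statistics.
#' @param pathway_size Genes per pathway.
#' @param enrichment_fold Mean count fold-change for a cluster's enriched
#'   pathway genes within that cluster.
#' @param baseline_mean Negative-binomial baseline mean count.
#' @param dispersion Negative-binomial dispersion (var = mu + dispersion*mu^2).
#' @param signature_genes_per_cluster Mutation signature genes per cluster.
#' @param in_cluster_mut_rate Signature-gene mutation probability within its
#'   cluster.
#' @param baseline_mut_rate Mutation probability otherwise.
#' @param n_sl_pairs Planted synthetic-lethal pairs.
#' @param sl_diffexp_fold Partner-gene mean count multiplier in samples
#'   mutated for the primary gene (< 1 = downregulation).
#' @param sl_corr_strength Scale of the shared log-normal latent factor
#'   coupling primary/partner expression.
#' @param sl_exclusivity_strength In [0, 1]; 1 means the partner never
#'   mutates in primary-mutant samples.
#' @param sl_partner_mut_rate Partner mutation probability in primary
#'   wild-type samples.
#' @param sl_shared_pathways Background pathways each planted pair is jointly
#'   inserted into.
#' @param sl_essentiality_shift Additive shift of the partner's RNAi score in
#'   primary-mutant cell lines (negative = more essential).
#' @param sl_survival_hr Hazard ratio of the high-partner-expression arm vs
#'   the co-inactivated (mutated, low-expression) arm; > 1 means
#'   co-inactivated patients progress later.
#' @param sl_drug_ic50_shift Additive LN-IC50 shift in primary-mutant cell
#'   lines for drugs targeting the partner (negative = more sensitive).
#' @param base_hazard Baseline exponential hazard per month.
#' @param follow_up_months Administrative censoring horizon (censoring times
#'   uniform on [0, follow_up_months]).
#' @param n_cell_lines Cell lines in the screen bundle.
#' @param cell_mut_rate Primary-gene mutation probability per cell line.
#' @param screen_noise_sd Gaussian noise sd of RNAi and LN-IC50 scores.
#' @param n_decoy_drugs Drugs targeting random genes with no planted effect.
#' @param seed RNG seed; fully determines all output.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(n_cancer_types = 3,
                       samples_per_type = 100,
                       n_genes = 600,
                       n_clusters = 3,
                       n_ddr_pathways = 10,
                       n_background_pathways = 40,
                       pathway_size = 30,
                       enrichment_fold = 3,
                       baseline_mean = 100,
                       dispersion = 0.2,
                       signature_genes_per_cluster = 5,
                       in_cluster_mut_rate = 0.3,
                       baseline_mut_rate = 0.02,
                       n_sl_pairs = 20,
                       sl_diffexp_fold = 0.25,
                       sl_corr_strength = 0.6,
                       sl_exclusivity_strength = 1,
                       sl_partner_mut_rate = 0.15,
                       sl_shared_pathways = 3,
                       sl_essentiality_shift = -2,
                       sl_survival_hr = 3,
                       sl_drug_ic50_shift = -2,
                       base_hazard = 0.02,
                       follow_up_months = 120,
                       n_cell_lines = 60,
                       cell_mut_rate = 0.5,
                       screen_noise_sd = 1,
                       n_decoy_drugs = 5,
                       seed = 1) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$in_cluster_mut_rate, cfg$baseline_mut_rate,
             cfg$sl_partner_mut_rate, cfg$cell_mut_rate,
             cfg$sl_exclusivity_strength)
  if (any(probs < 0 | probs > 1)) stop("config error: probabilities must lie in [0, 1]")
  if (cfg$n_clusters < 2) stop("config error: n_clusters must be >= 2")
  if (cfg$samples_per_type < 0 || cfg$n_cancer_types < 1) {
    stop("config error: invalid cohort dimensions")
  }
  n_role <- cfg$n_clusters * cfg$signature_genes_per_cluster + cfg$n_sl_pairs
  if (n_role > cfg$n_genes) {
    stop("config error: gene universe too small for signature + SL genes")
  }
  if (cfg$sl_survival_hr <= 0 || cfg$base_hazard <= 0) {
    stop("config error: hazards must be positive")
  }
  if (cfg$dispersion < 0 || cfg$enrichment_fold <= 0) {
    stop("config error: invalid expression parameters")
  }
  invisible(cfg)
}

#' Load a simulation configuration from YAML
#'
#' Reads a YAML mapping of \code{\link{sim_config}} argument names; unlisted
#' arguments keep their defaults.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's value.
#' @return A \code{sim_config}.
#' @export
sim_config_from_yaml <- function(path, seed = NULL) {
  vals <- yaml::read_yaml(path)
  if (!is.null(seed)) vals$seed <- seed
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown) > 0L) {
    stop("config error: unknown field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(sim_config, vals)
}

sim_gene_names <- function(n) sprintf("G%04d", seq_len(n))

# fixed gene-role layout: signature genes first, then SL partners
sim_roles <- function(cfg) {
  genes <- sim_gene_names(cfg$n_genes)
  n_sig <- cfg$n_clusters * cfg$signature_genes_per_cluster
  signature <- split(genes[seq_len(n_sig)],
                     rep(seq_len(cfg$n_clusters),
                         each = cfg$signature_genes_per_cluster))
  partners <- genes[n_sig + seq_len(cfg$n_sl_pairs)]
  primaries <- rep(unlist(signature), length.out = cfg$n_sl_pairs)
  list(genes = genes, signature = signature,
       sl_pairs = data.frame(gene1 = primaries, gene2 = partners,
                             stringsAsFactors = FALSE))
}

#' Generate a synthetic tumor cohort with planted structure
#'
#' Each sample is assigned a latent cluster; genes of the cluster's enriched
#' DDR pathways get elevated negative-binomial counts; cluster signature
#' genes mutate at the in-cluster rate and at baseline elsewhere, producing
#' mutual exclusivity across clusters; planted SL pairs add partner
#' downregulation in primary-mutant samples, a shared expression latent
#' factor, partner-mutation exclusivity, joint background-pathway membership,
#' and a disease-free survival benefit for co-inactivated samples
#' (primary mutated and partner expression below its cohort median).
#'
#' @param cfg A \code{sim_config}.
#' @return List with \code{cohort} (a \code{cohort_bundle}), \code{genesets}
#'   (named list usable as a GMT collection) and \code{truth} (latent cluster
#'   labels, signature genes, enriched-pathway map, planted SL pairs).
#' @export
generate_cohort <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  roles <- sim_roles(cfg)
  genes <- roles$genes
  n <- cfg$n_cancer_types * cfg$samples_per_type

  # pathway membership: DDR pathways avoid role genes so the enrichment and
  # SL channels stay separable; background pathways host shared memberships
  non_role <- setdiff(genes, c(unlist(roles$signature), roles$sl_pairs$gene2))
  pw_names <- c(sprintf("DDR_PATHWAY_%02d", seq_len(cfg$n_ddr_pathways)),
                sprintf("BG_PATHWAY_%02d", seq_len(cfg$n_background_pathways)))
  genesets <- vector("list", length(pw_names))
  names(genesets) <- pw_names
  for (i in seq_len(cfg$n_ddr_pathways)) {
    genesets[[i]] <- sample(non_role, cfg$pathway_size)
  }
  for (i in cfg$n_ddr_pathways + seq_len(cfg$n_background_pathways)) {
    genesets[[i]] <- sample(genes, cfg$pathway_size)
  }
  # joint membership of planted pairs in sl_shared_pathways background sets
  if (cfg$n_background_pathways > 0 && cfg$sl_shared_pathways > 0) {
    for (p in seq_len(nrow(roles$sl_pairs))) {
      host <- cfg$n_ddr_pathways +
        sample.int(cfg$n_background_pathways, min(cfg$sl_shared_pathways,
                                                  cfg$n_background_pathways))
      for (h in host) {
        genesets[[h]] <- unique(c(genesets[[h]],
                                  roles$sl_pairs$gene1[[p]],
                                  roles$sl_pairs$gene2[[p]]))
      }
    }
  }
  # disjoint split of DDR pathways across clusters
  pw_cluster <- rep(seq_len(cfg$n_clusters), length.out = cfg$n_ddr_pathways)
  enriched <- split(pw_names[seq_len(cfg$n_ddr_pathways)],
                    pw_cluster)

  if (n == 0L) {
    empty_mut <- matrix(0L, 0, cfg$n_genes, dimnames = list(NULL, genes))
    empty_expr <- matrix(0, cfg$n_genes, 0, dimnames = list(genes, NULL))
    cohort <- structure(list(
      mutation = empty_mut, counts = empty_expr, zscore = empty_expr,
      clinical = data.frame(sample = character(0), dfs_months = numeric(0),
                            dfs_event = integer(0)),
      cancer_type = character(0)), class = "cohort_bundle")
    return(list(cohort = cohort, genesets = genesets,
                truth = list(cluster = integer(0), signature = roles$signature,
                             enriched_pathways = enriched,
                             sl_pairs = roles$sl_pairs[0, ])))
  }

  samples <- sprintf("S%04d", seq_len(n))
  cancer <- stats::setNames(
    rep(sprintf("CANCER%02d", seq_len(cfg$n_cancer_types)),
        each = cfg$samples_per_type), samples)
  cluster <- stats::setNames(
    sample.int(cfg$n_clusters, n, replace = TRUE), samples)

  # mutations: baseline everywhere, elevated for a cluster's signature genes
  rate <- matrix(cfg$baseline_mut_rate, nrow = n, ncol = cfg$n_genes,
                 dimnames = list(samples, genes))
  for (cl in seq_len(cfg$n_clusters)) {
    rate[cluster == cl, roles$signature[[as.character(cl)]]] <- cfg$in_cluster_mut_rate
  }
  for (p in seq_len(nrow(roles$sl_pairs))) {
    rate[, roles$sl_pairs$gene2[[p]]] <- cfg$sl_partner_mut_rate
  }
  mut <- matrix(stats::rbinom(n * cfg$n_genes, 1L, as.vector(rate)),
                nrow = n, dimnames = dimnames(rate))
  # exclusivity: suppress partner mutations in primary-mutant samples
  for (p in seq_len(nrow(roles$sl_pairs))) {
    g1 <- roles$sl_pairs$gene1[[p]]
    g2 <- roles$sl_pairs$gene2[[p]]
    carrier <- mut[, g1] == 1L
    if (any(carrier)) {
      keep <- stats::rbinom(sum(carrier), 1L, 1 - cfg$sl_exclusivity_strength)
      mut[carrier, g2] <- mut[carrier, g2] * keep
    }
  }

  # expression means: cluster enrichment, SL co-expression and diffexp shifts
  mu <- matrix(cfg$baseline_mean, nrow = cfg$n_genes, ncol = n,
               dimnames = list(genes, samples))
  for (cl in seq_len(cfg$n_clusters)) {
    cl_genes <- unique(unlist(genesets[enriched[[as.character(cl)]]]))
    mu[cl_genes, cluster == cl] <- mu[cl_genes, cluster == cl] * cfg$enrichment_fold
  }
  for (p in seq_len(nrow(roles$sl_pairs))) {
    g1 <- roles$sl_pairs$gene1[[p]]
    g2 <- roles$sl_pairs$gene2[[p]]
    z <- stats::rnorm(n)
    mu[g1, ] <- mu[g1, ] * exp(cfg$sl_corr_strength * z)
    mu[g2, ] <- mu[g2, ] * exp(cfg$sl_corr_strength * z)
    mu[g2, mut[, g1] == 1L] <- mu[g2, mut[, g1] == 1L] * cfg$sl_diffexp_fold
  }
  size <- if (cfg$dispersion > 0) 1 / cfg$dispersion else Inf
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu), size = size),
                   nrow = cfg$n_genes, dimnames = dimnames(mu))
  logc <- log2(counts + 1)
  gm <- rowMeans(logc)
  gs <- apply(logc, 1, stats::sd)
  gs[gs == 0] <- 1
  zsc <- (logc - gm) / gs

  # disease-free survival: exponential baseline; co-inactivated samples
  # (primary mutated, partner expression below its median) progress later
  hazard <- rep(cfg$base_hazard, n)
  for (p in seq_len(nrow(roles$sl_pairs))) {
    g1 <- roles$sl_pairs$gene1[[p]]
    g2 <- roles$sl_pairs$gene2[[p]]
    carrier <- mut[, g1] == 1L
    if (sum(carrier) >= 2L) {
      # median taken within the mutated stratum: co-inactivation is defined
      # relative to the population the survival comparison conditions on
      low <- zsc[g2, ] <= stats::median(zsc[g2, carrier])
      co <- carrier & low
      hazard[co] <- hazard[co] / cfg$sl_survival_hr
    }
  }
  t_event <- stats::rexp(n, rate = hazard)
  t_cens <- stats::runif(n, 0, cfg$follow_up_months)
  clinical <- data.frame(
    sample = samples,
    dfs_months = pmin(t_event, t_cens),
    dfs_event = as.integer(t_event <= t_cens),
    stringsAsFactors = FALSE)

  cohort <- cohort_bundle(mutation = mut, counts = counts, zscore = zsc,
                          clinical = clinical, cancer_type = cancer)
  list(cohort = cohort, genesets = genesets,
       truth = list(cluster = cluster, signature = roles$signature,
                    enriched_pathways = enriched,
                    sl_pairs = roles$sl_pairs))
}

#' Generate a synthetic cell-line screen bundle
#'
#' Cell lines mutate the primary genes of the planted SL pairs at the
#' configured rate; for each planted pair, the partner's RNAi essentiality
#' score is shifted negative (more essential) in primary-mutant lines, and
#' each drug mapped to a planted partner has its LN-IC50 shifted down (more
#' sensitive) in primary-mutant lines. Non-planted genes and decoy drugs
#' carry no shift.
#'
#' @param cfg A \code{sim_config}.
#' @param truth Ground truth from \code{\link{generate_cohort}} (planted
#'   pairs).
#' @return A \code{screen_bundle}.
#' @export
generate_screens <- function(cfg, truth) {
  validate_sim_config(cfg)
  genes <- sim_gene_names(cfg$n_genes)
  bad <- setdiff(c(truth$sl_pairs$gene1, truth$sl_pairs$gene2), genes)
  if (length(bad) > 0L) {
    stop("config error: SL genes absent from the universe: ",
         paste(bad, collapse = ", "))
  }
  set.seed(cfg$seed + 7919L)  # independent stream from the cohort draw
  n <- cfg$n_cell_lines
  lines <- if (n > 0) sprintf("CL%03d", seq_len(n)) else character(0)
  primaries <- unique(truth$sl_pairs$gene1)

  mut <- matrix(0L, nrow = n, ncol = cfg$n_genes,
                dimnames = list(lines, genes))
  if (n > 0) {
    mut[] <- stats::rbinom(n * cfg$n_genes, 1L, cfg$baseline_mut_rate)
    for (g in primaries) {
      mut[, g] <- stats::rbinom(n, 1L, cfg$cell_mut_rate)
    }
  }

  ess <- matrix(stats::rnorm(cfg$n_genes * n, 0, cfg$screen_noise_sd),
                nrow = cfg$n_genes, dimnames = list(genes, lines))
  for (p in seq_len(nrow(truth$sl_pairs))) {
    g1 <- truth$sl_pairs$gene1[[p]]
    g2 <- truth$sl_pairs$gene2[[p]]
    carrier <- mut[, g1] == 1L
    ess[g2, carrier] <- ess[g2, carrier] + cfg$sl_essentiality_shift
  }

  planted_drugs <- if (nrow(truth$sl_pairs) > 0) {
    sprintf("DRUG_%s", truth$sl_pairs$gene2)
  } else character(0)
  decoys <- if (cfg$n_decoy_drugs > 0) {
    sprintf("DECOY%02d", seq_len(cfg$n_decoy_drugs))
  } else character(0)
  drugs <- c(planted_drugs, decoys)
  drug_targets <- data.frame(
    drug = drugs,
    target = c(truth$sl_pairs$gene2,
               if (length(decoys)) sample(genes, length(decoys)) else character(0)),
    stringsAsFactors = FALSE)
  ic50 <- matrix(stats::rnorm(length(drugs) * n, 0, cfg$screen_noise_sd),
                 nrow = length(drugs), dimnames = list(drugs, lines))
  for (p in seq_len(nrow(truth$sl_pairs))) {
    carrier <- mut[, truth$sl_pairs$gene1[[p]]] == 1L
    ic50[planted_drugs[[p]], carrier] <-
      ic50[planted_drugs[[p]], carrier] + cfg$sl_drug_ic50_shift
  }
  screen_bundle(mutation = mut, essentiality = ess, ic50 = ic50,
                drug_targets = drug_targets)
}
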