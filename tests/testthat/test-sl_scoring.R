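test_that("differential expression test is calibrated, powered, and guarded", {
  set.seed(61)
  null_p <- replicate(1000, diffexp_pvalue(rnbinom(40, mu = 100, size = 5),
                                           rep(c(TRUE, FALSE), each = 20)))
  expect_gt(mean(null_p < 0.05), 0.03)
  expect_lt(mean(null_p < 0.05), 0.07)

  set.seed(62)
  pow_p <- replicate(50, {
    counts <- c(rnbinom(20, mu = 400, size = 5), rnbinom(20, mu = 100, size = 5))
    diffexp_pvalue(counts, rep(c(TRUE, FALSE), each = 20))
  })
  expect_gt(mean(pow_p < 0.01), 0.95)

  expect_error(diffexp_pvalue(c(1, 2, 3), c(TRUE, FALSE, FALSE)), ">= 2")
})

test_that("Pearson correlation matches hand computation and null uniformity", {
  r <- expression_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$r, 0.8)
  x <- c(0.3, 1.7, 2.2, 5)
  expect_equal(expression_correlation(x, 2 * x + 1)$r, 1)
  expect_error(expression_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(expression_correlation(c(1, 2), c(1, 2)), ">= 3")

  set.seed(63)
  null_p <- replicate(1000, expression_correlation(rnorm(50), rnorm(50))$p)
  ks <- suppressWarnings(ks.test(null_p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("shared-pathway tail matches the direct enumeration", {
  sets <- c(
    lapply(1:3, function(i) c("g1", "g2", sprintf("x%d", i))),  # both
    list(c("g1", "y1")),                                        # g1 only
    list(c("g2", "z1"), c("g2", "z2")),                         # g2 only
    lapply(1:4, function(i) sprintf("w%d", i))                  # neither
  )
  names(sets) <- sprintf("P%02d", seq_along(sets))
  # N=10, K=4, n=5, k=3: [C(4,3)C(6,2) + C(4,4)C(6,1)] / C(10,5) = 66/252
  expect_equal(shared_pathway_pvalue("g1", "g2", sets), 66 / 252)
  expect_equal(shared_pathway_pvalue("g1", "w1", sets), 1)  # k = 0
  # both genes confined to one common pathway: K = n = k = 1, single-term tail
  expect_equal(shared_pathway_pvalue("q1", "q2", c(sets,
    list(PX = c("q1", "q2")))), 1 / 11)
  expect_error(shared_pathway_pvalue("a", "b", list()), "empty")
})

test_that("feature assembly flags planted pairs and skips unknown genes", {
  cfg <- sim_config(seed = 71, samples_per_type = 60, n_genes = 150,
                    n_sl_pairs = 3, n_background_pathways = 10,
                    pathway_size = 10)
  sim <- generate_cohort(cfg)
  planted <- sim$truth$sl_pairs
  set.seed(5)
  decoys <- data.frame(
    gene1 = rep(planted$gene1, 3),
    gene2 = sample(setdiff(sim_gene_names(cfg$n_genes),
                           c(unlist(sim$truth$signature), planted$gene2)), 9))
  feats <- build_features(sim$cohort, rbind(planted, decoys), sim$genesets,
                          context = "pooled")
  is_planted <- paste(feats$gene1, feats$gene2) %in%
    paste(planted$gene1, planted$gene2)
  # the strong channels separate planted from decoy pairs outright; mutex
  # can tie at 0 when a decoy partner happens never to co-mutate
  for (col in c("diffexp_p", "corr_p")) {
    expect_lt(max(feats[[col]][is_planted]), min(feats[[col]][!is_planted]))
  }
  expect_lt(mean(feats$sharedpath_p[is_planted]),
            mean(feats$sharedpath_p[!is_planted]))
  expect_lte(mean(feats$mutex_p[is_planted]),
             mean(feats$mutex_p[!is_planted]))
  # the mutex feature is the shared mutual_exclusivity implementation
  g1 <- planted$gene1[[1]]; g2 <- planted$gene2[[1]]
  mut <- sim$cohort$mutation
  me <- mutual_exclusivity(contingency_counts(
    nrow(mut), sum(mut[, g1]), sum(mut[, g2]), sum(mut[, g1] & mut[, g2])))
  expect_identical(feats$mutex_p[feats$gene1 == g1 & feats$gene2 == g2],
                   me$mutex_p)

  expect_identical(nrow(build_features(sim$cohort, planted[0, ], sim$genesets)), 0L)
  ghost <- data.frame(gene1 = planted$gene1[1], gene2 = "NOT_A_GENE")
  expect_warning(out <- build_features(sim$cohort, ghost, sim$genesets),
                 "absent")
  expect_identical(nrow(out), 0L)
})

test_that("the random forest separates separable features and rejects bad input", {
  set.seed(81)
  n <- 60
  feats <- data.frame(
    diffexp_p = c(runif(n / 2, 0, 0.01), runif(n / 2, 0.5, 1)),
    corr_p = c(runif(n / 2, 0, 0.01), runif(n / 2, 0.5, 1)),
    mutex_p = runif(n), sharedpath_p = runif(n))
  labels <- rep(c(1L, 0L), each = n / 2)
  m <- train_sl_model(feats, labels, seed = 7)
  expect_equal(auroc(m$oob_prob, labels == 1L), 1)
  expect_match(m$fingerprint, "seed7")

  m2 <- train_sl_model(feats, labels, seed = 7)
  expect_identical(m2$oob_prob, m$oob_prob)  # deterministic under seed

  expect_error(train_sl_model(feats, rep(1L, n)), "both classes")
  feats_na <- feats; feats_na$mutex_p[1] <- NA
  expect_error(train_sl_model(feats_na, labels), "NA")

  preds <- predict_sl(m, feats)
  expect_true(all(preds$sl_prob >= 0 & preds$sl_prob <= 1))
  expect_identical(preds$sl_label, preds$sl_prob >= 0.5)
  expect_identical(nrow(predict_sl(m, feats[0, ])), 0L)
  expect_error(predict_sl(m, feats[, 1:2]), "schema")
})
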