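test_that("co-occurrence tail matches hand-evaluated summations", {
  # C(3,2)C(7,2)/C(10,4) + C(3,3)C(7,1)/C(10,4) = (63 + 7)/210
  expect_equal(hypergeom_cooccurrence(contingency_counts(10, 3, 4, 2)),
               70 / 210)
  # single-term tail C(5,5)C(15,0)/C(20,5)
  expect_equal(hypergeom_cooccurrence(contingency_counts(20, 5, 5, 5)),
               1 / 15504)
  # zero overlap sums the full support
  expect_equal(hypergeom_cooccurrence(contingency_counts(30, 10, 7, 0)), 1)
})

test_that("count invariants are enforced", {
  expect_error(contingency_counts(0, 0, 0, 0), "positive")
  expect_error(contingency_counts(10, 11, 3, 1), "exceed")
  expect_error(contingency_counts(10, 3, 4, 5), "overlap")
  expect_error(contingency_counts(10, 3.5, 4, 2), "integer")
  expect_error(contingency_counts(10, 9, 9, 4), "feasible")
})

test_that("the tail is symmetric under swapping the gene and category roles", {
  set.seed(101)
  for (i in 1:50) {
    cc <- random_counts()
    swapped <- contingency_counts(cc$s_total, cc$s2, cc$s1_mut, cc$s12_mut)
    expect_equal(hypergeom_cooccurrence(cc), hypergeom_cooccurrence(swapped))
  }
})

test_that("mutex_p is the exact complement and the direction tag follows alpha", {
  me <- mutual_exclusivity(contingency_counts(10, 3, 4, 2))
  expect_equal(me$mutex_p, 1 - 70 / 210)
  expect_identical(me$direction, "neither")

  # zero overlap with ample margins: maximally exclusive observation
  me0 <- mutual_exclusivity(contingency_counts(100, 30, 30, 0))
  expect_equal(me0$mutex_p, 0)
  expect_identical(me0$direction, "exclusive")

  # full overlap with a tiny tail: tagged co-occurring
  me1 <- mutual_exclusivity(contingency_counts(20, 5, 5, 5))
  expect_identical(me1$direction, "cooccurring")
  expect_gt(me1$mutex_p, 0.999)

  set.seed(17)
  for (i in 1:100) {
    cc <- random_counts()
    me <- mutual_exclusivity(cc)
    expect_equal(me$mutex_p + me$p_cooccur, 1, tolerance = 1e-12)
  }
})

test_that("log-space accumulation agrees with the permutation null on random counts", {
  set.seed(23)
  for (i in 1:25) {
    cc <- random_counts()
    p <- hypergeom_cooccurrence(cc)
    ov <- perm_overlap(cc$s_total, cc$s1_mut, cc$s2, 20000)
    p_hat <- mean(ov >= cc$s12_mut)
    se <- sqrt(p * (1 - p) / 20000)
    expect_lt(abs(p - p_hat), 3.5 * se + 1e-4)
  }
})

test_that("BH step-up matches the hand-worked example and its identities", {
  expect_equal(bh_fdr(c(0.005, 0.01, 0.02, 0.9)),
               c(0.02, 0.02, 0.0266666666666667, 0.9))
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))
  expect_equal(bh_fdr(0.42), 0.42)
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(31)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, p.adjust(p, method = "BH"))
    expect_true(all(adj >= p))
  }
})

test_that("recurrence filter applies the per-cancer fraction rule", {
  mut <- matrix(0L, 250, 3, dimnames = list(sprintf("s%03d", 1:250),
                                            c("keep", "drop", "never")))
  ct <- setNames(rep(c("A", "B"), c(100, 150)), rownames(mut))
  mut[1:2, "keep"] <- 1L        # 2/100 in A
  mut[101:103, "keep"] <- 1L    # 3/150 in B
  mut[3:4, "drop"] <- 1L        # 2/100 in A only
  kept <- recurrent_gene_filter(mut, ct, min_fraction = 0.01, min_cancers = 2)
  expect_identical(kept, "keep")
  expect_error(recurrent_gene_filter(mut, ct, min_fraction = 0), "min_fraction")
  expect_error(recurrent_gene_filter(mut, ct[-1]), "label")
})

test_that("cluster-gene scan pinpoints a cluster-private gene and ignores uniform ones", {
  set.seed(47)
  n <- 60
  clusters <- setNames(rep(1:3, each = 20), sprintf("s%02d", 1:n))
  mut <- matrix(0L, n, 2, dimnames = list(names(clusters), c("private", "uniform")))
  mut[1:12, "private"] <- 1L                      # only cluster 1
  mut[seq(1, n, by = 4), "uniform"] <- 1L         # spread evenly
  tab <- cluster_gene_cooccurrence(mut, clusters)
  priv <- tab[tab$gene == "private", ]
  expect_identical(priv$cluster[which.min(priv$p_cooccur)], 1L)
  expect_true(tab$kept[tab$gene == "private" & tab$cluster == 1])
  expect_equal(tab$fdr, bh_fdr(tab$p_cooccur))

  # null gene in a large cohort: nothing kept at FDR < 0.3
  n2 <- 600
  clusters2 <- setNames(rep(1:3, each = 200), sprintf("t%03d", 1:n2))
  mut2 <- matrix(rbinom(n2, 1, 0.1), n2, 1,
                 dimnames = list(names(clusters2), "nullgene"))
  tab2 <- cluster_gene_cooccurrence(mut2, clusters2)
  expect_false(any(tab2$kept))

  empty <- cluster_gene_cooccurrence(mut[, 0, drop = FALSE], clusters)
  expect_identical(nrow(empty), 0L)
})

test_that("pairwise mutex runs per cancer type with a BH family per stratum", {
  set.seed(53)
  n <- 200
  mut <- matrix(rbinom(n * 2, 1, 0.2), n, 2,
                dimnames = list(sprintf("s%03d", 1:n), c("gA", "gB")))
  ct <- setNames(rep(c("X", "Y"), each = 100), rownames(mut))
  pairs <- data.frame(gene1 = "gA", gene2 = "gB")
  res <- pairwise_mutex(mut, pairs, ct)
  expect_identical(sort(res$cancer_type), c("X", "Y"))
  for (s in c("X", "Y")) {
    sel <- mut[ct == s, ]
    cc <- contingency_counts(100, sum(sel[, 1]), sum(sel[, 2]),
                             sum(sel[, 1] & sel[, 2]))
    expect_equal(res$p_cooccur[res$cancer_type == s],
                 hypergeom_cooccurrence(cc))
  }
  pooled <- pairwise_mutex(mut, pairs, cancer_type = NULL)
  expect_identical(nrow(pooled), 1L)
})
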