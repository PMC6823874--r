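test_that("conditional essentiality reproduces the Welch worked example", {
  r <- conditional_essentiality(c(-3, -2, -1, 1, 2, 3),
                                c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(r$t, -4.898979, tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_equal(r$p_one_sided, 0.004024947, tolerance = 1e-6)
  expect_identical(r$direction, "essential_in_mutants")

  same <- conditional_essentiality(rep(c(1, 2, 3), 2),
                                   rep(c(TRUE, FALSE), each = 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_error(conditional_essentiality(1:4, c(TRUE, FALSE, FALSE, FALSE)),
               ">= 2")
})

test_that("log-rank reproduces the hand-computed O-E example and identities", {
  # down arm events at 1, 2; up arm events at 3, 4; no censoring:
  # O - E = 1.1667, Var = 0.4722 -> chisq = 2.882, p = 0.0896
  clin <- make_clinical(c(1, 2, 3, 4), rep(1, 4), ids = letters[1:4])
  expr <- setNames(c(1, 1, 10, 10), letters[1:4])
  mask <- setNames(rep(TRUE, 4), letters[1:4])
  km <- km_survival_benefit(clin, expr, mask, min_group = 2)
  expect_equal(km$chisq, 2.882353, tolerance = 1e-5)
  expect_equal(km$p, 0.08956, tolerance = 1e-3)
  expect_identical(km$direction, "harm")  # low-expression arm progresses first

  # identical arm data: chisq 0, p 1
  clin2 <- make_clinical(rep(c(1, 2, 3, 4), 2), rep(1, 8))
  expr2 <- setNames(rep(c(0, 9), each = 4), clin2$sample)
  km2 <- km_survival_benefit(clin2, expr2,
                             setNames(rep(TRUE, 8), clin2$sample),
                             min_group = 2)
  expect_equal(km2$p, 1)
  expect_identical(km2$direction, "none")

  # relabeling the arms (negated expression) keeps p, flips direction
  km3 <- km_survival_benefit(clin, -expr, mask, min_group = 2)
  expect_equal(km3$p, km$p)
  expect_identical(km3$direction, "benefit")

  # too few mutated samples is a filtered outcome, not an exception
  km4 <- km_survival_benefit(clin, expr, mask, min_group = 5)
  expect_identical(km4$status, "insufficient")
  expect_true(is.na(km4$p))
})

test_that("survival benefit is detected for a planted hazard ratio at n_mut = 100", {
  set.seed(91)
  hits <- replicate(40, {
    n <- 100
    low <- rep(c(TRUE, FALSE), each = n / 2)
    haz <- ifelse(low, 0.05 / 3, 0.05)      # planted HR = 3 favoring low arm
    tm <- rexp(n, haz)
    cs <- runif(n, 0, 120)
    clin <- make_clinical(pmin(tm, cs), tm <= cs)
    expr <- setNames(ifelse(low, -1, 1) + rnorm(n, 0, 0.1), clin$sample)
    km <- km_survival_benefit(clin, expr, setNames(rep(TRUE, n), clin$sample))
    km$status == "ok" && km$p < 0.05 && km$direction == "benefit"
  })
  expect_gte(mean(hits), 0.9)
})

test_that("drug sensitivity is one-sided in the sensitizing direction", {
  same <- drug_sensitivity(rep(c(1, 2, 3), 2), rep(c(TRUE, FALSE), each = 3))
  expect_equal(same$p_one_sided, 0.5)

  set.seed(92)
  shifted <- drug_sensitivity(c(rnorm(30, -2), rnorm(30, 0)),
                              rep(c(TRUE, FALSE), each = 30))
  expect_lt(shifted$p_one_sided, 0.01)
  expect_true(shifted$sensitive)

  wrong_way <- drug_sensitivity(c(rnorm(30, 2), rnorm(30, 0)),
                                rep(c(TRUE, FALSE), each = 30))
  expect_gt(wrong_way$p_one_sided, 0.5)
  expect_false(wrong_way$sensitive)
  expect_identical(wrong_way$direction, "not_sensitive")
})

test_that("the cascade passes planted pairs and fails a survival-null pair", {
  cfg <- validation_config(seed = 95)
  sim <- generate_cohort(cfg)
  screens <- generate_screens(cfg, sim$truth)
  preds <- cbind(sim$truth$sl_pairs, sl_prob = 1, sl_label = TRUE)
  rec <- validate_pairs(preds, screens, sim$cohort)
  expect_identical(nrow(rec), nrow(preds))
  expect_true(all(rec$rnai_pass))
  expect_true(all(rec$final_list))
  expect_true(all(rec$drug_sensitive))

  # same channels but no survival effect: the KM filter blocks the final list
  cfg0 <- sim_config(seed = 95, samples_per_type = 200, n_sl_pairs = 3,
                     sl_survival_hr = 1, base_hazard = 0.04)
  sim0 <- generate_cohort(cfg0)
  screens0 <- generate_screens(cfg0, sim0$truth)
  preds0 <- cbind(sim0$truth$sl_pairs, sl_prob = 1, sl_label = TRUE)
  rec0 <- validate_pairs(preds0, screens0, sim0$cohort)
  expect_true(all(rec0$rnai_pass))       # essentiality channel still fires
  expect_false(any(rec0$final_list))     # survival filter gates it out

  expect_identical(nrow(validate_pairs(preds[0, ], screens, sim$cohort)), 0L)
})

test_that("all four validation tests hold their null size at alpha 0.05", {
  set.seed(97)
  ess <- replicate(400, conditional_essentiality(
    rnorm(40), rep(c(TRUE, FALSE), each = 20))$p_one_sided)
  drg <- replicate(400, drug_sensitivity(
    rnorm(40), rep(c(TRUE, FALSE), each = 20))$p_one_sided)
  km <- replicate(400, {
    n <- 40
    tm <- rexp(n, 0.03); cs <- runif(n, 0, 60)
    clin <- make_clinical(pmin(tm, cs), tm <= cs)
    expr <- setNames(rnorm(n), clin$sample)
    km_survival_benefit(clin, expr, setNames(rep(TRUE, n), clin$sample))$p
  })
  for (p in list(ess, drg, km)) {
    expect_gt(mean(p < 0.05), 0.025)
    expect_lt(mean(p < 0.05), 0.075)
  }
})
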