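test_that("generation is deterministic given a seed and validates its config", {
  cfg <- synthetic_config(n_reviews = 8, trials_per_review = c(4, 6), seed = 5)
  g1 <- generate_dataset(cfg)
  g2 <- generate_dataset(cfg)
  expect_identical(g1$records, g2$records)
  g3 <- generate_dataset(synthetic_config(n_reviews = 8,
                                          trials_per_review = c(4, 6),
                                          seed = 6))
  expect_false(identical(g1$records, g3$records))
  expect_error(synthetic_config(crob_error = 1.2))
  expect_error(synthetic_config(n_reviews = 1))
  expect_error(synthetic_config(trials_per_review = c(9, 3)))
})

test_that("the unclear channel hits its analytic rate", {
  cfg <- synthetic_config(
    n_reviews = 100, trials_per_review = c(20, 20),
    clarity_prob = stats::setNames(rep(0.5, 7),
                                   names(synthetic_config()$clarity_prob)),
    unclear_to_rating = 0, seed = 77)
  rec <- generate_dataset(cfg)$records
  p_hat <- mean(rec$allocation_concealment == "unclear")
  n <- nrow(rec)  # 2000 trials
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(p_hat - 0.5), 3 * se)
})

test_that("the analytic joint hits its noiseless and independence limits", {
  noiseless <- synthetic_config(
    clarity_prob = stats::setNames(rep(1, 7),
                                   names(synthetic_config()$clarity_prob)),
    crob_error = 0, pedro_error = 0, unclear_to_rating = 0)
  a <- analytic_joint_distribution(noiseless, "allocation")
  expect_equal(unname(a$kappa), rep(1, 3))
  indep <- synthetic_config(
    clarity_prob = stats::setNames(rep(1, 7),
                                   names(synthetic_config()$clarity_prob)),
    pedro_error = 0.5)
  b <- analytic_joint_distribution(indep, "allocation")
  expect_equal(unname(b$kappa["main"]), 0, tolerance = 1e-12)
  expect_equal(sum(b$joint), 1, tolerance = 1e-12)
})

test_that("the closed-form review-effect integral matches numerical integration", {
  cfg <- synthetic_config(review_effect_sd = 0.8)
  for (p in c(0.1, 0.4, 0.7)) {
    closed <- pnorm(qnorm(p) / sqrt(1 + 0.8^2))
    numeric <- integrate(function(u)
      pnorm(qnorm(p) + u) * dnorm(u, 0, 0.8), -Inf, Inf)$value
    expect_equal(closed, numeric, tolerance = 1e-8)
  }
})

test_that("a large simulation matches the analytic joint and kappa", {
  cfg <- synthetic_config(n_reviews = 500, trials_per_review = c(100, 100),
                          duplicate_fraction = 0, seed = 404)
  gd <- generate_dataset(cfg)
  rec <- gd$records
  n <- nrow(rec)  # 50,000 trials
  a <- analytic_joint_distribution(cfg, "allocation")
  emp <- prop.table(table(
    factor(ifelse(rec$concealed_allocation == 1, "yes", "no"), c("yes", "no")),
    factor(rec$allocation_concealment, c("low", "unclear", "high"))))
  for (i in 1:2) for (j in 1:3) {
    p <- a$joint[i, j]
    se <- sqrt(p * (1 - p) / n)
    # clustering by review inflates the binomial SE; allow 5x
    expect_lt(abs(emp[i, j] - p), 5 * se + 1e-4)
  }
  k_emp <- pair_item_analysis(rec, "concealed_allocation",
                              "allocation_concealment", n_boot = 10,
                              seed = 1)$kappa
  expect_equal(k_emp, unname(a$kappa["main"]), tolerance = 0.03)
})

test_that("analytic kappa strictly decreases as rater error grows", {
  ks <- vapply(c(0, 0.05, 0.1, 0.2, 0.35), function(e)
    analytic_joint_distribution(synthetic_config(crob_error = e),
                                "allocation")$kappa["main"], numeric(1))
  expect_true(all(diff(ks) < 0))
})

test_that("default marginals mirror the qualitative shape of the reference sample", {
  cfg <- synthetic_config(seed = 2024)
  rec <- generate_dataset(cfg)$records
  # participant and therapist blinding rare, assessor blinding ~ a third
  expect_lt(mean(rec$subject_blinding), 0.15)
  expect_lt(mean(rec$therapist_blinding), 0.15)
  expect_gt(mean(rec$assessor_blinding), 0.20)
  expect_lt(mean(rec$assessor_blinding), 0.50)
  # allocation concealment leans heavily on "unclear"
  expect_gt(mean(rec$allocation_concealment == "unclear"), 0.35)
  # review sizes respect the configured range
  sizes <- table(rec$review_id)
  expect_true(all(sizes >= 7 & sizes <= 22))
})

test_that("duplicate injection controls pair counts and is seed-deterministic", {
  cfg0 <- synthetic_config(n_reviews = 50, trials_per_review = c(30, 30),
                           duplicate_fraction = 0, seed = 55)
  rec <- generate_dataset(cfg0)$records  # 1500 trials
  expect_identical(inject_duplicates(rec, cfg0), rec)
  cfg <- synthetic_config(n_reviews = 50, trials_per_review = c(30, 30),
                          duplicate_fraction = 0.05, seed = 55)
  aug <- inject_duplicates(rec, cfg)
  expect_equal(nrow(aug) - nrow(rec), 75)  # floor(0.05 * 1500)
  expect_identical(aug, inject_duplicates(rec, cfg))
  tiny <- synthetic_config(n_reviews = 2, trials_per_review = c(2, 2),
                           duplicate_fraction = 0.05, seed = 1)
  rec_tiny <- generate_dataset(tiny)$records
  expect_warning(inject_duplicates(rec_tiny, tiny), "no duplicates")
})
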