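test_that("percent exact agreement is the diagonal share", {
  expect_equal(percent_exact_agreement(matrix(c(5, 0, 0, 5), 2)), 100)
  expect_equal(percent_exact_agreement(matrix(c(0, 5, 5, 0), 2)), 0)
  tab <- reconstruct_two_by_two(1438, 81.2, 473, 517)
  # (360 + 808) / 1438
  expect_equal(percent_exact_agreement(tab), 100 * 1168 / 1438)
  expect_equal(round(percent_exact_agreement(tab), 1), 81.2)
})

test_that("kappa is 1 on diagonal tables, 0 at independence, NA when degenerate", {
  expect_equal(cohen_kappa(matrix(c(5, 0, 0, 5), 2)), 1)
  expect_equal(cohen_kappa(matrix(c(9, 81, 1, 9), 2)), 0)  # P_o = P_e = 0.18
  expect_true(is.na(cohen_kappa(matrix(c(10, 0, 0, 0), 2))))
  expect_lte(cohen_kappa(random_table(3)), 1)
})

test_that("kappa matches a brute-force double loop and an independent library", {
  set.seed(101)
  for (i in 1:300) {
    k <- sample(2:4, 1)
    tab <- random_table(k)
    ours <- cohen_kappa(tab)
    oracle <- brute_force_kappa(tab)
    if (is.na(oracle)) expect_true(is.na(ours))
    else expect_equal(ours, oracle, tolerance = 1e-12)
  }
  skip_if_not_installed("e1071")
  for (i in 1:50) {
    tab <- random_table(3)
    expect_equal(cohen_kappa(tab), e1071::classAgreement(tab)$kappa,
                 tolerance = 1e-10)
  }
})

test_that("the asymptotic kappa variance matches a numeric delta method", {
  set.seed(33)
  for (i in 1:100) {
    tab <- random_table(sample(2:3, 1), n = 500)
    r <- kappa_normal_ci(tab)
    if (is.na(r$kappa)) next
    v <- numeric_kappa_var(tab)
    expect_equal(r$se^2, v, tolerance = 1e-4)
    expect_lte(r$ci_low, r$kappa)
    expect_gte(r$ci_high, r$kappa)
  }
})

test_that("ICC(1,1) handles perfect, opposed and random data", {
  x <- c(1, 5, 9, 14)
  expect_equal(icc_oneway(cbind(x, x))$icc, 1)
  expect_equal(icc_oneway(rbind(c(0, 10), c(10, 0)))$icc, -1)
  r <- icc_oneway(cbind(c(2, 2), c(2, 2)))
  expect_true(is.na(r$icc))  # zero total variance
  set.seed(7)
  for (i in 1:200) {
    m <- matrix(rnorm(20), 10, 2)
    expect_equal(icc_oneway(m)$icc, aov_icc(m), tolerance = 1e-12)
  }
})

test_that("ICC decreases as measurement error grows, subjects fixed", {
  set.seed(15)
  subj <- rnorm(60, sd = 3)
  iccs <- vapply(c(0.5, 1, 2, 4), function(s) {
    icc_oneway(cbind(subj + rnorm(60, sd = s), subj + rnorm(60, sd = s)))$icc
  }, numeric(1))
  expect_true(all(diff(iccs) < 0))
})

test_that("cluster bootstrap is deterministic, degenerate on constants, and percentile-valid", {
  d <- data.frame(y = rnorm(40), cl = rep(1:8, each = 5))
  const <- cluster_bootstrap_ci(d, function(x) 4.2, "cl", n_boot = 50, seed = 1)
  expect_equal(const$ci_low, 4.2)
  expect_equal(const$ci_high, 4.2)
  a <- cluster_bootstrap_ci(d, function(x) mean(x$y), "cl", n_boot = 200, seed = 3)
  b <- cluster_bootstrap_ci(d, function(x) mean(x$y), "cl", n_boot = 200, seed = 3)
  expect_identical(a[c("ci_low", "ci_high")], b[c("ci_low", "ci_high")])
  # endpoints are order statistics of the replicate distribution
  expect_true(a$ci_low %in% a$replicates && a$ci_high %in% a$replicates)
  expect_lte(a$ci_low, median(a$replicates))
  expect_gte(a$ci_high, median(a$replicates))
  expect_error(
    cluster_bootstrap_ci(d, function(x) NA_real_, "cl", n_boot = 20, seed = 1),
    "undefined")
  expect_error(cluster_bootstrap_ci(d[d$cl == 1, ], function(x) 1, "cl"),
               "2 clusters")
})

test_that("2x2 reconstruction solves the published-cell algebra", {
  expect_equal(unname(reconstruct_two_by_two(10, 100, 5, 5)),
               matrix(c(5L, 0L, 0L, 5L), 2))
  tab <- reconstruct_two_by_two(1438, 81.2, 473, 517)
  expect_equal(as.vector(tab), c(360L, 157L, 113L, 808L))
  expect_error(reconstruct_two_by_two(10, 0, 9, 9), "inconsistent")
})

test_that("interpretation labels respect the printed closed boundaries", {
  expect_equal(agreement_label(0.582, "kappa"), "moderate")
  expect_equal(agreement_label(0.818, "kappa"), "almost perfect")
  expect_equal(agreement_label(c(-0.01, 0, 0.20, 0.21, 0.40, 0.41, 0.60,
                                 0.61, 0.80, 0.81), "kappa"),
               c("poor", "slight", "slight", "fair", "fair", "moderate",
                 "moderate", "substantial", "substantial", "almost perfect"))
  expect_equal(agreement_label(0.285, "icc"), "poor")
  expect_equal(agreement_label(c(0.39, 0.40, 0.75, 0.76), "icc"),
               c("poor", "fair to good", "fair to good", "excellent"))
  expect_true(is.na(agreement_label(NA_real_, "kappa")))
})

test_that("the chance-agreement identity P_e = (P_o - k)/(1 - k) holds on computed tables", {
  set.seed(4)
  for (i in 1:100) {
    tab <- random_table(2)
    k <- cohen_kappa(tab)
    if (is.na(k) || k >= 1) next
    n <- sum(tab)
    po <- sum(diag(tab)) / n
    pe <- sum(rowSums(tab) * colSums(tab)) / n^2
    expect_equal((po - k) / (1 - k), pe, tolerance = 1e-12)
  }
})
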