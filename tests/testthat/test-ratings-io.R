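write_fixture_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(rows, path)
  path
}

pedro_cols <- paste(pedro_items()$item, collapse = ",")
pedro_yes <- paste(rep("yes", 11), collapse = ",")

test_that("a well-formed table round-trips with defaults for absent CROB columns", {
  f <- write_fixture_csv(c(
    paste0("trial_id,review_id,allocation_concealment,", pedro_cols),
    paste0("t1,r1,low,", pedro_yes),
    paste0("t2,r1,Unclear,", paste(rep("no", 11), collapse = ","))))
  rec <- read_trial_ratings(f)
  expect_s3_class(rec, "trial_ratings")
  expect_equal(nrow(rec), 2)
  expect_equal(rec$allocation_concealment, c("low", "unclear"))
  # absent CROB columns default to not assessed
  expect_true(all(rec$random_sequence_generation == "not_assessed"))
  expect_equal(rec$random_allocation, c(1L, 0L))
})

test_that("unknown rating tokens and missing mandatory columns are rejected", {
  f <- write_fixture_csv(c(
    paste0("trial_id,review_id,allocation_concealment,", pedro_cols),
    paste0("t1,r1,moderate,", pedro_yes)))
  expect_error(read_trial_ratings(f), "moderate")
  f2 <- write_fixture_csv(c("trial_id,allocation_concealment", "t1,low"))
  expect_error(read_trial_ratings(f2), "mandatory")
  f3 <- write_fixture_csv(c(
    paste0("trial_id,review_id,", pedro_cols),
    paste0("t1,r1,", paste(c("maybe", rep("yes", 10)), collapse = ","))))
  expect_error(read_trial_ratings(f3), "maybe")
})

test_that("duplicate trials across reviews get occurrence indices; within-review duplicates are invalid", {
  f <- write_fixture_csv(c(
    paste0("trial_id,review_id,", pedro_cols),
    paste0("t1,r1,", pedro_yes),
    paste0("t1,r2,", pedro_yes)))
  rec <- read_trial_ratings(f)
  expect_equal(rec$occurrence, c(1L, 2L))
  f2 <- write_fixture_csv(c(
    paste0("trial_id,review_id,", pedro_cols),
    paste0("t1,r1,", pedro_yes),
    paste0("t1,r1,", pedro_yes)))
  expect_error(read_trial_ratings(f2), "duplicated")
})

test_that("a stated PEDro total disagreeing with recomputation warns", {
  f <- write_fixture_csv(c(
    paste0("trial_id,review_id,pedro_total,", pedro_cols),
    paste0("t1,r1,10,", pedro_yes),
    paste0("t2,r1,3,", pedro_yes)))
  expect_warning(read_trial_ratings(f), "disagrees")
})

test_that("deduplication keeps one record per trial, pairs the second, drops the rest", {
  rec <- make_records(
    trial_id = c("a", "a", "a", "b", "c", "c"),
    review_id = c("r1", "r2", "r3", "r1", "r2", "r3"),
    crob = list(allocation_concealment = c("low", "high", "unclear",
                                           "low", "low", "low")))
  dd <- deduplicate_trials(rec, seed = 11)
  expect_equal(sort(unique(dd$main$trial_id)), c("a", "b", "c"))
  expect_equal(nrow(dd$main), 3)
  expect_equal(nrow(dd$pairs$first), 2)   # trials a and c
  expect_equal(dd$pairs$first$trial_id, dd$pairs$second$trial_id)
  expect_equal(dd$n_dropped, 1)           # third record of trial a
  # retained + paired + dropped covers every record of duplicated trials
  expect_false(anyDuplicated(dd$main$trial_id) > 0)
})

test_that("deduplication is seed-deterministic and order-invariant", {
  rec <- make_records(
    trial_id = rep(sprintf("t%02d", 1:12), each = 2),
    review_id = rep(c("r1", "r2", "r3", "r4"), 6))
  d1 <- deduplicate_trials(rec, seed = 5)
  d2 <- deduplicate_trials(rec, seed = 5)
  expect_identical(d1, d2)
  shuffled <- rec[rev(seq_len(nrow(rec))), ]
  class(shuffled) <- class(rec)
  d3 <- deduplicate_trials(shuffled, seed = 5)
  key <- function(d) paste(d$main$trial_id, d$main$review_id)
  expect_setequal(key(d1), key(d3))
  d4 <- deduplicate_trials(rec, seed = 6)
  expect_equal(sort(unique(d4$main$trial_id)), sort(unique(d1$main$trial_id)))
})

test_that("tables without duplicated trials pass through untouched", {
  rec <- make_records(trial_id = c("a", "b"), review_id = c("r1", "r2"))
  dd <- deduplicate_trials(rec, seed = 1)
  expect_equal(nrow(dd$main), 2)
  expect_equal(nrow(dd$pairs$first), 0)
  expect_equal(dd$n_dropped, 0)
})

test_that("reports round-trip through CSV at the stated display precision", {
  res <- list(
    item_pairs = data.frame(analysis = "x", n = 100L,
                            agreement = 81.2345, kappa = 0.58214,
                            ci_low = 0.4951, ci_high = 0.65616,
                            label = "moderate"),
    meta = list(seed = 1))
  d <- file.path(tempdir(), "report_rt")
  write_report(res, d)
  back <- read.csv(file.path(d, "item_pairs.csv"))
  expect_equal(back$agreement, 81.2)
  expect_equal(back$kappa, 0.582)
  expect_equal(back$ci_high, 0.656)
  js <- jsonlite::read_json(file.path(d, "report.json"))
  expect_equal(js$tables$item_pairs[[1]]$kappa, 0.58214)
  # empty results still produce a valid report
  d2 <- file.path(tempdir(), "report_empty")
  write_report(list(empty = data.frame()), d2)
  expect_true(file.exists(file.path(d2, "empty.csv")))
  expect_true(file.exists(file.path(d2, "report.json")))
})

test_that("read -> write -> read preserves every rating", {
  cfg <- synthetic_config(n_reviews = 6, trials_per_review = c(3, 5), seed = 3)
  rec <- generate_dataset(cfg)$records
  f <- tempfile(fileext = ".csv")
  write.csv(as.data.frame(rec), f, row.names = FALSE)
  back <- read_trial_ratings(f)
  expect_equal(as.data.frame(back), as.data.frame(rec))
})
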