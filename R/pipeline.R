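# point-estimate ICC without CI machinery (bootstrap statistic)
.icc_point <- function(m) {
  n <- nrow(m); k <- ncol(m)
  if (n < 2) return(NA_real_)
  rm_ <- rowMeans(m); gm <- mean(m)
  msb <- k * sum((rm_ - gm)^2) / (n - 1)
  msw <- sum((m - rm_)^2) / (n * (k - 1))
  den <- msb + (k - 1) * msw
  if (den <= .Machine$double.eps^0.5 * max(1, gm^2)) return(NA_real_)
  (msb - msw) / den
}

# first assessed variant per trial in the precedence order of `variants`
.select_variant_rating <- function(records, variants) {
  out <- rep(NA_character_, nrow(records))
  for (it in variants) {
    v <- records[[it]]
    take <- is.na(out) & v != "not_assessed"
    out[take] <- v[take]
  }
  out
}

#' Item-level agreement between a PEDro item and CROB variant(s)
#'
#' Pairs the binary PEDro rating with the dichotomized CROB rating over
#' the trials where the CROB item was assessed and not excluded by the
#' recoding scheme. When several CROB variants are given (a blinding
#' grouping), each trial contributes through the first variant in the
#' given order that its review assessed. Returns percent exact agreement,
#' Cohen's kappa with a review-clustered percentile bootstrap CI, and the
#' Landis-Koch label.
#'
#' @param records A `trial_ratings` table (deduplicated main set).
#' @param pedro_item PEDro item key.
#' @param crob_item CROB item key, or an ordered vector of variant keys.
#' @param scheme Recoding scheme for the CROB side (see [recode_crob()]).
#' @param n_boot Bootstrap replicates for the CI.
#' @param seed Seed for the bootstrap.
#' @return An `agreement_result`.
#' @export
pair_item_analysis <- function(records, pedro_item, crob_item,
                               scheme = "main", n_boot = 5000, seed = 1L) {
  stopifnot(pedro_item %in% pedro_items()$item,
            all(crob_item %in% crob_items()$item))
  y <- recode_crob(.select_variant_rating(records, crob_item), scheme)
  x <- records[[pedro_item]]
  keep <- !is.na(y)
  x <- x[keep]; y <- y[keep]
  cl <- records$review_id[keep]
  n <- length(x)
  if (n == 0) return(agreement_result(n = 0L))
  tab <- matrix(c(sum(x & y), sum(!x & y), sum(x & !y), sum(!x & !y)), 2, 2,
                dimnames = list(pedro = c("yes", "no"),
                                crob = c("1", "0")))
  kap <- cohen_kappa(tab)
  agr <- percent_exact_agreement(tab)
  ci <- list(ci_low = NA_real_, ci_high = NA_real_, n_undefined = NA_integer_)
  if (!is.na(kap) && length(unique(cl)) >= 2)
    ci <- .boot_kappa_ci(x, y, cl, n_boot = n_boot, seed = seed)
  agreement_result(n = n, table = tab, kappa = kap, agreement = agr,
                   ci_low = ci$ci_low, ci_high = ci$ci_high,
                   n_boot = n_boot, n_undefined = ci$n_undefined)
}

#' Agreement for a catalogued grouping of CROB blinding variants
#'
#' Convenience wrapper over [pair_item_analysis()] using the grouping
#' catalogue from [blinding_groupings()]; recoding always uses the main
#' scheme (low vs unclear-or-high).
#'
#' @param records A `trial_ratings` table.
#' @param pedro_item One of `subject_blinding`, `therapist_blinding`,
#'   `assessor_blinding`.
#' @param grouping Name of a grouping in
#'   `blinding_groupings()[[pedro_item]]`, or an ordered character vector
#'   of CROB variant keys.
#' @inheritParams pair_item_analysis
#' @return An `agreement_result`.
#' @export
grouped_blinding_analysis <- function(records, pedro_item, grouping,
                                      n_boot = 5000, seed = 1L) {
  cat_ <- blinding_groupings()
  stopifnot(pedro_item %in% names(cat_))
  if (is.character(grouping) && length(grouping) == 1L &&
      grouping %in% names(cat_[[pedro_item]]))
    grouping <- cat_[[pedro_item]][[grouping]]
  pair_item_analysis(records, pedro_item, grouping, scheme = "main",
                     n_boot = n_boot, seed = seed)
}

#' Agreement between the CROB summary score and total PEDro score
#'
#' Computes ICC(1,1) between the per-trial CROB summary score (percentage
#' of evaluated core domains at low risk) and the total PEDro score
#' rescaled to 0-100 (x10) so the two summaries share a scale, with a
#' review-clustered percentile bootstrap CI. Trials with no evaluated core
#' domain are excluded.
#'
#' @param records A `trial_ratings` table.
#' @param include_unclear Use the sensitivity summary-score definition
#'   (unclear counted with low).
#' @param n_boot Bootstrap replicates.
#' @param seed Seed for the bootstrap.
#' @return An `icc_result` with bootstrap `ci_low`/`ci_high` and `n_used`.
#' @export
summary_score_icc <- function(records, include_unclear = FALSE,
                              n_boot = 5000, seed = 1L) {
  cs <- crob_summary_score(records, include_unclear)
  pt <- 10 * pedro_total(records)
  keep <- !is.na(cs)
  d <- data.frame(s1 = cs[keep], s2 = pt[keep],
                  review = records$review_id[keep])
  res <- icc_oneway(cbind(d$s1, d$s2))
  res$n_used <- nrow(d)
  if (!is.na(res$icc) && length(unique(d$review)) >= 2) {
    ci <- cluster_bootstrap_ci(d, function(dd) .icc_point(cbind(dd$s1, dd$s2)),
                               cluster = "review", n_boot = n_boot,
                               seed = seed)
    res$ci_low <- ci$ci_low; res$ci_high <- ci$ci_high
    res$ci_method <- "clustered percentile bootstrap"
    res$n_undefined <- ci$n_undefined
  }
  res
}

#' Threshold-agreement matrix between the two summary scores
#'
#' For every combination of a total-PEDro-score threshold (1-point steps)
#' and a CROB-summary-score threshold (10% steps), dichotomizes trials by
#' "meets the threshold" on each instrument and computes the number
#' meeting both, percent exact agreement, and kappa with a
#' review-clustered bootstrap CI. The CROB summary uses the main
#' dichotomization (unclear counted as not met). Cells with no rating
#' variation are flagged not calculable.
#'
#' @param records A `trial_ratings` table.
#' @param pedro_thresholds,crob_thresholds Threshold grids (applied as >=).
#' @param n_boot Bootstrap replicates per cell.
#' @param seed Seed; one resampling plan is shared across cells.
#' @return Data frame with one row per cell: `pedro_threshold`,
#'   `crob_threshold`, `n_both`, `agreement`, `kappa`, `ci_low`,
#'   `ci_high`, `label`.
#' @export
threshold_matrix <- function(records, pedro_thresholds = 1:10,
                             crob_thresholds = seq(10, 100, 10),
                             n_boot = 1000, seed = 1L) {
  cs <- crob_summary_score(records, include_unclear = FALSE)
  pt <- pedro_total(records)
  keep <- !is.na(cs)
  cs <- cs[keep]; pt <- pt[keep]
  cl <- factor(records$review_id[keep])
  W <- with_local_seed(seed, .boot_weights(nlevels(cl), n_boot))
  out <- vector("list", length(pedro_thresholds) * length(crob_thresholds))
  i <- 0L
  for (tp in pedro_thresholds) for (tc in crob_thresholds) {
    x <- as.integer(pt >= tp); y <- as.integer(cs >= tc)
    tab <- matrix(c(sum(x & y), sum(!x & y), sum(x & !y), sum(!x & !y)), 2)
    kap <- cohen_kappa(tab)
    ci <- c(NA_real_, NA_real_)
    if (!is.na(kap) && nlevels(cl) >= 2) {
      M <- rowsum(cbind(x * y, x * (1 - y), (1 - x) * y, (1 - x) * (1 - y)),
                  cl)
      T <- W %*% M
      reps <- .kappa_abcd(T[, 1], T[, 2], T[, 3], T[, 4])
      reps <- reps[!is.na(reps)]
      if (length(reps) >= n_boot / 2) {
        pc <- .percentile_ci(reps, 0.95)
        ci <- c(pc$ci_low, pc$ci_high)
      }
    }
    i <- i + 1L
    out[[i]] <- data.frame(
      pedro_threshold = tp, crob_threshold = tc, n_both = sum(x & y),
      agreement = percent_exact_agreement(tab), kappa = kap,
      ci_low = ci[1], ci_high = ci[2],
      label = ifelse(is.na(kap), "not calculable",
                     agreement_label(kap, "kappa")))
  }
  do.call(rbind, out)
}

#' Between-review reliability of CROB ratings
#'
#' For trials rated independently by two reviews, computes per-item 3x3
#' unweighted kappa on the raw low/unclear/high ratings (over pairs where
#' both reviews assessed the item) with an unclustered normal-approximation
#' CI, plus ICC(1,1) with exact F intervals for the two summary-score
#' definitions. Items with no informative pairs or no rating variation are
#' flagged not calculable.
#'
#' @param pairs Row-aligned list `first`/`second` of `trial_ratings`
#'   tables, as produced by [deduplicate_trials()].
#' @return List with `items` (data frame: item, n, agreement, kappa,
#'   ci_low, ci_high, label) and `summary_icc` (list of `icc_result` for
#'   the `main` and `with_unclear` summary definitions).
#' @export
between_review_reliability <- function(pairs) {
  stopifnot(nrow(pairs$first) == nrow(pairs$second))
  lev <- c("low", "unclear", "high")
  rows <- lapply(crob_items()$item, function(it) {
    v1 <- pairs$first[[it]]; v2 <- pairs$second[[it]]
    keep <- v1 != "not_assessed" & v2 != "not_assessed"
    n <- sum(keep)
    if (n == 0)
      return(data.frame(item = it, n = 0L, agreement = NA_real_,
                        kappa = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, label = "not calculable"))
    tab <- table(factor(v1[keep], lev), factor(v2[keep], lev))
    ci <- kappa_normal_ci(tab)
    data.frame(item = it, n = n, agreement = percent_exact_agreement(tab),
               kappa = ci$kappa, ci_low = ci$ci_low, ci_high = ci$ci_high,
               label = ifelse(is.na(ci$kappa), "not calculable",
                              agreement_label(ci$kappa, "kappa")))
  })
  items <- do.call(rbind, rows)
  items <- items[order(-items$kappa, na.last = TRUE), ]
  rownames(items) <- NULL
  summary_icc <- lapply(c(main = FALSE, with_unclear = TRUE), function(fl) {
    s1 <- crob_summary_score(pairs$first, fl)
    s2 <- crob_summary_score(pairs$second, fl)
    keep <- !is.na(s1) & !is.na(s2)
    if (sum(keep) < 2) return(NULL)
    icc_oneway(cbind(s1[keep], s2[keep]))
  })
  list(items = items, summary_icc = summary_icc)
}

#' Run the complete agreement analysis
#'
#' Assembles every stage end-to-end from a raw rating table: duplicate
#' resolution, transformed rating counts, the six item-pair agreement
#' analyses under all three recoding schemes, the blinding-variant
#' groupings, summary-score ICCs (main and sensitivity), the
#' threshold-agreement matrix, between-review reliability, and score
#' descriptives. All randomness (duplicate retention, bootstraps) derives
#' deterministically from `seed`, so reruns reproduce identical output.
#'
#' @param records A `trial_ratings` table (duplicates still present).
#' @param n_boot Bootstrap replicates for clustered CIs.
#' @param n_boot_matrix Bootstrap replicates per threshold-matrix cell.
#' @param seed Master seed.
#' @return A named list of result tables suitable for [write_report()]:
#'   `descriptives`, `transformed_counts`, `item_pairs`, `blinding`,
#'   `summary_icc`, `thresholds`, `between_review`, plus `meta`.
#' @export
run_pipeline <- function(records, n_boot = 5000, n_boot_matrix = n_boot,
                         seed = 1L) {
  dd <- deduplicate_trials(records, seed = seed)
  main <- dd$main

  pairs6 <- item_pairs()
  ip <- list()
  for (sc in c("main", "sens1", "sens2"))
    for (i in seq_len(nrow(pairs6))) {
      nm <- paste(pairs6$pedro[i], sc, sep = ".")
      ip[[nm]] <- pair_item_analysis(main, pairs6$pedro[i], pairs6$crob[i],
                                     scheme = sc, n_boot = n_boot,
                                     seed = seed + i)
    }
  ip_df <- .results_to_df(ip)
  ip_df$pedro_item <- sub("\\..*$", "", ip_df$analysis)
  ip_df$scheme <- sub("^.*\\.", "", ip_df$analysis)

  bg <- list()
  cat_ <- blinding_groupings()
  for (pi in names(cat_))
    for (gn in names(cat_[[pi]]))
      bg[[paste(pi, gn, sep = ".")]] <-
        grouped_blinding_analysis(main, pi, gn, n_boot = n_boot,
                                  seed = seed + 100L)
  bg_df <- .results_to_df(bg)

  icc_main <- summary_score_icc(main, FALSE, n_boot = n_boot,
                                seed = seed + 200L)
  icc_sens <- summary_score_icc(main, TRUE, n_boot = n_boot,
                                seed = seed + 201L)
  icc_df <- data.frame(
    analysis = c("main", "with_unclear"),
    n = c(icc_main$n_used, icc_sens$n_used),
    icc = c(icc_main$icc, icc_sens$icc),
    ci_low = c(icc_main$ci_low, icc_sens$ci_low),
    ci_high = c(icc_main$ci_high, icc_sens$ci_high),
    label = c(icc_main$label, icc_sens$label))

  thr <- threshold_matrix(main, n_boot = n_boot_matrix, seed = seed + 300L)
  rel <- between_review_reliability(dd$pairs)
  rel_icc <- data.frame(
    analysis = names(rel$summary_icc),
    icc = vapply(rel$summary_icc, function(r) if (is.null(r)) NA_real_ else r$icc, 0),
    ci_low = vapply(rel$summary_icc, function(r) if (is.null(r)) NA_real_ else r$ci_low, 0),
    ci_high = vapply(rel$summary_icc, function(r) if (is.null(r)) NA_real_ else r$ci_high, 0))

  cs_main <- crob_summary_score(main, FALSE)
  cs_sens <- crob_summary_score(main, TRUE)
  pt <- pedro_total(main)
  descriptives <- data.frame(
    quantity = c("crob_summary_main_mean", "crob_summary_main_sd",
                 "crob_summary_unclear_mean", "crob_summary_unclear_sd",
                 "pedro_total_mean", "pedro_total_sd",
                 "n_trials", "n_reviews", "n_reliability_pairs", "n_dropped"),
    value = c(mean(cs_main, na.rm = TRUE), stats::sd(cs_main, na.rm = TRUE),
              mean(cs_sens, na.rm = TRUE), stats::sd(cs_sens, na.rm = TRUE),
              mean(pt), stats::sd(pt), nrow(main),
              length(unique(main$review_id)), nrow(dd$pairs$first),
              dd$n_dropped))

  list(descriptives = descriptives,
       transformed_counts = transformed_count_table(main),
       item_pairs = ip_df[, c("pedro_item", "scheme", "n", "agreement",
                              "kappa", "ci_low", "ci_high", "label")],
       blinding = bg_df,
       summary_icc = icc_df,
       thresholds = thr,
       between_review = list(items = rel$items, summary_icc = rel_icc),
       meta = list(seed = seed, n_boot = n_boot,
                   n_boot_matrix = n_boot_matrix,
                   ci_method = "clustered percentile bootstrap"))
}
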