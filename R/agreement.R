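#' Percent exact agreement on a square contingency table
#'
#' @param tab Square numeric matrix of paired rating counts.
#' @return Percentage (0-100) of pairs on the diagonal; `NA` for an empty
#'   table.
#' @export
percent_exact_agreement <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == ncol(tab), all(tab >= 0))
  n <- sum(tab)
  if (n == 0) return(NA_real_)
  100 * sum(diag(tab)) / n
}

#' Cohen's kappa on a square contingency table
#'
#' Chance-corrected agreement \eqn{\kappa = (P_o - P_e)/(1 - P_e)} with
#' observed agreement \eqn{P_o} the diagonal proportion and chance
#' agreement \eqn{P_e} the sum of marginal products. Works for any square
#' table (2x2 item comparisons, 3x3 raw three-level comparisons).
#' Degenerate tables with \eqn{P_e = 1} (all marginal mass in one
#' category) have no chance-corrected agreement and return `NA`
#' ("not calculable").
#'
#' @param tab Square numeric matrix of paired rating counts.
#' @return Kappa, or `NA` when not calculable.
#' @export
#' @examples
#' cohen_kappa(matrix(c(360, 157, 113, 808), 2))
cohen_kappa <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == ncol(tab), all(tab >= 0))
  n <- sum(tab)
  if (n == 0) return(NA_real_)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - pe <= .Machine$double.eps) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Asymptotic normal confidence interval for Cohen's kappa
#'
#' Large-sample delta-method variance of unweighted kappa (Fleiss, Cohen &
#' Everitt) on a k x k table, used for the analyses that are not
#' review-clustered.
#'
#' @param tab Square numeric matrix of paired rating counts.
#' @param level Confidence level.
#' @return List with `kappa`, `se`, `ci_low`, `ci_high` (all `NA` when
#'   kappa is not calculable).
#' @export
kappa_normal_ci <- function(tab, level = 0.95) {
  tab <- as.matrix(tab)
  k <- cohen_kappa(tab)
  if (is.na(k))
    return(list(kappa = NA_real_, se = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_))
  n <- sum(tab)
  p <- tab / n
  pr <- rowSums(p); pc <- colSums(p)
  pe <- sum(pr * pc)
  d <- diag(p)
  term1 <- sum(d * (1 - (pr + pc) * (1 - k))^2)
  off <- p; diag(off) <- 0
  w <- outer(seq_along(pr), seq_along(pc),
             function(i, j) (pc[i] + pr[j])^2)
  term2 <- (1 - k)^2 * sum(off * w)
  term3 <- (k - pe * (1 - k))^2
  v <- (term1 + term2 - term3) / (n * (1 - pe)^2)
  se <- sqrt(max(v, 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(kappa = k, se = se, ci_low = k - z * se, ci_high = k + z * se)
}

#' One-way random-effects intraclass correlation, ICC(1,1)
#'
#' Single-measurement ICC from a one-way ANOVA decomposition over subjects
#' (trials), each measured by `k` raters/instruments:
#' \eqn{ICC = (MS_B - MS_W)/(MS_B + (k-1) MS_W)}. For `k = 2` the ICC lies
#' in \eqn{[-1, 1]}. The exact confidence interval uses the one-way F
#' distribution.
#'
#' @param scores Numeric matrix or data frame, one row per subject, one
#'   column per measurement, on a common scale.
#' @param level Confidence level for the exact F interval.
#' @return An object of class `icc_result`: list with `icc`, `msb`, `msw`,
#'   `n`, `k`, `ci_low`, `ci_high`, `label`.
#' @export
icc_oneway <- function(scores, level = 0.95) {
  m <- as.matrix(scores)
  stopifnot(ncol(m) >= 2, nrow(m) >= 2, !anyNA(m))
  n <- nrow(m); k <- ncol(m)
  rm_ <- rowMeans(m); gm <- mean(m)
  msb <- k * sum((rm_ - gm)^2) / (n - 1)
  msw <- sum((m - rm_)^2) / (n * (k - 1))
  if (msb + (k - 1) * msw <= .Machine$double.eps^0.5 * max(1, gm^2)) {
    res <- list(icc = NA_real_, msb = msb, msw = msw, n = n, k = k,
                ci_low = NA_real_, ci_high = NA_real_, label = NA_character_)
    class(res) <- "icc_result"
    return(res)
  }
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  if (msw > 0) {
    f0 <- msb / msw
    a <- 1 - (1 - level) / 2
    fl <- f0 / stats::qf(a, n - 1, n * (k - 1))
    fu <- f0 * stats::qf(a, n * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else ci <- c(NA_real_, NA_real_)
  res <- list(icc = icc, msb = msb, msw = msw, n = n, k = k,
              ci_low = ci[1], ci_high = ci[2],
              label = agreement_label(icc, "icc"))
  class(res) <- "icc_result"
  res
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(1,1) = %s over %d subjects x %d measurements",
              ifelse(is.na(x$icc), "not calculable", sprintf("%.3f", x$icc)),
              x$n, x$k))
  if (!is.na(x$ci_low))
    cat(sprintf(" (95%% CI %.3f to %.3f)", x$ci_low, x$ci_high))
  if (!is.na(x$icc)) cat(sprintf(' — "%s"', x$label))
  cat("\n")
  invisible(x)
}

#' Interpretation label for an agreement coefficient
#'
#' Landis-Koch categories for kappa (<0 poor, 0.00-0.20 slight, 0.21-0.40
#' fair, 0.41-0.60 moderate, 0.61-0.80 substantial, 0.81-1.00 almost
#' perfect) and Fleiss categories for ICC (<0.40 poor, 0.40-0.75 fair to
#' good, >0.75 excellent). Boundary values belong to the closed printed
#' ranges, so kappa 0.20 is "slight" and ICC 0.75 is "fair to good".
#'
#' @param value Numeric coefficient(s).
#' @param scale `"kappa"` or `"icc"`.
#' @return Character vector of category labels (`NA` in, `NA` out).
#' @export
agreement_label <- function(value, scale = c("kappa", "icc")) {
  scale <- match.arg(scale)
  lab <- function(v) {
    if (is.na(v)) return(NA_character_)
    if (scale == "kappa") {
      if (v < 0) "poor"
      else if (v <= 0.20) "slight"
      else if (v <= 0.40) "fair"
      else if (v <= 0.60) "moderate"
      else if (v <= 0.80) "substantial"
      else "almost perfect"
    } else {
      if (v < 0.40) "poor"
      else if (v <= 0.75) "fair to good"
      else "excellent"
    }
  }
  vapply(value, lab, character(1))
}

# replicate-by-cluster count matrix: W[b, j] = times cluster j appears in
# bootstrap replicate b (each replicate draws n_clusters clusters with
# replacement)
.boot_weights <- function(n_clusters, n_boot) {
  W <- matrix(0L, n_boot, n_clusters)
  for (b in seq_len(n_boot))
    W[b, ] <- tabulate(sample.int(n_clusters, n_clusters, replace = TRUE),
                       n_clusters)
  W
}

# kappa on 2x2 totals (a = both positive, b = first-only, c = second-only,
# d = both negative); vectorized over replicates
.kappa_abcd <- function(a, b, c, d) {
  n <- a + b + c + d
  po <- (a + d) / n
  pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  k <- (po - pe) / (1 - pe)
  k[1 - pe <= .Machine$double.eps | n == 0] <- NA_real_
  k
}

.percentile_ci <- function(reps, level) {
  # endpoints are order statistics of the replicate distribution
  q <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                       type = 1, names = FALSE)
  list(ci_low = q[1], ci_high = q[2])
}

#' Review-clustered bootstrap confidence interval
#'
#' Percentile bootstrap interval for an arbitrary statistic of a rating
#' table, resampling whole clusters (systematic reviews) with replacement
#' to respect within-review correlation. Each replicate draws as many
#' clusters as the original data and keeps every row of a sampled cluster
#' (sampled duplicates count as distinct clusters). Replicates where the
#' statistic is undefined (`NA`) are dropped and counted; more than
#' `max_undefined` undefined replicates is an error.
#'
#' @param data Data frame of analysis rows.
#' @param statistic Function mapping a data frame like `data` to a single
#'   numeric value (`NA` when undefined).
#' @param cluster Cluster id for each row (vector, or name of a column of
#'   `data`).
#' @param n_boot Number of bootstrap replicates.
#' @param level Confidence level.
#' @param seed Integer seed; same seed, same interval.
#' @param max_undefined Maximum tolerated fraction of undefined replicates.
#' @return List with `ci_low`, `ci_high`, `n_boot`, `n_undefined` and
#'   `replicates` (the defined replicate values).
#' @export
cluster_bootstrap_ci <- function(data, statistic, cluster, n_boot = 5000,
                                 level = 0.95, seed = 1L,
                                 max_undefined = 0.5) {
  if (is.character(cluster) && length(cluster) == 1L)
    cluster <- data[[cluster]]
  stopifnot(length(cluster) == nrow(data))
  idx <- split(seq_len(nrow(data)), as.character(cluster))
  if (length(idx) < 2) stop("cluster bootstrap needs at least 2 clusters")
  reps <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      take <- unlist(idx[sample.int(length(idx), length(idx),
                                    replace = TRUE)], use.names = FALSE)
      statistic(data[take, , drop = FALSE])
    }, numeric(1))
  })
  n_undef <- sum(is.na(reps))
  if (n_undef > max_undefined * n_boot)
    stop(sprintf("statistic undefined in %.0f%% of bootstrap replicates",
                 100 * n_undef / n_boot))
  reps <- reps[!is.na(reps)]
  c(.percentile_ci(reps, level),
    list(n_boot = n_boot, n_undefined = n_undef, replicates = reps))
}

# fast clustered percentile bootstrap for kappa on paired binaries:
# aggregates the 2x2 cell contributions per cluster once, then a replicate
# is a weighted sum of cluster rows (identical in law to concatenating the
# sampled clusters)
.boot_kappa_ci <- function(x, y, cluster, n_boot, level = 0.95, seed = 1L,
                           max_undefined = 0.5) {
  cl <- factor(cluster)
  if (nlevels(cl) < 2) return(list(ci_low = NA_real_, ci_high = NA_real_,
                                   n_boot = n_boot, n_undefined = NA_integer_))
  M <- rowsum(cbind(a = x * y, b = x * (1 - y), c = (1 - x) * y,
                    d = (1 - x) * (1 - y)), cl)
  reps <- with_local_seed(seed, {
    W <- .boot_weights(nrow(M), n_boot)
    T <- W %*% M
    .kappa_abcd(T[, 1], T[, 2], T[, 3], T[, 4])
  })
  n_undef <- sum(is.na(reps))
  if (n_undef > max_undefined * n_boot)
    stop(sprintf("kappa undefined in %.0f%% of bootstrap replicates",
                 100 * n_undef / n_boot))
  reps <- reps[!is.na(reps)]
  c(.percentile_ci(reps, level),
    list(n_boot = n_boot, n_undefined = n_undef))
}

#' Reconstruct a paired 2x2 table from published summary numbers
#'
#' Solves the four cells of a paired dichotomous table from its size, the
#' printed percent exact agreement, and the two positive marginals: with
#' agreement count \eqn{A = n \cdot pct/100}, \eqn{a = (A + m_1 + m_2 -
#' n)/2}, \eqn{b = m_1 - a}, \eqn{c = m_2 - a}, \eqn{d = A - a}. Because a
#' printed agreement percentage carries 1-decimal precision, the agreement
#' count is allowed +/-1 slack to reach an integral, non-negative table;
#' anything beyond that is an inconsistency error. Used to validate
#' published item-level kappas against published marginal counts.
#'
#' @param n Number of paired ratings.
#' @param percent_agreement Printed percent exact agreement (0-100).
#' @param margin1,margin2 Positive counts for instrument 1 and 2.
#' @return 2x2 integer matrix `rbind(c(a, b), c(c, d))` (rows: instrument 1
#'   positive/negative; columns: instrument 2).
#' @export
#' @examples
#' reconstruct_two_by_two(1438, 81.2, 473, 517)
reconstruct_two_by_two <- function(n, percent_agreement, margin1, margin2) {
  stopifnot(n >= 1, margin1 >= 0, margin2 >= 0,
            percent_agreement >= 0, percent_agreement <= 100)
  a0 <- n * percent_agreement / 100
  cand <- round_half_up(a0) + c(0, 1, -1)
  cand <- cand[order(abs(cand - a0))]
  for (A in cand) {
    if (A < 0 || A > n) next
    a <- (A + margin1 + margin2 - n) / 2
    if (a != floor(a)) next
    b <- margin1 - a; cc <- margin2 - a; d <- A - a
    if (min(a, b, cc, d) < 0) next
    tab <- matrix(as.integer(c(a, cc, b, d)), 2, 2)
    dimnames(tab) <- list(instrument1 = c("pos", "neg"),
                          instrument2 = c("pos", "neg"))
    return(tab)
  }
  stop(sprintf(
    "inconsistent inputs: no non-negative integer table for n=%d, agreement=%.1f%%, margins=(%d, %d)",
    n, percent_agreement, margin1, margin2))
}

# result container for an item-level comparison
agreement_result <- function(n, table = NULL, kappa = NA_real_,
                             agreement = NA_real_, ci_low = NA_real_,
                             ci_high = NA_real_, n_boot = NA_integer_,
                             n_undefined = NA_integer_,
                             ci_method = "clustered percentile bootstrap") {
  res <- list(n = n, agreement = agreement, kappa = kappa,
              ci_low = ci_low, ci_high = ci_high,
              label = agreement_label(kappa, "kappa"),
              ci_method = ci_method, n_boot = n_boot,
              n_undefined = n_undefined, table = table)
  class(res) <- "agreement_result"
  res
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("n = %d, agreement = %s, kappa = %s",
              x$n,
              ifelse(is.na(x$agreement), "NA", sprintf("%.1f%%", x$agreement)),
              ifelse(is.na(x$kappa), "not calculable",
                     sprintf("%.3f", x$kappa))))
  if (!is.na(x$ci_low))
    cat(sprintf(" (95%% CI %.3f to %.3f)", x$ci_low, x$ci_high))
  if (!is.na(x$kappa)) cat(sprintf(' — "%s"', x$label))
  cat("\n")
  invisible(x)
}

# flatten a list of agreement_result into a report table
.results_to_df <- function(results) {
  do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(analysis = nm, n = r$n, agreement = r$agreement,
               kappa = r$kappa, ci_low = r$ci_low, ci_high = r$ci_high,
               label = ifelse(is.na(r$kappa), "not calculable", r$label),
               stringsAsFactors = FALSE)
  }))
}
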