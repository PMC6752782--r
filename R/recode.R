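#' Dichotomize a CROB rating under a recoding scheme
#'
#' The three-level Cochrane ratings are dichotomized three ways, differing
#' in how the "unclear" category is handled:
#' \describe{
#'   \item{main}{low -> 1; unclear or high -> 0.}
#'   \item{sens1}{low or unclear -> 1; high -> 0.}
#'   \item{sens2}{low -> 1; high -> 0; unclear excluded (`NA`).}
#' }
#' `not_assessed` is excluded under every scheme; exclusions propagate as
#' pairwise deletion downstream.
#'
#' @param rating Character vector of levels low/unclear/high/not_assessed.
#' @param scheme One of `"main"`, `"sens1"`, `"sens2"`.
#' @return Integer vector of 0/1 with `NA` for excluded ratings.
#' @export
#' @examples
#' recode_crob(c("low", "unclear", "high", "not_assessed"), "main")
recode_crob <- function(rating, scheme = c("main", "sens1", "sens2")) {
  scheme <- match.arg(scheme)
  bad <- setdiff(unique(rating), c(.crob_levels, NA))
  if (length(bad)) stop("invalid CROB level(s): ", paste(bad, collapse = ", "))
  map <- switch(scheme,
    main  = c(low = 1L, unclear = 0L, high = 0L, not_assessed = NA_integer_),
    sens1 = c(low = 1L, unclear = 1L, high = 0L, not_assessed = NA_integer_),
    sens2 = c(low = 1L, unclear = NA_integer_, high = 0L,
              not_assessed = NA_integer_))
  unname(map[rating])
}

#' Transform three-level rating counts under a recoding scheme
#'
#' Given the counts of trials rated low/unclear/high for an item, returns
#' the number coded 1, the denominator, and the percentage under each
#' dichotomization scheme (percent displayed as an integer, round-half-up).
#'
#' @param low,unclear,high Non-negative counts (vectorized).
#' @param scheme One of `"main"`, `"sens1"`, `"sens2"`.
#' @return Data frame with columns `n1`, `denominator`, `percent`
#'   (unrounded) and `percent_display` (integer, round-half-up; `NA` when
#'   the denominator is zero).
#' @export
transform_counts <- function(low, unclear, high,
                             scheme = c("main", "sens1", "sens2")) {
  scheme <- match.arg(scheme)
  stopifnot(all(low >= 0), all(unclear >= 0), all(high >= 0))
  n1 <- switch(scheme, main = low, sens1 = low + unclear, sens2 = low)
  denom <- switch(scheme, main = , sens1 = low + unclear + high,
                  sens2 = low + high)
  pct <- ifelse(denom > 0, 100 * n1 / denom, NA_real_)
  data.frame(n1 = n1, denominator = denom, percent = pct,
             percent_display = ifelse(is.na(pct), NA_integer_,
                                      as.integer(round_half_up(pct))))
}

# Collapse the reported variants of each core domain to one rating per
# (trial, domain), taking the worst rating (high > unclear > low) when a
# review reports several variants of the same domain.
.domain_ratings <- function(records) {
  severity <- c(low = 1L, unclear = 2L, high = 3L)
  out <- matrix(NA_character_, nrow(records), length(.crob_domains),
                dimnames = list(NULL, .crob_domains))
  for (it in crob_items()$item) {
    v <- records[[it]]
    assessed <- v != "not_assessed"
    for (dom in .crob_domain_map[[it]]) {
      cur <- out[, dom]
      take <- assessed & (is.na(cur) | severity[v] > severity[cur])
      out[take, dom] <- v[take]
    }
  }
  out
}

#' Per-trial CROB summary score
#'
#' Percentage of evaluated core domains rated low risk of bias (or low or
#' unclear when `include_unclear = TRUE`). The twelve reporting variants
#' are first mapped to the seven core domains; the combined
#' participants+personnel+outcome variant fills both the performance and
#' detection domains; when several variants of one domain are reported for
#' a trial the worst rating is used. Domains the review did not evaluate
#' are excluded from the denominator.
#'
#' @param records A `trial_ratings` table.
#' @param include_unclear Count unclear ratings in the numerator
#'   (sensitivity definition).
#' @return Numeric vector (0-100), `NA` when no core domain was evaluated.
#' @export
crob_summary_score <- function(records, include_unclear = FALSE) {
  dr <- .domain_ratings(records)
  evaluated <- !is.na(dr)
  good <- dr == "low"
  if (include_unclear) good <- good | dr == "unclear"
  num <- rowSums(good, na.rm = TRUE)
  den <- rowSums(evaluated)
  ifelse(den > 0, 100 * num / den, NA_real_)
}

#' Per-trial total PEDro score
#'
#' Number of items met over the ten scored items; the inclusion-criteria
#' item is recorded but never counted.
#'
#' @param records A `trial_ratings` table.
#' @return Integer vector in 0-10.
#' @export
pedro_total <- function(records) {
  scored <- pedro_items()$item[pedro_items()$scored]
  as.integer(rowSums(as.matrix(records[, scored])))
}

#' Transformed rating counts for every CROB item
#'
#' Tabulates low/unclear/high counts per CROB item over a rating table and
#' applies all three recoding schemes, mirroring the layout of a published
#' transformed-ratings table.
#'
#' @param records A `trial_ratings` table.
#' @return Data frame with one row per CROB item: raw counts and, per
#'   scheme, `n1` and display percentage.
#' @export
transformed_count_table <- function(records) {
  items <- crob_items()$item
  low <- unclear <- high <- integer(length(items))
  for (i in seq_along(items)) {
    v <- records[[items[i]]]
    low[i] <- sum(v == "low"); unclear[i] <- sum(v == "unclear")
    high[i] <- sum(v == "high")
  }
  out <- data.frame(item = items, n = low + unclear + high,
                    low = low, unclear = unclear, high = high)
  for (sc in c("main", "sens1", "sens2")) {
    tc <- transform_counts(low, unclear, high, sc)
    out[[paste0("n1_", sc)]] <- tc$n1
    out[[paste0("percent_", sc)]] <- tc$percent_display
  }
  out
}
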