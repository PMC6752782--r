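#' Column-naming and vocabulary configuration for rating tables
#'
#' Published review exports rarely share column names or rating spellings,
#' so ingestion is driven by a dialect object: a map from canonical item
#' keys (see [crob_items()], [pedro_items()]) to source column names, plus
#' token vocabularies for the two instruments. Tokens are matched
#' case-insensitively after trimming whitespace.
#'
#' @param columns Named character vector mapping canonical column keys
#'   (`trial_id`, `review_id`, item keys, optionally `pedro_total`) to
#'   source column names. Defaults to identity for every canonical key.
#' @param crob_tokens Named character vector mapping lowercase source tokens
#'   to the levels `low`, `unclear`, `high`, `not_assessed`.
#' @param pedro_tokens Named numeric vector mapping lowercase source tokens
#'   to 0/1.
#' @param delim Field delimiter for [read_trial_ratings()].
#' @return A list of class `rating_dialect`.
#' @export
rating_dialect <- function(columns = NULL, crob_tokens = NULL,
                           pedro_tokens = NULL, delim = ",") {
  canon <- c("trial_id", "review_id", crob_items()$item, pedro_items()$item,
             "pedro_total")
  cols <- stats::setNames(canon, canon)
  if (!is.null(columns)) {
    bad <- setdiff(names(columns), canon)
    if (length(bad))
      stop("unknown canonical column key(s): ", paste(bad, collapse = ", "))
    cols[names(columns)] <- columns
  }
  ct <- c(low = "low", unclear = "unclear", high = "high",
          "not assessed" = "not_assessed", not_assessed = "not_assessed",
          na = "not_assessed")
  ct <- c(ct, stats::setNames("not_assessed", ""))  # blank cell -> not assessed
  if (!is.null(crob_tokens)) ct <- c(crob_tokens, ct[!names(ct) %in% names(crob_tokens)])
  pt <- c(yes = 1, no = 0, y = 1, n = 0, "1" = 1, "0" = 0)
  if (!is.null(pedro_tokens)) pt <- c(pedro_tokens, pt[!names(pt) %in% names(pedro_tokens)])
  structure(list(columns = cols, crob_tokens = ct, pedro_tokens = pt,
                 delim = delim), class = "rating_dialect")
}

.norm_token <- function(x) tolower(trimws(as.character(x)))

#' Read a trial-rating table
#'
#' Reads a delimited text file with one row per (trial, review) pair,
#' validates rating vocabularies, and returns a canonical rating table.
#' CROB item columns absent from the file are filled with `not_assessed`
#' (reviews each use a subset of the reporting variants); all eleven PEDro
#' items are mandatory and must parse to yes/no.
#'
#' @param file Path to a delimited UTF-8 text file with a header row.
#' @param dialect A [rating_dialect()].
#' @return A `trial_ratings` data frame: `trial_id`, `review_id`,
#'   `occurrence` (order of appearance of duplicate trials), twelve CROB
#'   columns (levels low/unclear/high/not_assessed) and eleven 0/1 PEDro
#'   columns.
#' @export
read_trial_ratings <- function(file, dialect = rating_dialect()) {
  raw <- utils::read.csv(file, sep = dialect$delim, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  cols <- dialect$columns
  need <- c("trial_id", "review_id", pedro_items()$item)
  missing_cols <- need[!cols[need] %in% names(raw)]
  if (length(missing_cols))
    stop("missing mandatory column(s): ",
         paste(cols[missing_cols], collapse = ", "))

  out <- data.frame(trial_id = trimws(raw[[cols["trial_id"]]]),
                    review_id = trimws(raw[[cols["review_id"]]]),
                    stringsAsFactors = FALSE)
  for (it in crob_items()$item) {
    src <- cols[[it]]
    if (src %in% names(raw)) {
      tok <- .norm_token(raw[[src]])
      lev <- dialect$crob_tokens[tok]
      bad <- which(is.na(lev))
      if (length(bad))
        stop(sprintf("row %d, column '%s': unknown CROB rating token '%s'",
                     bad[1], src, tok[bad[1]]))
      out[[it]] <- unname(lev)
    } else {
      out[[it]] <- "not_assessed"
    }
  }
  for (it in pedro_items()$item) {
    src <- cols[[it]]
    tok <- .norm_token(raw[[src]])
    val <- dialect$pedro_tokens[tok]
    bad <- which(is.na(val))
    if (length(bad))
      stop(sprintf("row %d, column '%s': unknown PEDro rating token '%s'",
                   bad[1], src, tok[bad[1]]))
    out[[it]] <- as.integer(unname(val))
  }
  res <- as_trial_ratings(out)
  if (cols["pedro_total"] %in% names(raw)) {
    stated <- suppressWarnings(as.numeric(raw[[cols["pedro_total"]]]))
    mism <- which(!is.na(stated) & stated != pedro_total(res))
    if (length(mism))
      warning(sprintf(
        "stated PEDro total disagrees with recomputation in %d row(s), e.g. row %d",
        length(mism), mism[1]))
  }
  res
}

#' Construct a validated trial-rating table from a data frame
#'
#' Accepts a data frame with `trial_id`, `review_id`, any subset of CROB
#' item columns and all PEDro item columns in canonical naming; fills
#' absent CROB columns with `not_assessed`, assigns the occurrence index
#' for duplicate trials and validates invariants.
#'
#' @param df A data frame in canonical column naming.
#' @return A `trial_ratings` data frame.
#' @export
as_trial_ratings <- function(df) {
  stopifnot(is.data.frame(df))
  for (key in c("trial_id", "review_id"))
    if (!key %in% names(df)) stop("missing column: ", key)
  df$trial_id <- as.character(df$trial_id)
  df$review_id <- as.character(df$review_id)
  for (it in crob_items()$item) {
    if (!it %in% names(df)) df[[it]] <- "not_assessed"
    v <- as.character(df[[it]])
    v[is.na(v)] <- "not_assessed"
    bad <- setdiff(unique(v), .crob_levels)
    if (length(bad))
      stop(sprintf("column '%s': invalid CROB level(s): %s", it,
                   paste(bad, collapse = ", ")))
    df[[it]] <- v
  }
  for (it in pedro_items()$item) {
    if (!it %in% names(df)) stop("missing PEDro item column: ", it)
    v <- df[[it]]
    if (any(is.na(v)) || !all(v %in% c(0L, 1L)))
      stop(sprintf("column '%s': PEDro ratings must be complete 0/1", it))
    df[[it]] <- as.integer(v)
  }
  key <- paste(df$trial_id, df$review_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (trial_id, review_id) pair: ",
         df$trial_id[duplicated(key)][1])
  df$occurrence <- stats::ave(seq_len(nrow(df)), df$trial_id,
                              FUN = seq_along)
  ord <- c("trial_id", "review_id", "occurrence",
           crob_items()$item, pedro_items()$item)
  df <- df[, ord]
  class(df) <- c("trial_ratings", "data.frame")
  df
}

#' @export
print.trial_ratings <- function(x, ...) {
  cat(sprintf("<trial_ratings> %d trial ratings, %d reviews, %d distinct trials\n",
              nrow(x), length(unique(x$review_id)),
              length(unique(x$trial_id))))
  NextMethod()
}

#' Resolve duplicate trials into a main set and reliability pairs
#'
#' Trials appearing in more than one review carry independent rating sets.
#' For each such trial one record is retained in the main analysis set,
#' chosen uniformly at random among its reviews; a second record (the first
#' remaining occurrence in a canonical sort of review ids) is paired with
#' it for between-review reliability; third and later occurrences are
#' dropped. Deterministic given `seed`.
#'
#' @param records A `trial_ratings` table.
#' @param seed Integer seed controlling the random retention.
#' @return A list with `main` (a `trial_ratings` table, one row per trial),
#'   `pairs` (list with row-aligned `trial_ratings` tables `first` and
#'   `second`) and `n_dropped` (count of third and later occurrences).
#' @export
deduplicate_trials <- function(records, seed = 1L) {
  stopifnot(inherits(records, "trial_ratings"))
  idx_by_trial <- split(seq_len(nrow(records)), records$trial_id)
  # sort groups by trial id so that the seeded draws are order-independent
  idx_by_trial <- idx_by_trial[order(names(idx_by_trial))]
  keep <- integer(0); first <- integer(0); second <- integer(0)
  n_dropped <- 0L
  with_local_seed(seed, {
    for (ix in idx_by_trial) {
      if (length(ix) == 1L) {
        keep <- c(keep, ix)
      } else {
        ix <- ix[order(records$review_id[ix])]
        r <- ix[sample.int(length(ix), 1L)]
        rest <- setdiff(ix, r)
        keep <- c(keep, r)
        first <- c(first, r)
        second <- c(second, rest[1L])
        n_dropped <- n_dropped + length(rest) - 1L
      }
    }
  })
  main <- records[sort(keep), , drop = FALSE]
  o <- order(records$trial_id[first])
  pairs <- list(first = records[first[o], , drop = FALSE],
                second = records[second[o], , drop = FALSE])
  class(main) <- class(records)
  class(pairs$first) <- class(records)
  class(pairs$second) <- class(records)
  list(main = main, pairs = pairs, n_dropped = n_dropped)
}

# numeric display formatting used by write_report: percentages to 1 decimal,
# kappa/ICC-scale quantities to 3 decimals
.format_report_df <- function(df) {
  for (nm in names(df)) {
    if (!is.numeric(df[[nm]])) next
    if (grepl("percent|agreement", nm)) df[[nm]] <- round(df[[nm]], 1)
    else if (grepl("kappa|icc|ci_low|ci_high", nm)) df[[nm]] <- round(df[[nm]], 3)
  }
  df
}

#' Write analysis results to delimited and structured-text reports
#'
#' Writes every data-frame element of `results` (nested lists are
#' flattened with dot-separated names) as a CSV with display formatting —
#' percentages to 1 decimal, kappa/ICC and CI bounds to 3 decimals — plus a
#' single `report.json` carrying the unrounded values and any metadata.
#'
#' @param results Named list of data frames (possibly nested) and metadata.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  flat <- list(); meta <- list()
  flatten <- function(x, prefix = "") {
    for (nm in names(x)) {
      full <- if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm
      if (is.data.frame(x[[nm]])) flat[[full]] <<- x[[nm]]
      else if (is.list(x[[nm]])) flatten(x[[nm]], full)
      else meta[[full]] <<- x[[nm]]
    }
  }
  flatten(results)
  paths <- character(0)
  for (nm in names(flat)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(.format_report_df(flat[[nm]]), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(c(list(tables = flat), list(meta = meta)), jp,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(paths, jp))
}
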