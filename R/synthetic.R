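#' Configuration for the synthetic rating-data generator
#'
#' The generator emulates the structure the agreement analysis assumes:
#' trials nested in reviews with a review-level quality shift, a latent
#' per-domain methodological status, a reporting-clarity channel that
#' drives the "unclear" category, two instruments reading the same latent
#' status with independent error, review-specific choices of blinding
#' reporting variant, and cross-review duplicate ratings. Defaults mirror
#' the descriptive shape of a large published sample of physical-therapy
#' trials: about a hundred reviews of 7-22 trials, participant/therapist
#' blinding rare, assessor blinding in roughly a third of trials, and
#' heavy "unclear" use for allocation concealment.
#'
#' @param n_reviews Number of reviews (clusters).
#' @param trials_per_review Integer range `c(lo, hi)`; sizes are drawn
#'   uniformly.
#' @param domain_prevalence Named probability per core domain that the
#'   latent status is "met".
#' @param clarity_prob Named probability per core domain that the trial
#'   report is clear enough to judge.
#' @param crob_error Probability the CROB rater misclassifies a clearly
#'   reported status.
#' @param pedro_error Same for the PEDro rater.
#' @param unclear_to_rating Probability an unclear report is nonetheless
#'   rated low/high rather than unclear.
#' @param review_effect_sd SD of the review-level shift applied to the
#'   probit-transformed latent prevalence.
#' @param duplicate_fraction Share of trials also rated by a second review.
#' @param duplicate_error Probability a duplicate review's rating of an
#'   item differs from the first review's.
#' @param blinding_style_probs Named probabilities over the review-level
#'   blinding reporting styles (`separate`, `participants_only`,
#'   `combined`, `triple`, `split_outcomes`).
#' @param assessed_prob Named review-level probabilities that the optional
#'   items `selective_reporting` and `other_bias` are evaluated at all.
#' @param extra_pedro_prevalence Marginal yes-probabilities for the PEDro
#'   items not tied to a core domain.
#' @param seed Integer seed.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_reviews = 108,
    trials_per_review = c(7, 22),
    domain_prevalence = c(sequence = 0.55, allocation = 0.40,
                          performance = 0.08, detection = 0.45,
                          attrition = 0.55, reporting = 0.50, other = 0.55),
    clarity_prob = c(sequence = 0.60, allocation = 0.45, performance = 0.85,
                     detection = 0.70, attrition = 0.78, reporting = 0.62,
                     other = 0.70),
    crob_error = 0.10,
    pedro_error = 0.07,
    unclear_to_rating = 0.15,
    review_effect_sd = 0.5,
    duplicate_fraction = 0.05,
    duplicate_error = 0.15,
    blinding_style_probs = c(separate = 0.20, participants_only = 0.12,
                             combined = 0.38, triple = 0.15,
                             split_outcomes = 0.15),
    assessed_prob = c(selective_reporting = 0.91, other_bias = 0.60),
    extra_pedro_prevalence = c(eligibility = 0.81,
                               baseline_comparability = 0.80,
                               intention_to_treat = 0.32,
                               between_group_comparisons = 0.95,
                               point_measures = 0.91),
    seed = 1L) {
  cfg <- list(n_reviews = as.integer(n_reviews),
              trials_per_review = as.integer(trials_per_review),
              domain_prevalence = domain_prevalence,
              clarity_prob = clarity_prob, crob_error = crob_error,
              pedro_error = pedro_error,
              unclear_to_rating = unclear_to_rating,
              review_effect_sd = review_effect_sd,
              duplicate_fraction = duplicate_fraction,
              duplicate_error = duplicate_error,
              blinding_style_probs = blinding_style_probs,
              assessed_prob = assessed_prob,
              extra_pedro_prevalence = extra_pedro_prevalence,
              seed = as.integer(seed))
  probs <- c(cfg$domain_prevalence, cfg$clarity_prob, cfg$crob_error,
             cfg$pedro_error, cfg$unclear_to_rating, cfg$duplicate_fraction,
             cfg$duplicate_error, cfg$blinding_style_probs,
             cfg$assessed_prob, cfg$extra_pedro_prevalence)
  stopifnot(cfg$n_reviews >= 2, length(cfg$trials_per_review) == 2,
            cfg$trials_per_review[1] <= cfg$trials_per_review[2],
            cfg$trials_per_review[1] >= 1,
            all(probs >= 0 & probs <= 1), cfg$review_effect_sd >= 0,
            setequal(names(cfg$domain_prevalence), .crob_domains),
            setequal(names(cfg$clarity_prob), .crob_domains))
  class(cfg) <- "synthetic_config"
  cfg
}

# variants a review assesses under each blinding reporting style
.style_variants <- list(
  separate = c("blinding_participants", "blinding_personnel",
               "blinding_outcome_assessment"),
  participants_only = c("blinding_participants",
                        "blinding_outcome_assessment"),
  combined = c("blinding_participants_personnel",
               "blinding_outcome_assessment"),
  triple = "blinding_participants_personnel_outcome",
  split_outcomes = c("blinding_participants_personnel",
                     "blinding_outcome_subjective",
                     "blinding_outcome_objective")
)

# CROB rating of a variant given latent status and clarity of its domains
.draw_crob <- function(s_var, c_var, cfg) {
  n <- length(s_var)
  forced <- stats::runif(n) < cfg$unclear_to_rating
  unclear <- !c_var & !forced
  err <- stats::runif(n) < cfg$crob_error
  low <- xor(s_var, err)
  out <- ifelse(unclear, "unclear", ifelse(low, "low", "high"))
  out
}

#' Generate a synthetic trial-rating dataset
#'
#' Draws a full rating table from the generative model described in
#' [synthetic_config()]: per review a quality shift, a blinding reporting
#' style and optional-item assessment flags; per trial and core domain a
#' latent status and a clarity flag; then a CROB rating per assessed
#' variant (unclear with probability (1-clarity)(1-unclear_to_rating),
#' otherwise low/high tracking the latent status with error `crob_error`)
#' and a PEDro binary per paired item (yes tracks the latent status with
#' error `pedro_error`, degraded to no when the report is unclear, since
#' the scale requires explicit reporting). Combined blinding variants
#' track the conjunction of their component domains. Deterministic given
#' `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return List with `records` (a `trial_ratings` table), `truth` (list
#'   with the per-trial latent status and clarity matrices, review
#'   effects, and the per-domain analytic joint distributions from
#'   [analytic_joint_distribution()]).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  with_local_seed(cfg$seed, {
    rng <- seq(cfg$trials_per_review[1], cfg$trials_per_review[2])
    sizes <- if (length(rng) == 1L) rep(rng, cfg$n_reviews)
             else sample(rng, cfg$n_reviews, replace = TRUE)
    n <- sum(sizes)
    review <- rep(sprintf("rev%03d", seq_len(cfg$n_reviews)), sizes)
    u <- stats::rnorm(cfg$n_reviews, 0, cfg$review_effect_sd)
    u_row <- rep(u, sizes)
    styles <- sample(names(cfg$blinding_style_probs), cfg$n_reviews,
                     replace = TRUE, prob = cfg$blinding_style_probs)
    style_row <- rep(styles, sizes)
    sr_assessed <- rep(stats::runif(cfg$n_reviews) <
                         cfg$assessed_prob["selective_reporting"], sizes)
    ob_assessed <- rep(stats::runif(cfg$n_reviews) <
                         cfg$assessed_prob["other_bias"], sizes)

    S <- C <- matrix(FALSE, n, length(.crob_domains),
                     dimnames = list(NULL, .crob_domains))
    for (d in .crob_domains) {
      p <- stats::pnorm(stats::qnorm(cfg$domain_prevalence[[d]]) + u_row)
      S[, d] <- stats::runif(n) < p
      C[, d] <- stats::runif(n) < cfg$clarity_prob[[d]]
    }

    df <- data.frame(trial_id = sprintf("trial%05d", seq_len(n)),
                     review_id = review, stringsAsFactors = FALSE)
    assessed_of <- function(it) {
      switch(it,
        random_sequence_generation = ,
        allocation_concealment = ,
        incomplete_outcome_data = rep(TRUE, n),
        selective_reporting = sr_assessed,
        other_bias = ob_assessed,
        vapply(style_row, function(st) it %in% .style_variants[[st]],
               logical(1)))
    }
    for (it in crob_items()$item) {
      doms <- .crob_domain_map[[it]]
      s_var <- Reduce(`&`, lapply(doms, function(d) S[, d]))
      c_var <- Reduce(`&`, lapply(doms, function(d) C[, d]))
      r <- .draw_crob(s_var, c_var, cfg)
      a <- assessed_of(it)
      df[[it]] <- ifelse(a, r, "not_assessed")
    }
    paired <- stats::setNames(item_pairs()$crob, item_pairs()$pedro)
    dom_of_pedro <- c(random_allocation = "sequence",
                      concealed_allocation = "allocation",
                      subject_blinding = "performance",
                      therapist_blinding = "performance",
                      assessor_blinding = "detection",
                      follow_up = "attrition")
    for (it in names(dom_of_pedro)) {
      d <- dom_of_pedro[[it]]
      err <- stats::runif(n) < cfg$pedro_error
      df[[it]] <- as.integer(C[, d] & xor(S[, d], err))
    }
    for (it in names(cfg$extra_pedro_prevalence))
      df[[it]] <- as.integer(stats::runif(n) < cfg$extra_pedro_prevalence[[it]])

    records <- as_trial_ratings(df)
    joints <- lapply(stats::setNames(nm = .crob_domains),
                     function(d) analytic_joint_distribution(cfg, d))
    list(records = records,
         truth = list(latent = S, clarity = C, review_effect = u,
                      style = styles, joints = joints))
  })
}

#' Analytic joint distribution and population kappa for one domain
#'
#' Marginalizes the generative model exactly for a single-construct item
#' of one core domain: the joint probabilities of the (PEDro yes/no) x
#' (CROB low/unclear/high) outcome, and the implied population kappa of
#' the dichotomized pair under each recoding scheme. Every cell
#' probability is linear in the latent prevalence, so the review effect
#' integrates in closed form: the marginal prevalence is
#' `pnorm(qnorm(p) / sqrt(1 + sd^2))`.
#'
#' @param config A [synthetic_config()].
#' @param domain One of the seven core domain names.
#' @return List with `joint` (2x3 matrix, rows `yes`/`no`, columns
#'   `low`/`unclear`/`high`), `prevalence` (marginal latent prevalence)
#'   and `kappa` (named vector: `main`, `sens1`, `sens2`).
#' @export
analytic_joint_distribution <- function(config, domain) {
  stopifnot(inherits(config, "synthetic_config"),
            domain %in% .crob_domains)
  cfg <- config
  pbar <- stats::pnorm(stats::qnorm(cfg$domain_prevalence[[domain]]) /
                         sqrt(1 + cfg$review_effect_sd^2))
  cl <- cfg$clarity_prob[[domain]]
  joint <- matrix(0, 2, 3, dimnames = list(pedro = c("yes", "no"),
                                           crob = c("low", "unclear", "high")))
  for (S in c(1, 0)) for (Cc in c(1, 0)) {
    w <- (if (S) pbar else 1 - pbar) * (if (Cc) cl else 1 - cl)
    p_yes <- if (Cc) (if (S) 1 - cfg$pedro_error else cfg$pedro_error) else 0
    p_unclear <- if (Cc) 0 else 1 - cfg$unclear_to_rating
    m <- if (Cc) 1 else cfg$unclear_to_rating
    p_low <- m * (if (S) 1 - cfg$crob_error else cfg$crob_error)
    p_high <- m * (if (S) cfg$crob_error else 1 - cfg$crob_error)
    crob <- c(p_low, p_unclear, p_high)
    joint["yes", ] <- joint["yes", ] + w * p_yes * crob
    joint["no", ] <- joint["no", ] + w * (1 - p_yes) * crob
  }
  kap <- function(p) {
    # p: 2x2 probability table
    po <- p[1, 1] + p[2, 2]
    pe <- sum(rowSums(p) * colSums(p))
    if (1 - pe <= .Machine$double.eps) return(NA_real_)
    (po - pe) / (1 - pe)
  }
  two <- function(scheme) {
    crob1 <- switch(scheme,
                    main = joint[, "low"],
                    sens1 = joint[, "low"] + joint[, "unclear"],
                    sens2 = joint[, "low"])
    crob0 <- switch(scheme,
                    main = joint[, "unclear"] + joint[, "high"],
                    sens1 = joint[, "high"],
                    sens2 = joint[, "high"])
    p <- cbind(crob1, crob0)
    p / sum(p)
  }
  list(joint = joint, prevalence = pbar,
       kappa = c(main = kap(two("main")), sens1 = kap(two("sens1")),
                 sens2 = kap(two("sens2"))))
}

#' Add cross-review duplicate ratings to a synthetic dataset
#'
#' Selects a fraction of trials, gives each a second review id, and
#' re-rates every assessed CROB item independently: with probability
#' `duplicate_error` the second review's rating moves to one of the other
#' two categories (uniformly). PEDro ratings are trial-level (downloaded
#' from one database) and are copied unchanged. Deterministic given
#' `config$seed`.
#'
#' @param records A `trial_ratings` table.
#' @param config A [synthetic_config()]; uses `duplicate_fraction`,
#'   `duplicate_error` and `seed`.
#' @return A `trial_ratings` table with the duplicate rows appended.
#' @export
inject_duplicates <- function(records, config) {
  stopifnot(inherits(records, "trial_ratings"),
            inherits(config, "synthetic_config"))
  m <- floor(config$duplicate_fraction * nrow(records))
  if (m < 1) {
    if (config$duplicate_fraction > 0)
      warning("duplicate_fraction too small for dataset size; no duplicates added")
    return(records)
  }
  lev <- c("low", "unclear", "high")
  with_local_seed(config$seed + 1L, {
    pick <- sort(sample.int(nrow(records), m))
    dup <- as.data.frame(records[pick, , drop = FALSE])
    dup$review_id <- paste0("dup_", dup$review_id)
    for (it in crob_items()$item) {
      v <- dup[[it]]
      assessed <- v != "not_assessed"
      flip <- assessed & stats::runif(nrow(dup)) < config$duplicate_error
      if (any(flip))
        dup[[it]][flip] <- vapply(v[flip], function(r)
          sample(setdiff(lev, r), 1L), character(1))
    }
    out <- rbind(as.data.frame(records)[, names(dup)], dup)
    out$occurrence <- NULL
    as_trial_ratings(out)
  })
}
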