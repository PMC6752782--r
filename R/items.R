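#' @keywords internal
"_PACKAGE"

# Canonical item keys used throughout. CROB items are the reporting variants
# reviews actually use; the 7 core bias domains sit behind them.

.crob_levels <- c("low", "unclear", "high", "not_assessed")

.crob_domains <- c("sequence", "allocation", "performance", "detection",
                   "attrition", "reporting", "other")

.crob_domain_map <- list(
  random_sequence_generation              = "sequence",
  allocation_concealment                  = "allocation",
  blinding_participants_personnel         = "performance",
  blinding_participants                   = "performance",
  blinding_personnel                      = "performance",
  blinding_outcome_assessment             = "detection",
  blinding_outcome_subjective             = "detection",
  blinding_outcome_objective              = "detection",
  blinding_participants_personnel_outcome = c("performance", "detection"),
  incomplete_outcome_data                 = "attrition",
  selective_reporting                     = "reporting",
  other_bias                              = "other"
)

.crob_labels <- c(
  random_sequence_generation              = "Random sequence generation",
  allocation_concealment                  = "Allocation concealment",
  blinding_participants_personnel         = "Blinding of participants and personnel",
  blinding_participants                   = "Blinding of participants",
  blinding_personnel                      = "Blinding of personnel",
  blinding_outcome_assessment             = "Blinding of outcome assessment",
  blinding_outcome_subjective             = "Blinding of outcome assessment (subjective outcomes)",
  blinding_outcome_objective              = "Blinding of outcome assessment (objective outcomes)",
  blinding_participants_personnel_outcome = "Blinding of participants, personnel and outcome assessment",
  incomplete_outcome_data                 = "Incomplete outcome data",
  selective_reporting                     = "Selective reporting",
  other_bias                              = "Other sources of bias"
)

.pedro_labels <- c(
  eligibility               = "Inclusion criteria and source",
  random_allocation         = "Random allocation",
  concealed_allocation      = "Concealed allocation",
  baseline_comparability    = "Baseline comparability",
  subject_blinding          = "Subject blinding",
  therapist_blinding        = "Therapist blinding",
  assessor_blinding         = "Assessor blinding",
  follow_up                 = "Completeness of follow up",
  intention_to_treat        = "Intention-to-treat analysis",
  between_group_comparisons = "Between-group statistical comparisons",
  point_measures            = "Point measures and variability"
)

#' Catalogue of Cochrane risk-of-bias item variants
#'
#' The Cochrane tool rates seven core bias domains, but published reviews
#' report the blinding domains under several variants (participants only,
#' personnel only, combined, subjective/objective outcomes, or a single
#' combined participants+personnel+outcome item). This catalogue lists the
#' twelve reporting variants and the core domain(s) each one covers.
#'
#' @return A data frame with columns `item` (canonical key), `label`
#'   (display name) and `domains` (comma-separated core domains the variant
#'   fills in the summary score).
#' @export
#' @examples
#' crob_items()
crob_items <- function() {
  data.frame(
    item = names(.crob_domain_map),
    label = unname(.crob_labels[names(.crob_domain_map)]),
    domains = vapply(.crob_domain_map, paste, "", collapse = ","),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Catalogue of PEDro scale items
#'
#' Eleven binary (yes/no) items; the first (inclusion criteria and source)
#' is recorded but excluded from the 0-10 total score.
#'
#' @return A data frame with columns `item`, `label` and `scored` (logical:
#'   counts toward the total score).
#' @export
pedro_items <- function() {
  data.frame(
    item = names(.pedro_labels),
    label = unname(.pedro_labels),
    scored = names(.pedro_labels) != "eligibility",
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Canonical item pairs evaluating similar constructs
#'
#' The six PEDro/CROB item pairs compared in the item-level agreement
#' analysis: randomization, allocation concealment, the three blinding
#' items, and completeness of follow up / incomplete outcome data.
#'
#' @return A data frame with columns `pedro` and `crob` (canonical keys).
#' @export
item_pairs <- function() {
  data.frame(
    pedro = c("random_allocation", "concealed_allocation", "subject_blinding",
              "therapist_blinding", "assessor_blinding", "follow_up"),
    crob = c("random_sequence_generation", "allocation_concealment",
             "blinding_participants", "blinding_personnel",
             "blinding_outcome_assessment", "incomplete_outcome_data"),
    stringsAsFactors = FALSE
  )
}

#' Catalogue of blinding-variant groupings
#'
#' Sensitivity analyses pool different reporting variants of the CROB
#' blinding items against the corresponding PEDro blinding item. Each
#' grouping is an ordered character vector of CROB variants; when a review
#' reports more than one variant for a trial, the first variant in the
#' grouping's order is used (single-construct variant first, then combined
#' variants).
#'
#' @return A named list with elements `subject_blinding`,
#'   `therapist_blinding` and `assessor_blinding`, each a named list of
#'   groupings (ordered character vectors of CROB item keys).
#' @export
blinding_groupings <- function() {
  list(
    subject_blinding = list(
      participants_only = "blinding_participants",
      participants_all_variants = c("blinding_participants",
                                    "blinding_participants_personnel",
                                    "blinding_participants_personnel_outcome"),
      participants_personnel_combined = "blinding_participants_personnel",
      triple_combined = "blinding_participants_personnel_outcome"
    ),
    therapist_blinding = list(
      personnel_only = "blinding_personnel",
      personnel_all_variants = c("blinding_personnel",
                                 "blinding_participants_personnel",
                                 "blinding_participants_personnel_outcome"),
      participants_personnel_combined = "blinding_participants_personnel",
      triple_combined = "blinding_participants_personnel_outcome"
    ),
    assessor_blinding = list(
      outcome_assessment_only = "blinding_outcome_assessment",
      outcome_plus_triple = c("blinding_outcome_assessment",
                              "blinding_participants_personnel_outcome"),
      triple_combined = "blinding_participants_personnel_outcome",
      outcome_plus_subjective_plus_triple = c("blinding_outcome_assessment",
                                              "blinding_outcome_subjective",
                                              "blinding_participants_personnel_outcome"),
      subjective_only = "blinding_outcome_subjective",
      outcome_plus_objective_plus_triple = c("blinding_outcome_assessment",
                                             "blinding_outcome_objective",
                                             "blinding_participants_personnel_outcome"),
      objective_only = "blinding_outcome_objective"
    )
  )
}

# Evaluate an expression under a fixed seed without disturbing the caller's
# RNG stream.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# round-half-up to integer (display convention for percentage cells)
round_half_up <- function(x) floor(x + 0.5)
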