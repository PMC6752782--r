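#' Published reference counts and agreement estimates
#'
#' Item-level rating counts and agreement estimates reported for a large
#' meta-epidemiological sample of 1442 physical-therapy randomized trials
#' drawn from 108 Cochrane systematic reviews. Shipped as plain-text
#' tables and used to validate the transformation arithmetic and the 2x2
#' reconstruction utility against published values.
#'
#' Available tables:
#' \describe{
#'   \item{crob_counts}{Per CROB item variant, the number of trials rated
#'     low/unclear/high.}
#'   \item{transformed_counts}{The published dichotomized counts and
#'     integer percentages per recoding scheme.}
#'   \item{pedro_counts}{Per PEDro item, the number of trials rated yes
#'     (of 1442).}
#'   \item{item_agreement}{Per item pair and scheme: n, percent exact
#'     agreement, kappa and its published 95% CI.}
#'   \item{between_review}{Between-review reliability per CROB item over
#'     the duplicate-rated trials (n = 74).}
#' }
#'
#' @param which One of the table names above.
#' @return A data frame.
#' @export
#' @examples
#' reference_table("item_agreement")
reference_table <- function(which = c("crob_counts", "transformed_counts",
                                      "pedro_counts", "item_agreement",
                                      "between_review")) {
  which <- match.arg(which)
  f <- system.file("extdata", paste0("reference_", which, ".csv"),
                   package = "robagree", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}
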