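#' OxCAP-MH instrument specification
#'
#' Returns the fixed structure of the OxCAP-MH capability wellbeing
#' questionnaire: 16 items, each rated on a 1-5 level scale, with the set of
#' reverse-coded items (those for which answer level 1 denotes the highest
#' capability). The raw equal-weight total score ranges from 16 (all items at
#' the lowest capability) to 80 (16 items x 5 levels); the score range used
#' for standardisation is therefore 64.
#'
#' @return An object of class `oxcap_spec`: a list with elements `items`
#'   (data frame with `item_number`, `question_number`, `label`, `reversed`),
#'   `n_items`, `n_levels`, `level_factors` (the multiplication factors
#'   0, 0.25, 0.5, 0.75, 1 applied from worst to best capability level),
#'   `min_raw_score`, `max_raw_score` and `score_range`.
#' @export
#' @examples
#' spec <- oxcap_mh_spec()
#' spec$items$label[spec$items$reversed]
oxcap_mh_spec <- function() {
  items <- read.csv(system.file("extdata", "oxcap_mh_items.csv",
                                package = "capbws"),
                    stringsAsFactors = FALSE)
  items$reversed <- as.logical(items$reversed)
  structure(
    list(items = items,
         n_items = nrow(items),
         n_levels = 5L,
         level_factors = c(0, 0.25, 0.5, 0.75, 1),
         min_raw_score = nrow(items),
         max_raw_score = nrow(items) * 5L,
         score_range = nrow(items) * 5L - nrow(items)),
    class = "oxcap_spec")
}

#' @export
print.oxcap_spec <- function(x, ...) {
  cat("OxCAP-MH instrument:", x$n_items, "items x", x$n_levels, "levels\n")
  cat("Reverse-coded items:",
      paste(x$items$item_number[x$items$reversed], collapse = ", "), "\n")
  cat("Raw score range:", x$min_raw_score, "-", x$max_raw_score, "\n")
  invisible(x)
}

#' Reference mean relative importance scores
#'
#' Full-cohort mean relative importance scores (RIS) and standard deviations
#' for the 16 OxCAP-MH items from the Austrian German-language valuation
#' study (158 participants across psychiatric-patient, healthcare-expert and
#' primary-care cohorts). The 16 printed means sum to 100.01 due to
#' rounding. These values are the published inputs to the indicative
#' preference weight set and are used for validation; they are not computed
#' by this package.
#'
#' @return Data frame with `item_number`, `question_number`, `label`,
#'   `ris_mean`, `ris_sd`.
#' @seealso [build_weight_set()], [reference_weights()]
#' @export
reference_ris <- function() {
  spec <- oxcap_mh_spec()
  ris <- read.csv(system.file("extdata", "reference_ris.csv",
                              package = "capbws"))
  merge(spec$items[, c("item_number", "question_number", "label")],
        ris, by = "item_number")
}

#' Published indicative preference weight set
#'
#' The published 16 x 5 indicative preference weight table for the German
#' OxCAP-MH (weights at 4-decimal precision, anchored 0 = no capability to
#' 1 = full capability), used as the reference when validating
#' [build_weight_set()].
#'
#' @return A 16 x 5 numeric matrix; rows are items, columns answer levels
#'   1 to 5.
#' @export
reference_weights <- function() {
  w <- read.csv(system.file("extdata", "reference_weights.csv",
                            package = "capbws"))
  m <- as.matrix(w[, paste0("level_", 1:5)])
  dimnames(m) <- list(item = w$item_number, level = 1:5)
  m
}
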