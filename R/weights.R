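#' Build the anchored 0-1 preference weight set
#'
#' Converts mean relative importance scores into a 16 x 5 matrix of level
#' weights: item `k`'s weight at its best capability level is
#' `ris_mean[k] / 100`, its worst level carries weight 0, and the three
#' intermediate levels carry the multiplication factors 0.25, 0.5 and 0.75
#' of the item weight (levels are assumed to contribute proportionately).
#' For non-reversed items answer level 1 is the worst capability (factor 0)
#' and level 5 the best (factor 1); for reverse-coded items the orientation
#' is flipped. When all item means sum to 100 the weight of the full
#' capability state is 1, anchoring the scale at 0 (no capability) to 1
#' (full capability).
#'
#' Weights are kept at full precision internally; rounding to 4 decimals
#' happens only on export ([write_weight_set()]) or via `round()` on the
#' matrix.
#'
#' @param ris_mean Numeric vector of 16 non-negative mean RIS values.
#' @param spec An [oxcap_mh_spec()] instrument specification.
#' @return An object of class `bws_weight_set`: list with `weights`
#'   (items x levels matrix, full precision), `ris_mean`, `spec`.
#' @export
#' @examples
#' ws <- build_weight_set(reference_ris()$ris_mean)
#' round(ws$weights[14, ], 4)  # Self-determination, reverse coded
build_weight_set <- function(ris_mean, spec = oxcap_mh_spec()) {
  if (length(ris_mean) != spec$n_items)
    stop("`ris_mean` must have length ", spec$n_items)
  if (any(ris_mean < 0)) stop("`ris_mean` must be non-negative")
  fac <- spec$level_factors
  W <- t(vapply(seq_len(spec$n_items), function(k) {
    f <- if (spec$items$reversed[k]) rev(fac) else fac
    ris_mean[k] / 100 * f
  }, numeric(spec$n_levels)))
  dimnames(W) <- list(item = spec$items$item_number,
                      level = seq_len(spec$n_levels))
  structure(list(weights = W, ris_mean = ris_mean, spec = spec),
            class = "bws_weight_set")
}

#' @export
print.bws_weight_set <- function(x, digits = 4, ...) {
  cat("OxCAP-MH preference weight set (", nrow(x$weights), " items x ",
      ncol(x$weights), " levels, anchored 0-1)\n", sep = "")
  print(round(x$weights, digits))
  invisible(x)
}

check_levels <- function(levels, spec) {
  if (length(levels) != spec$n_items)
    stop("`levels` must have length ", spec$n_items)
  bad <- which(!(levels %in% seq_len(spec$n_levels)))
  if (length(bad))
    stop("answer level out of range 1..", spec$n_levels, " for item(s): ",
         paste(bad, collapse = ", "))
  invisible(levels)
}

#' Preference-weighted score of a capability state
#'
#' Scores a capability state (one answer level per item) under a preference
#' weight set by summing the per-item level weights. The all-worst state
#' scores 0 and the all-best state scores `sum(ris_mean) / 100` (1 when the
#' mean scores sum to exactly 100). The score is monotone non-decreasing in
#' each item's capability.
#'
#' @param levels Integer vector of answer levels (1 to 5 per item, in the
#'   questionnaire's coding; reverse-coded items need no pre-processing, the
#'   weight set already carries their orientation).
#' @param weight_set A [`bws_weight_set`][build_weight_set()] object.
#' @return Scalar preference-weighted score.
#' @export
score_state <- function(levels, weight_set) {
  stopifnot(inherits(weight_set, "bws_weight_set"))
  spec <- weight_set$spec
  check_levels(levels, spec)
  sum(weight_set$weights[cbind(seq_len(spec$n_items), levels)])
}

#' Equal-weight standardised OxCAP-MH score
#'
#' The conventional scoring of the instrument: answer levels are oriented so
#' that higher means better capability (reverse-coded items are flipped),
#' summed to the raw total (16 to 80), and standardised to 0-100 as
#' `100 * (raw - min) / range` with minimum 16 and range 64.
#'
#' @param levels Integer vector of answer levels (1 to 5 per item, raw
#'   questionnaire coding).
#' @param spec An [oxcap_mh_spec()] object.
#' @return Scalar score between 0 and 100.
#' @export
#' @examples
#' equal_weight_score(rep(3, 16))  # mid levels -> 50
equal_weight_score <- function(levels, spec = oxcap_mh_spec()) {
  check_levels(levels, spec)
  oriented <- ifelse(spec$items$reversed, spec$n_levels + 1L - levels,
                     levels)
  raw <- sum(oriented)
  100 * (raw - spec$min_raw_score) / spec$score_range
}

#' Write a preference weight set to CSV
#'
#' Exports the weight table in the published layout: one row per item with
#' `item_number`, `question_number`, `label` and the five level weights
#' rounded to `digits` decimals.
#'
#' @param weight_set A [`bws_weight_set`][build_weight_set()] object.
#' @param path Output CSV path.
#' @param digits Decimals for the exported weights.
#' @return The path, invisibly.
#' @export
write_weight_set <- function(weight_set, path, digits = 4) {
  stopifnot(inherits(weight_set, "bws_weight_set"))
  spec <- weight_set$spec
  df <- data.frame(item_number = spec$items$item_number,
                   question_number = spec$items$question_number,
                   label = spec$items$label)
  w <- round(weight_set$weights, digits)
  for (l in seq_len(spec$n_levels))
    df[[paste0("answer_level_", l)]] <- w[, l]
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a preference weight set from CSV
#'
#' Counterpart of [write_weight_set()]; the item means are reconstructed
#' from each row's maximum weight.
#'
#' @param path CSV path with columns `item_number` and `answer_level_1..5`.
#' @param spec An [oxcap_mh_spec()] object.
#' @return A [`bws_weight_set`][build_weight_set()] object.
#' @export
read_weight_set <- function(path, spec = oxcap_mh_spec()) {
  df <- read.csv(path)
  need <- c("item_number", paste0("answer_level_", seq_len(spec$n_levels)))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("weight set file is missing column(s): ",
         paste(miss, collapse = ", "))
  df <- df[order(df$item_number), , drop = FALSE]
  W <- as.matrix(df[, paste0("answer_level_", seq_len(spec$n_levels))])
  dimnames(W) <- list(item = df$item_number, level = seq_len(spec$n_levels))
  structure(list(weights = W, ris_mean = 100 * apply(W, 1L, max),
                 spec = spec),
            class = "bws_weight_set")
}

#' Number of distinct capability states
#'
#' @param spec An [oxcap_mh_spec()] object.
#' @return `n_levels ^ n_items` as a double (152,587,890,625 for the
#'   OxCAP-MH's 5^16).
#' @export
n_capability_states <- function(spec = oxcap_mh_spec()) {
  as.numeric(spec$n_levels)^spec$n_items
}
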