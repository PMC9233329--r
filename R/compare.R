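#' Rank items by descending importance
#'
#' Rank 1 is the largest value (most important item); ties are broken by
#' item index, so equal values rank in item order.
#'
#' @param x Numeric vector of per-item values (e.g. mean RIS).
#' @return Integer vector of ranks, a permutation of `seq_along(x)`.
#' @export
#' @examples
#' rank_items(c(2, 5, 5, 1))  # 3 1 2 4
rank_items <- function(x) {
  if (any(!is.finite(x))) stop("`x` must be finite")
  ord <- order(-x, seq_along(x))
  r <- integer(length(x))
  r[ord] <- seq_along(x)
  r
}

#' Kruskal-Wallis tests of item importance across cohorts
#'
#' For each item, tests whether the distribution of individual relative
#' importance scores differs across cohorts by the Kruskal-Wallis
#' equality-of-populations rank test (midranks with the standard tie
#' correction; p-value from the chi-square approximation with
#' `groups - 1` degrees of freedom). When all values of an item are
#' identical across every cohort, the statistic is 0 and the p-value 1 (the
#' tie-corrected statistic is otherwise undefined there). No multiplicity
#' correction is applied; all per-item p-values are reported.
#'
#' @param ris_individual Respondents x items matrix of individual scores.
#' @param cohorts Cohort label per respondent (length `nrow`).
#' @return Data frame with `item`, `H`, `p`. A warning is attached when any
#'   cohort has fewer than 2 respondents.
#' @export
kruskal_wallis_by_cohort <- function(ris_individual, cohorts) {
  ris_individual <- as.matrix(ris_individual)
  cohorts <- as.factor(cohorts)
  if (nlevels(cohorts) < 2L) stop("need at least 2 cohorts")
  if (length(cohorts) != nrow(ris_individual))
    stop("`cohorts` must have one label per respondent")
  small <- table(cohorts) < 2L
  if (any(small))
    warning("cohort(s) with fewer than 2 respondents: ",
            paste(names(small)[small], collapse = ", "))
  res <- t(apply(ris_individual, 2L, function(x) {
    if (length(unique(x)) == 1L) return(c(H = 0, p = 1))
    kt <- kruskal.test(x, cohorts)
    c(H = unname(kt$statistic), p = kt$p.value)
  }))
  data.frame(item = seq_len(ncol(ris_individual)), H = res[, "H"],
             p = res[, "p"], row.names = NULL)
}

#' Cohort rank table
#'
#' Per-cohort mean relative importance scores and rank orders (1 = most
#' important), combined with the across-cohort Kruskal-Wallis test per item.
#'
#' @inheritParams kruskal_wallis_by_cohort
#' @return Data frame in long format: `item`, `cohort`, `mean_ris`, `rank`,
#'   and the item-level `H` and `p` repeated within item.
#' @export
cohort_rank_table <- function(ris_individual, cohorts) {
  ris_individual <- as.matrix(ris_individual)
  cohorts <- as.factor(cohorts)
  kw <- kruskal_wallis_by_cohort(ris_individual, cohorts)
  out <- do.call(rbind, lapply(levels(cohorts), function(g) {
    m <- colMeans(ris_individual[cohorts == g, , drop = FALSE])
    data.frame(item = seq_along(m), cohort = g, mean_ris = m,
               rank = rank_items(m), row.names = NULL)
  }))
  merge(out, kw, by = "item")
}

#' Pearson correlation matrix of item importance scores
#'
#' Pairwise product-moment correlations between items over respondents'
#' individual relative importance scores. Items with zero variance yield
#' undefined (NA) off-diagonal entries and a named warning rather than
#' silently zeroed values; the diagonal is always 1.
#'
#' @param ris_individual Respondents x items matrix; at least 3 rows.
#' @return Symmetric items x items matrix with unit diagonal.
#' @export
pearson_matrix <- function(ris_individual) {
  x <- as.matrix(ris_individual)
  if (nrow(x) < 3L) stop("need at least 3 respondents")
  sds <- apply(x, 2L, sd)
  constant <- sds == 0
  if (any(constant))
    warning("constant column(s), correlations undefined: ",
            paste(which(constant), collapse = ", "))
  cc <- suppressWarnings(cor(x))
  diag(cc) <- 1
  cc
}
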