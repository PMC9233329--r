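#' Covariate design matrix for the per-item regressions
#'
#' Builds the regression design used throughout: an indicator for male
#' (reference female), one indicator per non-reference cohort (reference is
#' the general-population / primary-care cohort), and an intercept, in the
#' column order male, cohort contrasts, constant.
#'
#' @param covariates Data frame with `respondent_id`, `cohort`, `gender`.
#' @param reference_cohort Cohort acting as the reference category.
#' @return Numeric matrix with rownames set to the respondent ids.
#' @export
regression_design <- function(covariates,
                              reference_cohort = "general population") {
  stopifnot(all(c("respondent_id", "cohort", "gender") %in%
                  names(covariates)))
  if (!reference_cohort %in% covariates$cohort)
    stop("reference cohort '", reference_cohort,
         "' not present in the covariates")
  others <- setdiff(unique(covariates$cohort), reference_cohort)
  X <- cbind(male = as.numeric(covariates$gender == "male"))
  for (g in others)
    X <- cbind(X, as.numeric(covariates$cohort == g))
  colnames(X) <- c("male",
                   paste0(gsub("[^a-z0-9]+", "_", tolower(others)),
                          "_vs_ref"))
  X <- cbind(X, constant = 1)
  rownames(X) <- covariates$respondent_id
  X
}

#' Per-item ordinary least squares regressions
#'
#' Regresses each item's individual relative importance score on the
#' covariate design of [regression_design()] (male vs female, cohort
#' contrasts against the general-population reference, intercept).
#'
#' @param ris_individual Respondents x items matrix, rows named by
#'   respondent id.
#' @param covariates Data frame with `respondent_id`, `cohort`, `gender`
#'   covering all rows of `ris_individual`.
#' @param reference_cohort Reference cohort label.
#' @return Items x coefficients matrix.
#' @export
fit_item_regressions <- function(ris_individual, covariates,
                                 reference_cohort = "general population") {
  Y <- as.matrix(ris_individual)
  covariates <- covariates[match(rownames(Y), covariates$respondent_id), ,
                           drop = FALSE]
  if (anyNA(covariates$respondent_id))
    stop("covariates missing for some respondents")
  X <- regression_design(covariates, reference_cohort)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    stop("regression design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- lm.fit(X, Y)
  coefs <- t(fit$coefficients)
  rownames(coefs) <- colnames(Y)
  coefs
}

#' Jackknife variance from leave-one-out replicates
#'
#' The robust variance of a coefficient is
#' `v = ((n - 1) / n) * sum_i (beta_loo_i - beta_hat)^2`, the sum running
#' over the `n` leave-one-participant-out re-estimates and `beta_hat` being
#' the full-sample coefficient.
#'
#' @param beta_loo Numeric vector (or matrix with one row per omitted
#'   participant) of leave-one-out estimates.
#' @param beta_hat Full-sample estimate (scalar, or vector matching the
#'   columns of `beta_loo`).
#' @return Variance(s) on the scale of the coefficients.
#' @export
jackknife_variance <- function(beta_loo, beta_hat) {
  if (is.null(dim(beta_loo))) beta_loo <- matrix(beta_loo, ncol = 1L)
  n <- nrow(beta_loo)
  dev <- sweep(beta_loo, 2L, beta_hat)
  drop((n - 1) / n * colSums(dev^2))
}

#' Jackknife robust regression over a full re-estimation pipeline
#'
#' Re-runs an arbitrary estimation pipeline once per participant, omitting
#' that participant, and derives robust variances for every regression
#' coefficient from the spread of the leave-one-out estimates around the
#' full-sample fit (see [jackknife_variance()]). Standard errors are the
#' square roots, t statistics are `beta_hat / se`, and two-sided p-values
#' come from a t-distribution with `n - J - 1` degrees of freedom, `J`
#' being the number of regression coefficients (4 for the default design:
#' male, two cohort contrasts, constant). The jackknife is deterministic
#' whenever the pipeline is.
#'
#' @param fitter Function of one argument: the id of the participant to
#'   omit, or `NULL` for the full sample. Must return an items x
#'   coefficients matrix. See [ols_fitter()] and [hb_fitter()].
#' @param ids Character vector of participant ids to omit in turn.
#' @return An object of class `bws_jackknife`: list with `beta_hat`,
#'   `beta_loo` (n x items x coefficients array), `v_hat`, `s_hat`,
#'   `t_stat`, `p_value`, `n`, `J`, `df`.
#' @export
jackknife_robust <- function(fitter, ids) {
  beta_hat <- fitter(NULL)
  n <- length(ids)
  J <- ncol(beta_hat)
  if (n < J + 2L)
    stop("need at least J + 2 = ", J + 2L, " participants, got ", n)
  beta_loo <- array(NA_real_,
                    c(n, nrow(beta_hat), J),
                    dimnames = list(ids, rownames(beta_hat),
                                    colnames(beta_hat)))
  for (i in seq_len(n))
    beta_loo[i, , ] <- fitter(ids[i])
  v_hat <- beta_hat
  for (k in seq_len(nrow(beta_hat)))
    v_hat[k, ] <- jackknife_variance(beta_loo[, k, ], beta_hat[k, ])
  s_hat <- sqrt(v_hat)
  t_stat <- ifelse(s_hat > 0, beta_hat / s_hat,
                   ifelse(beta_hat == 0, 0, Inf * sign(beta_hat)))
  df <- n - J - 1L
  p_value <- 2 * pt(abs(t_stat), df = df, lower.tail = FALSE)
  structure(
    list(beta_hat = beta_hat, beta_loo = beta_loo, v_hat = v_hat,
         s_hat = s_hat, t_stat = t_stat, p_value = p_value,
         n = n, J = J, df = df),
    class = "bws_jackknife")
}

#' @export
print.bws_jackknife <- function(x, ...) {
  cat("Jackknife robust regression:", nrow(x$beta_hat), "items,",
      x$J, "coefficients,", x$n, "leave-one-out replicates (df =",
      paste0(x$df, ")\n"))
  invisible(x)
}

#' Direct-regression fitter for the jackknife
#'
#' Returns a fitter for [jackknife_robust()] that regresses the supplied
#' individual relative importance scores directly on the covariates,
#' without re-estimating the choice model. This is the appropriate pipeline
#' when the utility estimates are treated as fixed data, and the reference
#' case against which the full hierarchical Bayes re-estimation pipeline
#' ([hb_fitter()]) is compared.
#'
#' @inheritParams fit_item_regressions
#' @return Function suitable as the `fitter` argument of
#'   [jackknife_robust()].
#' @export
ols_fitter <- function(ris_individual, covariates,
                       reference_cohort = "general population") {
  ris_individual <- as.matrix(ris_individual)
  force(covariates); force(reference_cohort)
  function(omit) {
    keep <- if (is.null(omit)) rep(TRUE, nrow(ris_individual))
            else rownames(ris_individual) != omit
    fit_item_regressions(ris_individual[keep, , drop = FALSE],
                         covariates[covariates$respondent_id %in%
                                      rownames(ris_individual)[keep], ,
                                    drop = FALSE],
                         reference_cohort)
  }
}

#' Full-pipeline fitter: hierarchical Bayes re-estimation per replicate
#'
#' Returns a fitter for [jackknife_robust()] that, for each omitted
#' participant, re-runs the hierarchical Bayes estimation on the remaining
#' responses (same MCMC settings and seed for every replicate), recomputes
#' the relative importance scores, and re-fits all per-item regressions.
#' The inclusion set is frozen from the full-sample fit: the root-likelihood
#' exclusion rule is applied once to the full sample, and replicates differ
#' from it only by the omitted participant, so sample composition never
#' depends on replicate-specific fit statistics. A reduced MCMC profile for
#' the replicates is standard practice given the cost of `n` refits; the
#' profile used is recorded in the attribute `"mcmc_profile"` of the
#' returned fitter.
#'
#' @param responses A [`bws_responses`][simulate_responses()] data frame.
#' @param design The matching [`bws_design`][generate_design()].
#' @param config [mcmc_config()] profile used for every refit.
#' @param threshold Root-likelihood exclusion threshold applied to the
#'   full-sample fit.
#' @param reference_cohort Reference cohort label for the regressions.
#' @return Function suitable as the `fitter` argument of
#'   [jackknife_robust()]; its attribute `"included"` holds the frozen
#'   inclusion set.
#' @export
hb_fitter <- function(responses, design, config = mcmc_config(),
                      threshold = 0.2,
                      reference_cohort = "general population") {
  full <- fit_hb(responses, design, config)
  included <- filter_inconsistent(full, threshold)$included
  covariates <- full$covariates
  f <- function(omit) {
    keep <- setdiff(included, omit)
    sub <- responses[responses$respondent_id %in% keep, , drop = FALSE]
    post <- fit_hb(sub, design, config)
    ris <- compute_ris(post, set_size = design$set_size)
    fit_item_regressions(ris$ris_individual,
                         covariates[covariates$respondent_id %in% keep, ,
                                    drop = FALSE],
                         reference_cohort)
  }
  attr(f, "included") <- included
  attr(f, "mcmc_profile") <- config
  f
}

#' Annotated coefficient table with robust standard errors
#'
#' Combines the per-item mean (SD) of the relative importance scores with
#' the jackknife regression coefficients, robust standard errors, t
#' statistics, p-values and significance stars (`*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001; no multiplicity correction).
#'
#' @param result A [`bws_jackknife`][jackknife_robust()] object.
#' @param ris A [`bws_ris`][compute_ris()] object (for the mean/SD columns);
#'   optional.
#' @param labels Optional item labels.
#' @param alpha Unused except for documentation of the convention; stars
#'   are always drawn at 0.05 / 0.01 / 0.001.
#' @return Data frame with one row per item and, per coefficient, columns
#'   `<name>_est`, `<name>_se`, `<name>_t`, `<name>_p`, `<name>_stars`.
#' @export
significance_table <- function(result, ris = NULL, labels = NULL,
                               alpha = 0.05) {
  stopifnot(inherits(result, "bws_jackknife"))
  n_items <- nrow(result$beta_hat)
  out <- data.frame(item = seq_len(n_items))
  if (!is.null(labels)) out$label <- labels
  if (!is.null(ris)) {
    out$ris_mean <- ris$ris_mean
    out$ris_sd <- ris$ris_sd
  }
  for (j in colnames(result$beta_hat)) {
    out[[paste0(j, "_est")]] <- result$beta_hat[, j]
    out[[paste0(j, "_se")]] <- result$s_hat[, j]
    out[[paste0(j, "_t")]] <- result$t_stat[, j]
    out[[paste0(j, "_p")]] <- result$p_value[, j]
    out[[paste0(j, "_stars")]] <- significance_stars(result$p_value[, j])
  }
  out
}

#' Significance star annotation
#'
#' @param p Vector of p-values.
#' @return Character vector: `***` for p < 0.001, `**` for p < 0.01,
#'   `*` for p < 0.05, empty otherwise.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}
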