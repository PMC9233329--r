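#' MCMC settings for hierarchical Bayes estimation
#'
#' @param n_burn Burn-in iterations (adaptive proposal tuning happens here).
#' @param n_keep Retained post-burn-in iterations; posterior means of the
#'   individual utilities average over all of them.
#' @param thinning Interval at which population-level draws (`mu`, `Sigma`)
#'   are stored.
#' @param prior_variance Prior variance of each component of the population
#'   mean (`mu ~ N(0, prior_variance * I)`).
#' @param df_prior Degrees of freedom of the inverse-Wishart prior on the
#'   population covariance (identity scale); defaults to `n_items + 2`.
#' @param proposal_scale Initial random-walk Metropolis step size, adapted
#'   towards 30 percent acceptance during burn-in.
#' @param seed Integer seed.
#' @return An object of class `bws_mcmc_config`.
#' @export
mcmc_config <- function(n_burn = 10000L, n_keep = 10000L, thinning = 10L,
                        prior_variance = 100, df_prior = NULL,
                        proposal_scale = 0.3, seed = 1L) {
  stopifnot(n_burn >= 1L, n_keep >= 1L, thinning >= 1L, proposal_scale > 0,
            prior_variance > 0)
  structure(list(n_burn = as.integer(n_burn), n_keep = as.integer(n_keep),
                 thinning = as.integer(thinning),
                 prior_variance = prior_variance, df_prior = df_prior,
                 proposal_scale = proposal_scale, seed = as.integer(seed)),
            class = "bws_mcmc_config")
}

# Resolve responses against the design into flat arrays for the compiled
# likelihood: one row per (respondent, task) with shown item ids, best and
# worst positions. Validates membership, distinctness and completeness.
prepare_choice_data <- function(responses, design, drop_incomplete = TRUE) {
  stopifnot(inherits(design, "bws_design"))
  req <- c("respondent_id", "version", "task", "best_item", "worst_item")
  miss <- setdiff(req, names(responses))
  if (length(miss))
    stop("responses are missing column(s): ", paste(miss, collapse = ", "))
  responses <- as.data.frame(responses)

  complete <- tapply(responses$task, responses$respondent_id, function(t)
    length(unique(t)) == design$n_tasks)
  if (any(!complete)) {
    bad <- names(complete)[!complete]
    if (!drop_incomplete)
      stop("incomplete respondent(s): ", paste(bad, collapse = ", "))
    warning("dropping ", length(bad), " incomplete respondent(s): ",
            paste(bad, collapse = ", "))
    responses <- responses[!responses$respondent_id %in% bad, , drop = FALSE]
  }
  if (nrow(responses) == 0L) stop("no complete respondents")

  ids <- unique(responses$respondent_id)
  resp_idx <- match(responses$respondent_id, ids)
  if (any(responses$version < 1L | responses$version > design$n_versions))
    stop("response references unknown questionnaire version")
  if (any(responses$task < 1L | responses$task > design$n_tasks))
    stop("response references unknown task number")

  k <- design$set_size
  shown <- matrix(0L, nrow(responses), k)
  for (v in seq_len(design$n_versions)) {
    rows <- which(responses$version == v)
    if (length(rows))
      shown[rows, ] <- design$versions[[v]][responses$task[rows], ,
                                            drop = FALSE]
  }
  best_pos <- worst_pos <- integer(nrow(responses))
  for (r in seq_len(nrow(responses))) {
    bp <- match(responses$best_item[r], shown[r, ])
    wp <- match(responses$worst_item[r], shown[r, ])
    if (is.na(bp))
      stop("respondent ", responses$respondent_id[r], ", task ",
           responses$task[r], ": best item ", responses$best_item[r],
           " was not shown in that task")
    if (is.na(wp))
      stop("respondent ", responses$respondent_id[r], ", task ",
           responses$task[r], ": worst item ", responses$worst_item[r],
           " was not shown in that task")
    if (bp == wp)
      stop("respondent ", responses$respondent_id[r], ", task ",
           responses$task[r], ": best and worst picks coincide")
    best_pos[r] <- bp; worst_pos[r] <- wp
  }
  cov_cols <- intersect(c("respondent_id", "cohort", "gender", "version"),
                        names(responses))
  covariates <- unique(responses[, cov_cols, drop = FALSE])
  rownames(covariates) <- NULL
  list(ids = ids, shown = shown, best_pos = best_pos, worst_pos = worst_pos,
       resp_idx = resp_idx, covariates = covariates,
       n_tasks = design$n_tasks, set_size = k, n_items = design$n_items)
}

# sum-zero effects coding: beta (n_items) = Z %*% theta (n_items - 1)
effects_code_matrix <- function(n_items) {
  rbind(diag(n_items - 1L), -1)
}

#' Fit the hierarchical Bayes best-worst choice model
#'
#' Estimates individual item utilities from best-worst choices under a
#' two-level model: each respondent's utility vector (sum-zero effects
#' coding, `n_items - 1` free dimensions) is drawn from a population
#' multivariate normal with mean `mu` and covariance `Sigma`. The sampler
#' alternates conjugate Gibbs updates of `(mu, Sigma)`
#' (normal / inverse-Wishart) with per-respondent random-walk Metropolis
#' updates of the utilities against the sequential best-then-worst
#' multinomial logit likelihood (best pick from the shown set with
#' probabilities proportional to `exp(beta)`, worst pick from the remaining
#' items proportional to `exp(-beta)`). Proposal step sizes are adapted
#' towards 30 percent acceptance during burn-in and then frozen. The run is
#' deterministic for a fixed `config$seed`.
#'
#' Respondents with incomplete task sets are listed and dropped before
#' fitting. Each respondent's root likelihood (RLH, the geometric mean of
#' the modelled probabilities of their `2 * n_tasks` observed picks) is
#' averaged over the kept draws and returned as the individual fit
#' statistic used by [filter_inconsistent()]. For a respondent answering at
#' chance this statistic concentrates around the chance level (1/sqrt(30)
#' for 6-item tasks), mostly but not always below the 0.2 exclusion
#' threshold, while consistent respondents sit well above it.
#'
#' @param responses A [`bws_responses`][simulate_responses()] data frame (or
#'   one read by [read_responses()]).
#' @param design The [`bws_design`][generate_design()] the responses refer
#'   to.
#' @param config A [mcmc_config()] object.
#' @return An object of class `bws_posterior`: list with `beta_mean`
#'   (respondents x items posterior means, each row summing to zero),
#'   `mu_draws` (thinned population-mean draws mapped to the item scale),
#'   `sigma_draws` (thinned covariance draws in the effects-coded space),
#'   `mu_mean`, `mu_sd`, `rlh`, `acceptance_rate`, `ids`, `covariates`,
#'   `n_tasks`, `set_size`, `config`.
#' @export
fit_hb <- function(responses, design, config = mcmc_config()) {
  stopifnot(inherits(config, "bws_mcmc_config"))
  prep <- prepare_choice_data(responses, design)
  n <- length(prep$ids)
  K <- prep$n_items
  d <- K - 1L
  Z <- effects_code_matrix(K)
  df_prior <- if (is.null(config$df_prior)) K + 2L else config$df_prior

  set.seed(config$seed)
  Theta <- matrix(0, n, d)
  mu <- rep(0, d)
  Sinv <- diag(d)
  step <- rep(config$proposal_scale, n)
  ll_cur <- cpp_seq_bw_loglik(tcrossprod(Theta, Z), prep$shown,
                              prep$best_pos, prep$worst_pos, prep$resp_idx)

  n_iter <- config$n_burn + config$n_keep
  keep_every <- config$thinning
  n_stored <- config$n_keep %/% keep_every
  mu_draws <- matrix(NA_real_, n_stored, K)
  sigma_draws <- array(NA_real_, c(d, d, n_stored))
  beta_sum <- matrix(0, n, K)
  rlh_sum <- numeric(n)
  n_tasks_fit <- prep$n_tasks
  acc_post <- numeric(n)
  acc_win <- numeric(n)
  win <- 50L
  stored <- 0L

  for (iter in seq_len(n_iter)) {
    ## Metropolis update of all respondents (vectorised over respondents)
    A <- chol(Sinv)                       # Sinv = A'A
    Prop <- Theta + step * matrix(rnorm(n * d), n, d)
    ll_prop <- cpp_seq_bw_loglik(tcrossprod(Prop, Z), prep$shown,
                                 prep$best_pos, prep$worst_pos,
                                 prep$resp_idx)
    if (any(!is.finite(ll_cur)))
      stop("non-finite likelihood for respondent(s) ",
           paste(prep$ids[!is.finite(ll_cur)], collapse = ", "))
    dev_cur <- sweep(Theta, 2L, mu)
    dev_prop <- sweep(Prop, 2L, mu)
    q_cur <- rowSums((dev_cur %*% t(A))^2)
    q_prop <- rowSums((dev_prop %*% t(A))^2)
    log_acc <- (ll_prop - 0.5 * q_prop) - (ll_cur - 0.5 * q_cur)
    accept <- log(runif(n)) < log_acc
    if (any(accept)) {
      Theta[accept, ] <- Prop[accept, , drop = FALSE]
      ll_cur[accept] <- ll_prop[accept]
    }
    acc_win <- acc_win + accept

    if (iter <= config$n_burn) {
      if (iter %% win == 0L) {
        step <- step * exp(acc_win / win - 0.3)
        step <- pmin(pmax(step, 0.01), 5)
        acc_win[] <- 0
      }
    } else {
      acc_post <- acc_post + accept
    }

    ## Gibbs update of mu
    Prec <- n * Sinv + diag(1 / config$prior_variance, d)
    ch <- chol(Prec)
    b <- Sinv %*% colSums(Theta)
    m <- backsolve(ch, forwardsolve(t(ch), b))
    mu <- drop(m + backsolve(ch, rnorm(d)))

    ## Gibbs update of Sigma (draw the precision from its Wishart)
    S <- crossprod(sweep(Theta, 2L, mu)) + diag(d)
    Sinv_scale <- chol2inv(chol(S))
    Sinv <- rWishart(1L, df_prior + n, Sinv_scale)[, , 1L]

    if (iter > config$n_burn) {
      beta_sum <- beta_sum + tcrossprod(Theta, Z)
      rlh_sum <- rlh_sum + exp(ll_cur / (2 * n_tasks_fit))
      if ((iter - config$n_burn) %% keep_every == 0L && stored < n_stored) {
        stored <- stored + 1L
        mu_draws[stored, ] <- drop(Z %*% mu)
        sigma_draws[, , stored] <- chol2inv(chol(Sinv))
      }
    }
  }

  beta_mean <- beta_sum / config$n_keep
  rownames(beta_mean) <- prep$ids
  colnames(beta_mean) <- seq_len(K)
  # individual fit statistic: RLH averaged over the kept draws. For a
  # respondent answering at chance the posterior stays close to the
  # population distribution, the draws wander, and the averaged fit falls
  # below the chance level -- which is what makes the 0.2 exclusion rule
  # discriminate. (The point-evaluated alternative at the posterior mean is
  # available through compute_rlh().)
  rlh <- rlh_sum / config$n_keep
  names(rlh) <- prep$ids

  structure(
    list(beta_mean = beta_mean,
         mu_draws = mu_draws[seq_len(stored), , drop = FALSE],
         sigma_draws = sigma_draws[, , seq_len(stored), drop = FALSE],
         mu_mean = colMeans(mu_draws[seq_len(stored), , drop = FALSE]),
         mu_sd = apply(mu_draws[seq_len(stored), , drop = FALSE], 2L, sd),
         rlh = rlh,
         acceptance_rate = setNames(acc_post / config$n_keep, prep$ids),
         ids = prep$ids, covariates = prep$covariates,
         n_tasks = prep$n_tasks, set_size = prep$set_size,
         n_items = K, config = config),
    class = "bws_posterior")
}

#' @export
print.bws_posterior <- function(x, ...) {
  cat("Hierarchical Bayes best-worst posterior:", length(x$ids),
      "respondents,", x$n_items, "items\n")
  cat("Burn-in", x$config$n_burn, "/ kept", x$config$n_keep,
      "iterations; mean Metropolis acceptance",
      sprintf("%.2f", mean(x$acceptance_rate)), "\n")
  cat("RLH range:", sprintf("%.3f - %.3f", min(x$rlh), max(x$rlh)), "\n")
  invisible(x)
}

#' Root likelihood of one respondent's choices
#'
#' The root likelihood (RLH) is the geometric mean of the modelled choice
#' probabilities of a respondent's `2 * n_tasks` observed picks (one best
#' and one worst per task) under the sequential best-worst multinomial logit
#' at the supplied utilities. It lies in (0, 1]; for tasks showing 6 items a
#' purely random responder has expected probabilities 1/6 (best) and 1/5
#' (worst), giving the chance level `sqrt(1/30) ~ 0.1826`. Computation is in
#' the log domain, so small probabilities never underflow to an exact zero.
#'
#' @param beta Utility vector of length `design$n_items`.
#' @param responses Response rows for a single respondent.
#' @param design The [`bws_design`][generate_design()] used.
#' @return The RLH, a scalar in (0, 1].
#' @export
#' @examples
#' d <- generate_design(6, 6, 2, n_iterations = 1, seed = 1)
#' r <- data.frame(respondent_id = "a", version = 1, task = 1:2,
#'                 best_item = c(1, 2), worst_item = c(3, 4))
#' compute_rlh(rep(0, 6), r, d)  # 1/sqrt(30)
compute_rlh <- function(beta, responses, design) {
  if (length(unique(responses$respondent_id)) != 1L)
    stop("`responses` must belong to a single respondent")
  prep <- prepare_choice_data(responses, design, drop_incomplete = FALSE)
  if (length(beta) != design$n_items)
    stop("`beta` must have length ", design$n_items)
  ll <- cpp_seq_bw_loglik(matrix(beta, 1L), prep$shown, prep$best_pos,
                          prep$worst_pos, prep$resp_idx)
  exp(ll / (2 * prep$n_tasks))
}

#' Partition respondents by the root-likelihood exclusion rule
#'
#' Respondents whose individual fit statistic (RLH) is strictly below the
#' threshold are flagged as inconsistent (assumed to have answered at
#' chance) and excluded; a respondent exactly at the threshold is retained.
#' The default threshold 0.2 sits above the chance level `1/sqrt(30)` for
#' 6-item best-worst tasks.
#'
#' @param posterior A [`bws_posterior`][fit_hb()] object (or any list with
#'   a named `rlh` vector).
#' @param threshold Exclusion threshold on the RLH scale.
#' @return List with character vectors `included` and `excluded`; the two
#'   partition the fitted respondents.
#' @export
filter_inconsistent <- function(posterior, threshold = 0.2) {
  rlh <- posterior$rlh
  if (is.null(rlh)) stop("`posterior` carries no RLH values")
  list(included = names(rlh)[rlh >= threshold],
       excluded = names(rlh)[rlh < threshold])
}

#' Relative importance scores from a fitted posterior
#'
#' Converts each included respondent's posterior-mean utilities into
#' relative importance scores (RIS) by the probability-rescaling transform:
#' `p_k = exp(beta_k) / (exp(beta_k) + set_size - 1)` is the model's
#' probability that item `k` is chosen best against `set_size - 1` average
#' (zero-utility) competitors, and `RIS_k = 100 * p_k / sum_j p_j`, so each
#' respondent's 16 scores are non-negative and sum to 100. Item means and
#' standard deviations are taken over the included respondents, and items
#' are ranked 1 (most important) to `n_items` by descending mean, ties
#' broken by item index.
#'
#' @param posterior A [`bws_posterior`][fit_hb()] object.
#' @param set_size Number of items per choice task (6).
#' @param include Respondent ids to keep (e.g. the `included` element of
#'   [filter_inconsistent()]); `NULL` keeps everyone.
#' @return An object of class `bws_ris`: list with `ris_individual`
#'   (respondents x items), `ris_mean`, `ris_sd`, `rank`, `covariates`
#'   (subset to the included respondents), `set_size`.
#' @export
compute_ris <- function(posterior, set_size = posterior$set_size,
                        include = NULL) {
  beta <- posterior$beta_mean
  if (!is.null(include)) {
    missing_ids <- setdiff(include, rownames(beta))
    if (length(missing_ids))
      stop("unknown respondent id(s): ", paste(missing_ids, collapse = ", "))
    beta <- beta[include, , drop = FALSE]
  }
  ris <- ris_from_beta(beta, set_size)
  ris_mean <- colMeans(ris)
  ris_sd <- apply(ris, 2L, sd)
  cov <- posterior$covariates
  if (!is.null(cov))
    cov <- cov[cov$respondent_id %in% rownames(ris), , drop = FALSE]
  structure(
    list(ris_individual = ris, ris_mean = ris_mean, ris_sd = ris_sd,
         rank = rank_items(ris_mean), covariates = cov,
         set_size = set_size),
    class = "bws_ris")
}

#' Probability-rescaled importance scores for a utility matrix
#'
#' @param beta Respondents x items utility matrix (or a single vector).
#' @param set_size Items per choice task.
#' @return Matrix of the same shape; each row is non-negative and sums
#'   to 100.
#' @export
ris_from_beta <- function(beta, set_size = 6L) {
  if (is.null(dim(beta))) beta <- matrix(beta, 1L)
  p <- exp(beta) / (exp(beta) + set_size - 1)
  100 * p / rowSums(p)
}

#' @export
print.bws_ris <- function(x, ...) {
  cat("Relative importance scores:", nrow(x$ris_individual),
      "respondents,", length(x$ris_mean), "items\n")
  ord <- order(x$rank)
  df <- data.frame(item = ord[1:3], mean = round(x$ris_mean[ord[1:3]], 2))
  cat("Top items:", paste(sprintf("%d (%.2f)", df$item, df$mean),
                          collapse = ", "), "\n")
  invisible(x)
}
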