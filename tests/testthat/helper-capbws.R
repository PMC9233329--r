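# Shared fixtures. The full-size hierarchical Bayes fit (159 respondents at
# the reduced MCMC profile) is computed once and cached for every test that
# needs it.

.fixture_cache <- new.env(parent = emptyenv())

study_design <- function(n_versions = 3L, n_iterations = 100L, seed = 7L) {
  key <- paste0("design_", n_versions, "_", n_iterations, "_", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_design(16, 6, 16,
                                             n_versions = n_versions,
                                             n_iterations = n_iterations,
                                             seed = seed)
  .fixture_cache[[key]]
}

# 158 default respondents plus one planted random responder, fitted at the
# reduced profile used throughout the tests.
study_fit <- function() {
  if (is.null(.fixture_cache$study_fit)) {
    design <- study_design()
    truth <- add_random_responder(
      simulate_population(population_config(seed = 1L)),
      cohort = "psychiatric patients")
    responses <- simulate_responses(design, truth, seed = 101L)
    posterior <- fit_hb(responses, design,
                        mcmc_config(n_burn = 2000L, n_keep = 2000L,
                                    thinning = 10L, seed = 201L))
    .fixture_cache$study_fit <- list(
      design = design, truth = truth, responses = responses,
      posterior = posterior, planted_id = attr(truth, "planted_id"),
      filter = filter_inconsistent(posterior))
  }
  .fixture_cache$study_fit
}

# single-version design on few items for toy likelihood checks
toy_design <- function(n_items = 6L, n_tasks = 2L) {
  n_items <- as.integer(n_items); n_tasks <- as.integer(n_tasks)
  tasks <- t(vapply(seq_len(n_tasks), function(t)
    ((seq_len(n_items) + t - 2L) %% n_items) + 1L, integer(n_items)))
  structure(
    list(n_items = n_items, set_size = n_items, n_tasks = n_tasks,
         n_versions = 1L, versions = list(tasks), pair_ss = NA_real_,
         min_pair_ss = NA_real_, r = n_tasks, seed = NA_integer_,
         n_iterations = NA_integer_),
    class = "bws_design")
}

# independent sequential best-worst choice probability for one task
oracle_task_prob <- function(beta, shown, best, worst) {
  p_best <- exp(beta[best]) / sum(exp(beta[shown]))
  rest <- setdiff(shown, best)
  p_worst <- exp(-beta[worst]) / sum(exp(-beta[rest]))
  p_best * p_worst
}

# midrank Kruskal-Wallis statistic with tie correction, written out in full
oracle_kruskal <- function(x, g) {
  g <- as.factor(g)
  r <- rank(x)
  N <- length(x)
  rbar <- (N + 1) / 2
  num <- (N - 1) * sum(tapply(r, g, function(ri)
    length(ri) * (mean(ri) - rbar)^2))
  den <- sum((r - rbar)^2)
  H <- num / den
  list(H = H, p = pchisq(H, nlevels(g) - 1L, lower.tail = FALSE))
}
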