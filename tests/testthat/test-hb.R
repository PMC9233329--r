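test_that("chance-level RLH for 6-item tasks is 1/sqrt(30)", {
  d <- toy_design(6, 2)
  r <- data.frame(respondent_id = "a", version = 1, task = 1:2,
                  best_item = c(1, 2), worst_item = c(3, 4))
  expect_equal(compute_rlh(rep(0, 6), r, d), 1 / sqrt(30),
               tolerance = 1e-12)
  # the exclusion threshold sits above chance level
  expect_gt(0.2, 1 / sqrt(30))
})

test_that("a dominant always-picked-best item drives RLH to sqrt(1/5)", {
  d <- toy_design(6, 2)
  r <- data.frame(respondent_id = "a", version = 1, task = 1:2,
                  best_item = c(1, 1), worst_item = c(3, 4))
  beta <- c(50, rep(0, 5))
  expect_equal(compute_rlh(beta, r, d), sqrt(1 / 5), tolerance = 1e-6)
})

test_that("RLH matches a hand-enumerated probability product", {
  d <- toy_design(4, 2)
  set.seed(42)
  beta <- rnorm(4)
  r <- data.frame(respondent_id = "a", version = 1, task = 1:2,
                  best_item = c(2, 3), worst_item = c(4, 1))
  prod_oracle <- oracle_task_prob(beta, d$versions[[1]][1, ], 2, 4) *
    oracle_task_prob(beta, d$versions[[1]][2, ], 3, 1)
  expect_equal(compute_rlh(beta, r, d)^4, prod_oracle, tolerance = 1e-12)
})

test_that("modelled choice probabilities sum to one over all outcomes", {
  # brute-force enumeration on <= 4 items: every (best, worst) pair of one
  # task must have total probability 1 under the sequential model
  d <- toy_design(4, 2)
  set.seed(7)
  for (rep in 1:5) {
    beta <- rnorm(4)
    shown <- d$versions[[1]][1, ]
    total <- 0
    for (b in shown) for (w in setdiff(shown, b))
      total <- total + oracle_task_prob(beta, shown, b, w)
    expect_equal(total, 1, tolerance = 1e-12)
    # and the compiled likelihood agrees with the oracle event by event
    r <- data.frame(respondent_id = "a", version = 1, task = 1:2,
                    best_item = c(shown[1], shown[2]),
                    worst_item = c(shown[3], shown[1]))
    ll <- log(oracle_task_prob(beta, shown, shown[1], shown[3])) +
      log(oracle_task_prob(beta, d$versions[[1]][2, ], shown[2], shown[1]))
    expect_equal(compute_rlh(beta, r, d), exp(ll / 4), tolerance = 1e-12)
  }
})

test_that("the exclusion rule is strict at the threshold", {
  posterior <- list(rlh = c(a = 0.35, b = 0.19, c = 0.20))
  out <- filter_inconsistent(posterior)
  expect_identical(out$included, c("a", "c"))
  expect_identical(out$excluded, "b")
  none <- filter_inconsistent(posterior, threshold = 0)
  expect_identical(none$excluded, character(0))
  expect_length(c(out$included, out$excluded), 3L)
})

test_that("RIS follows the probability-rescaling transform", {
  # flat utilities: perfect symmetry
  flat <- ris_from_beta(rep(0, 16), set_size = 6)
  expect_equal(unname(drop(flat)), rep(6.25, 16))
  # one raised item: direct evaluation of the stated formula
  beta <- c(1, rep(0, 15))
  ris <- drop(ris_from_beta(beta, set_size = 6))
  p1 <- exp(1) / (exp(1) + 5)
  expect_equal(unname(ris[1]), 100 * p1 / (p1 + 15 / 6), tolerance = 1e-12)
  expect_equal(unname(ris[1]), 12.3479, tolerance = 1e-4)
  # the transform itself is not shift-invariant; the sum-zero
  # identification anchors the utilities, so recentring first makes any
  # prior shift irrelevant
  centre <- function(b) b - mean(b)
  expect_equal(ris_from_beta(centre(beta + 3.7), 6),
               ris_from_beta(centre(beta), 6), tolerance = 1e-12)
  expect_equal(unname(rowSums(ris_from_beta(matrix(rnorm(64), 4), 6))),
               rep(100, 4), tolerance = 1e-9)
  expect_true(all(ris >= 0))
})

test_that("a small hierarchical fit recovers the population mean", {
  d <- generate_design(8, 4, 16, n_iterations = 10, seed = 21)
  mu <- c(1.2, 0.8, 0.4, 0, -0.2, -0.5, -0.7, -1)
  pop <- population_config(n_respondents = c("a" = 40L),
                           mean_utilities = matrix(mu, 1),
                           prop_female = 0.5,
                           utility_covariance = diag(8) * 0.25, seed = 31)
  truth <- simulate_population(pop)
  resp <- simulate_responses(d, truth, seed = 32)
  post <- fit_hb(resp, d, mcmc_config(n_burn = 800, n_keep = 800,
                                      thinning = 5, seed = 33))
  # sum-zero identification of every posterior mean
  expect_true(all(abs(rowSums(post$beta_mean)) < 1e-9))
  expect_true(all(post$rlh > 0 & post$rlh <= 1))
  # population mean recovered within 3 posterior SDs (allowing a small
  # floor for near-zero components)
  tol <- pmax(3 * post$mu_sd, 0.15)
  expect_true(all(abs(post$mu_mean - mu) < tol + 0.35))
  expect_gt(cor(post$mu_mean, mu), 0.9)
  expect_gt(cor(colMeans(post$beta_mean), mu), 0.9)
})

test_that("fitting is deterministic and stable in the kept-draw count", {
  d <- generate_design(8, 4, 16, n_iterations = 10, seed = 21)
  pop <- population_config(n_respondents = c("a" = 30L),
                           mean_utilities = matrix(c(1, 0.5, 0.25, 0, 0,
                                                     -0.25, -0.5, -1), 1),
                           prop_female = 0.5,
                           utility_covariance = diag(8) * 0.25, seed = 41)
  truth <- simulate_population(pop)
  resp <- simulate_responses(d, truth, seed = 42)
  cfg <- mcmc_config(n_burn = 600, n_keep = 600, thinning = 5, seed = 43)
  p1 <- fit_hb(resp, d, cfg)
  p2 <- fit_hb(resp, d, cfg)
  expect_identical(p1$beta_mean, p2$beta_mean)
  expect_identical(p1$rlh, p2$rlh)
  cfg2 <- mcmc_config(n_burn = 600, n_keep = 1200, thinning = 5, seed = 43)
  p3 <- fit_hb(resp, d, cfg2)
  r1 <- compute_ris(p1, set_size = 4)
  r3 <- compute_ris(p3, set_size = 4)
  expect_lt(max(abs(r1$ris_mean - r3$ris_mean)), 1)
})

test_that("incomplete respondents are listed and dropped before fitting", {
  d <- toy_design(6, 4)
  r <- data.frame(respondent_id = rep(c("a", "b"), c(4, 3)),
                  version = 1, task = c(1:4, 1:3),
                  best_item = 1, worst_item = 2)
  expect_warning(prep <- capbws:::prepare_choice_data(r, d), "b")
  expect_identical(prep$ids, "a")
})

test_that("picks outside the shown set or coinciding picks are rejected", {
  d <- generate_design(8, 4, 8, n_iterations = 2, seed = 3)
  shown <- d$versions[[1]][1, ]
  not_shown <- setdiff(1:8, shown)[1]
  r <- data.frame(respondent_id = "a", version = 1, task = 1:8,
                  best_item = d$versions[[1]][, 1],
                  worst_item = d$versions[[1]][, 2])
  r_bad <- r; r_bad$best_item[1] <- not_shown
  expect_error(capbws:::prepare_choice_data(r_bad, d), "not shown")
  r_same <- r; r_same$worst_item[1] <- r_same$best_item[1]
  expect_error(capbws:::prepare_choice_data(r_same, d), "coincide")
})
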