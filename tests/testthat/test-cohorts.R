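test_that("default population reproduces the study's cohort structure", {
  pop <- population_config(seed = 5)
  truth <- simulate_population(pop)
  tab <- table(truth$covariates$cohort)
  expect_equal(sum(tab), 158L)
  expect_equal(unname(tab[c("psychiatric patients", "general population",
                            "mental health experts")]),
               c(53L, 50L, 55L), ignore_attr = TRUE)
  expect_true(all(abs(rowSums(truth$beta_true)) < 1e-9))
  expect_true(all(truth$covariates$gender %in% c("female", "male")))
})

test_that("cohort mean utilities sum to zero and differ on two items only", {
  M <- default_mean_utilities(c("psychiatric patients",
                                "general population",
                                "mental health experts"))
  expect_equal(rowSums(M), rep(0, 3), ignore_attr = TRUE)
  base <- M["general population", ]
  dp <- M["psychiatric patients", ] - base
  de <- M["mental health experts", ] - base
  # the planted contrasts load on items 10 and 5; recentring spreads the
  # compensation equally over all items
  expect_equal(which.min(dp), 10L, ignore_attr = TRUE)
  expect_equal(which.min(de), 5L, ignore_attr = TRUE)
  expect_lt(max(abs(dp[-10])), 0.1)
  expect_lt(max(abs(de[-5])), 0.1)
})

test_that("zero covariance copies the cohort mean exactly", {
  pop <- population_config(n_respondents = c("a" = 4L, "b" = 3L),
                           mean_utilities = rbind(a = c(1, -1, rep(0, 14)),
                                                  b = c(0, 0, 2, -2,
                                                        rep(0, 12))),
                           prop_female = 0.5,
                           utility_covariance = matrix(0, 16, 16),
                           seed = 2)
  truth <- simulate_population(pop)
  expect_equal(unname(truth$beta_true[1, ]), c(1, -1, rep(0, 14)))
  expect_equal(unname(truth$beta_true[7, ]), c(0, 0, 2, -2, rep(0, 12)))
})

test_that("invalid covariance and mean vectors are rejected", {
  expect_error(population_config(utility_covariance = -diag(16)),
               "positive semi-definite")
  sig <- diag(16); sig[1, 2] <- 0.5
  expect_error(population_config(utility_covariance = sig), "symmetric")
  expect_error(population_config(mean_utilities =
                                   matrix(1, 3, 16)), "sum to zero")
})

test_that("sampled cohort means converge to the configured means", {
  pop <- population_config(n_respondents = c("a" = 2000L),
                           mean_utilities = matrix(default_mean_utilities("a"),
                                                   1),
                           prop_female = 0.5, seed = 11)
  truth <- simulate_population(pop)
  se <- 1.2 / sqrt(2000)
  dev <- colMeans(truth$beta_true) - pop$mean_utilities[1, ]
  expect_true(all(abs(dev) < 3.5 * se))
})

test_that("simulated choices follow the sequential best-worst MNL", {
  # beta = (1, 0, ..., 0) on 6 items shown together: P(best = item 1)
  # has the closed form e / (e + 5)
  n_resp <- 640L  # 10,240 tasks
  d <- toy_design(6, 16)
  beta <- c(1, rep(0, 5))
  truth <- structure(
    list(covariates = data.frame(respondent_id = sprintf("R%03d",
                                                         seq_len(n_resp)),
                                 cohort = "a", gender = "female"),
         beta_true = matrix(beta, n_resp, 6, byrow = TRUE,
                            dimnames = list(sprintf("R%03d",
                                                    seq_len(n_resp)),
                                            NULL))),
    class = "bws_truth")
  resp <- simulate_responses(d, truth, seed = 4)
  p1 <- exp(beta[1]) / sum(exp(beta))
  expect_equal(p1, exp(1) / (exp(1) + 5), tolerance = 1e-12)
  n_tasks_total <- nrow(resp)
  obs_best <- mean(resp$best_item == 1L)
  expect_lt(abs(obs_best - p1), 3.5 * sqrt(p1 * (1 - p1) / n_tasks_total))
  # chi-square goodness of fit of all best picks against the MNL
  exp_best <- exp(beta) / sum(exp(beta))
  gof <- suppressWarnings(chisq.test(tabulate(resp$best_item, 6),
                                     p = exp_best))
  expect_gt(gof$p.value, 0.01)
  # worst picks: conditional on the best pick, negated utilities
  worst_tab <- tabulate(resp$worst_item, 6)
  exp_worst <- vapply(1:6, function(j) sum(vapply(1:6, function(b) {
    if (b == j) return(0)
    rest <- setdiff(1:6, b)
    exp_best[b] * exp(-beta[j]) / sum(exp(-beta[rest]))
  }, 1.0)), 1.0)
  gof_w <- suppressWarnings(chisq.test(worst_tab, p = exp_worst))
  expect_gt(gof_w$p.value, 0.01)
})

test_that("a dominant item is almost always best and never worst", {
  d <- toy_design(6, 16)
  pop <- population_config(n_respondents = c("a" = 40L),
                           mean_utilities = matrix(c(10, rep(-2, 5)), 1),
                           prop_female = 0.5,
                           utility_covariance = matrix(0, 6, 6), seed = 8)
  truth <- simulate_population(pop)
  resp <- simulate_responses(d, truth, seed = 9)
  expect_gt(mean(resp$best_item == 1L), 0.999)
  expect_equal(mean(resp$worst_item == 1L), 0)
})

test_that("identical seeds give byte-identical responses", {
  d <- study_design()
  pop <- population_config(seed = 6)
  truth <- simulate_population(pop)
  r1 <- simulate_responses(d, truth, seed = 10)
  r2 <- simulate_responses(d, truth, seed = 10)
  expect_identical(r1, r2)
  expect_true(all(r1$best_item != r1$worst_item))
})
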