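# small synthetic respondent table used across the regression tests
make_reg_fixture <- function(n_per = 10L, seed = 5L, delta = 3,
                             n_items = 4L) {
  set.seed(seed)
  cohorts <- rep(c("general population", "psychiatric patients",
                   "mental health experts"), each = n_per)
  n <- length(cohorts)
  ids <- sprintf("R%03d", seq_len(n))
  gender <- sample(c("female", "male"), n, replace = TRUE)
  Y <- matrix(rnorm(n * n_items, mean = 6), n, n_items,
              dimnames = list(ids, NULL))
  # planted cohort effect on item 1: psychiatric lower by delta
  Y[cohorts == "psychiatric patients", 1] <-
    Y[cohorts == "psychiatric patients", 1] - delta
  list(Y = Y, covariates = data.frame(respondent_id = ids, cohort = cohorts,
                                      gender = gender), ids = ids)
}

test_that("the jackknife variance formula matches a naive loop exactly", {
  set.seed(1)
  loo <- rnorm(20, 1, 0.1)
  hat <- 1.02
  naive <- 0
  for (i in seq_along(loo)) naive <- naive + (loo[i] - hat)^2
  naive <- (20 - 1) / 20 * naive
  expect_identical(jackknife_variance(loo, hat), naive)
  expect_equal(jackknife_variance(rep(hat, 20), hat), 0)
})

test_that("OLS coefficients match the normal-equations oracle", {
  fx <- make_reg_fixture()
  beta <- fit_item_regressions(fx$Y, fx$covariates)
  X <- regression_design(fx$covariates)
  oracle <- t(solve(crossprod(X), crossprod(X, fx$Y)))
  expect_equal(unname(beta), unname(oracle), tolerance = 1e-10)
  # column order: male, psychiatric vs general, expert vs general, constant
  expect_match(colnames(beta)[1], "male")
  expect_match(colnames(beta)[2], "psychiatric")
  expect_match(colnames(beta)[3], "expert")
  expect_equal(colnames(beta)[4], "constant")
  # an identically zero outcome gives all-zero coefficients
  beta0 <- fit_item_regressions(matrix(0, 30, 2,
                                       dimnames = list(fx$ids, NULL)),
                                fx$covariates)
  expect_equal(unname(beta0), matrix(0, 2, 4))
})

test_that("planted cohort effects are recovered by the regressions", {
  fx <- make_reg_fixture(n_per = 200L, seed = 9L, delta = 3)
  beta <- fit_item_regressions(fx$Y, fx$covariates)
  expect_equal(unname(beta[1, 2]), -3, tolerance = 0.35)
  expect_lt(abs(beta[2, 2]), 0.35)   # null item
  expect_lt(abs(beta[1, 1]), 0.35)   # no gender effect
})

test_that("rank-deficient designs raise a singularity error", {
  fx <- make_reg_fixture()
  cov2 <- fx$covariates
  cov2$gender <- "male"   # male indicator collinear with the intercept
  expect_error(fit_item_regressions(fx$Y, cov2), "collinear")
})

test_that("jackknife SEs over plain OLS match direct delete-one refits", {
  fx <- make_reg_fixture(n_per = 8L, seed = 13L)
  jk <- jackknife_robust(ols_fitter(fx$Y, fx$covariates), fx$ids)
  n <- length(fx$ids)
  expect_equal(jk$n, n)
  expect_equal(jk$J, 4L)
  expect_equal(jk$df, n - 4L - 1L)
  # oracle: explicit normal-equations refits leaving each row out
  X <- regression_design(fx$covariates)
  full <- solve(crossprod(X), crossprod(X, fx$Y))
  for (k in c(1L, 3L)) {
    for (j in 1:4) {
      loo <- vapply(seq_len(n), function(i) {
        Xi <- X[-i, , drop = FALSE]
        solve(crossprod(Xi), crossprod(Xi, fx$Y[-i, k]))[j]
      }, 1.0)
      v <- (n - 1) / n * sum((loo - full[j, k])^2)
      expect_equal(unname(jk$v_hat[k, j]), v, tolerance = 1e-10)
      expect_gt(jk$v_hat[k, j], 0)
      expect_equal(unname(jk$s_hat[k, j]), sqrt(v), tolerance = 1e-10)
    }
  }
  # p-values use a t reference with n - J - 1 degrees of freedom
  expect_equal(jk$p_value[1, 2],
               2 * pt(abs(jk$t_stat[1, 2]), df = n - 5L,
                      lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("t statistics are invariant to rescaling the outcome", {
  fx <- make_reg_fixture(n_per = 8L, seed = 17L)
  jk1 <- jackknife_robust(ols_fitter(fx$Y, fx$covariates), fx$ids)
  jk2 <- jackknife_robust(ols_fitter(fx$Y * 7.3, fx$covariates), fx$ids)
  expect_equal(jk1$t_stat, jk2$t_stat, tolerance = 1e-9)
})

test_that("158 participants with 4 coefficients give 153 degrees of freedom", {
  set.seed(23)
  ids <- sprintf("R%03d", 1:158)
  cov <- data.frame(respondent_id = ids,
                    cohort = rep(c("general population",
                                   "psychiatric patients",
                                   "mental health experts"),
                                 c(50, 53, 55)),
                    gender = sample(c("female", "male"), 158, TRUE))
  Y <- matrix(rnorm(158 * 2), 158, 2, dimnames = list(ids, NULL))
  jk <- jackknife_robust(ols_fitter(Y, cov), ids)
  expect_identical(jk$df, 153L)
})

test_that("degenerate and annotated outputs behave as documented", {
  fx <- make_reg_fixture(n_per = 8L, seed = 19L)
  const_fitter <- function(omit) matrix(1.5, 2, 4,
                                        dimnames = list(NULL,
                                                        c("male", "p", "e",
                                                          "constant")))
  jk <- jackknife_robust(const_fitter, fx$ids)
  expect_true(all(jk$v_hat == 0))       # all replicates equal the full fit
  expect_error(jackknife_robust(const_fitter, fx$ids[1:4]), "at least")
  jk2 <- jackknife_robust(ols_fitter(fx$Y, fx$covariates), fx$ids)
  tab <- significance_table(jk2)
  expect_true(all(c("male_est", "male_se", "male_p", "male_stars") %in%
                    names(tab)))
  expect_identical(significance_stars(c(0.03, 0.2, 0.0005, 0.009)),
                   c("*", "", "***", "**"))
})

test_that("the full HB re-estimation jackknife runs and is deterministic", {
  d <- generate_design(6, 3, 8, n_iterations = 5, seed = 51)
  mu <- c(1, 0.5, 0, 0, -0.5, -1)
  pop <- population_config(
    n_respondents = c("general population" = 4L,
                      "psychiatric patients" = 4L,
                      "mental health experts" = 4L),
    mean_utilities = rbind(mu, mu, mu), prop_female = 0.5,
    utility_covariance = diag(6) * 0.25, seed = 52)
  truth <- simulate_population(pop)
  resp <- simulate_responses(d, truth, seed = 53)
  cfg <- mcmc_config(n_burn = 150, n_keep = 150, thinning = 5, seed = 54)
  fitter <- hb_fitter(resp, d, cfg)
  ids <- attr(fitter, "included")
  jk1 <- jackknife_robust(fitter, ids)
  jk2 <- jackknife_robust(fitter, ids)
  expect_identical(jk1$beta_hat, jk2$beta_hat)
  expect_identical(jk1$v_hat, jk2$v_hat)
  expect_true(all(jk1$v_hat >= 0))
  expect_equal(dim(jk1$beta_loo), c(length(ids), 6L, 4L))
})
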