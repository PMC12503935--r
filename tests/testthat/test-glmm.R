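# Design construction, quadrature accuracy, fitting, and LRT behaviour.

test_that("design matrices use reference coding and orthogonal polynomials", {
  d <- data.frame(y = 0:5, n = 6,
                  treatment = rep(c("none", "reliable", "unreliable"), 2),
                  t = c(1, 2, 3, 4, 5, 6))
  spec <- glmm_spec("y", ~ treatment, "binomial", size = "n")
  des <- build_design(spec, d)
  expect_equal(ncol(des$X), 3)  # intercept + 2 contrast columns

  spec2 <- glmm_spec("y", ~ poly(t, 2), "binomial", size = "n")
  des2 <- build_design(spec2, d)
  P <- des2$X[, 2:3]
  expect_lt(abs(sum(P[, 1] * P[, 2])), 1e-10)
  expect_lt(abs(sum(P[, 1])), 1e-10)

  expect_error(build_design(glmm_spec("y", ~ missing_col, "binomial",
                                      size = "n"), d),
               class = "cueload_unknown_column")
  d_one <- transform(d, treatment = "none")
  expect_error(build_design(spec, d_one), class = "cueload_invalid_design")
})

test_that("fixed-parameter bookkeeping gives df 4 for treatment-by-run terms", {
  b <- scale_run_time(gen_behavior(behavior_design(n_trials = 6), seed = 2))
  full <- glmm_spec("n_on_uninfested",
                    ~ treatment * poly(run_c, 2) + poly(time_c, 2),
                    "binomial", size = "n_females")
  red <- glmm_spec("n_on_uninfested",
                   ~ treatment + poly(run_c, 2) + poly(time_c, 2),
                   "binomial", size = "n_females")
  n_full <- ncol(build_design(full, b)$X)
  n_red <- ncol(build_design(red, b)$X)
  expect_equal(n_full - n_red, 4)
})

test_that("marginal likelihood reduces to the GLM at zero variance", {
  d <- toy_binomial_data()
  spec <- glmm_spec("y", ~ x, "binomial", size = "size", random = "g")
  beta <- c(-0.2, 0.5)
  ll <- marginal_loglik(spec, d, list(beta = beta, sd = 0))
  glm_ll <- sum(dbinom(d$y, d$size, plogis(beta[1] + beta[2] * d$x),
                       log = TRUE))
  expect_lt(abs(ll - glm_ll), 1e-10)
})

test_that("adaptive quadrature matches brute-force integration", {
  for (fam in c("binomial", "poisson")) {
    d <- toy_binomial_data(n_groups = 5, per_group = 4, seed = 11)
    if (fam == "poisson") d$y <- rpois(nrow(d), exp(0.3 + 0.2 * d$x))
    spec <- if (fam == "binomial")
      glmm_spec("y", ~ x, fam, size = "size", random = "g")
    else glmm_spec("y", ~ x, fam, random = "g")
    beta <- c(-0.2, 0.6)
    eta0 <- beta[1] + beta[2] * d$x
    for (sdv in c(0.4, 1.0)) {
      ll_or <- oracle_marginal_loglik(d$y, d$size, eta0, d$g, sdv, fam)
      ll15 <- marginal_loglik(spec, d, list(beta = beta, sd = sdv),
                              n_nodes = 15)
      expect_lt(abs(ll15 - ll_or), 1e-6)
      # refinement: more nodes at least as accurate as few
      ll3 <- marginal_loglik(spec, d, list(beta = beta, sd = sdv),
                             n_nodes = 3)
      ll25 <- marginal_loglik(spec, d, list(beta = beta, sd = sdv),
                              n_nodes = 25)
      expect_lte(abs(ll25 - ll_or), abs(ll3 - ll_or) + 1e-12)
    }
  }
})

test_that("marginal likelihood is invariant to row permutation", {
  d <- toy_binomial_data(n_groups = 8, per_group = 3, seed = 5)
  spec <- glmm_spec("y", ~ x, "binomial", size = "size", random = "g")
  params <- list(beta = c(0.1, -0.4), sd = 0.7)
  ll1 <- marginal_loglik(spec, d, params)
  set.seed(1)
  d2 <- d[sample(nrow(d)), ]
  ll2 <- marginal_loglik(spec, d2, params)
  expect_lt(abs(ll1 - ll2), 1e-8)
})

test_that("non-finite predictors are reported with a row index", {
  d <- toy_binomial_data(n_groups = 3, per_group = 2)
  d$x[4] <- Inf
  spec <- glmm_spec("y", ~ x, "binomial", size = "size", random = "g")
  expect_error(marginal_loglik(spec, d, list(beta = c(0, 1), sd = 0.5)),
               "row 4", class = "cueload_nonfinite_predictor")
})

test_that("fitting recovers known coefficients and matches lme4", {
  skip_if_not_installed("lme4")
  set.seed(101)
  n_g <- 200; per <- 6
  g <- factor(rep(seq_len(n_g), each = per))
  x <- rnorm(n_g * per)
  tr <- factor(rep_len(c("a", "b"), n_g * per))
  truth <- c(`(Intercept)` = -0.4, trb = 0.6, x = 0.8)
  u <- rnorm(n_g, 0, 0.5)
  eta <- truth[1] + truth[2] * (tr == "b") + truth[3] * x + u[as.integer(g)]
  d <- data.frame(y = rbinom(length(eta), 4, plogis(eta)), x = x, tr = tr,
                  g = g, size = 4)
  spec <- glmm_spec("y", ~ tr + x, "binomial", size = "size", random = "g")
  fit <- fit_glmm(spec, d)
  expect_true(fit$converged)
  z <- abs(coef(fit) - truth) / fit$se
  expect_true(all(z < 3))

  lf <- lme4::glmer(cbind(y, size - y) ~ tr + x + (1 | g), data = d,
                    family = binomial, nAGQ = 15)
  expect_equal(unname(coef(fit)), unname(lme4::fixef(lf)), tolerance = 1e-4)
  expect_equal(unname(fit$sd), unname(sqrt(unlist(lme4::VarCorr(lf)))),
               tolerance = 1e-3)
})

test_that("a zero generating variance is estimated at the boundary", {
  # informative design (100 groups of 20 binomial rows) so the profile in
  # the variance direction is not dominated by sampling noise
  d <- toy_binomial_data(n_groups = 100, per_group = 20, sd_u = 0, seed = 77)
  spec <- glmm_spec("y", ~ x, "binomial", size = "size", random = "g")
  fit <- fit_glmm(spec, d, options = list(compute_vcov = FALSE))
  expect_lt(fit$variance_components[[1]], 0.05)
})

test_that("refitting permuted rows reproduces the likelihood", {
  d <- toy_binomial_data(n_groups = 15, per_group = 4, seed = 9)
  spec <- glmm_spec("y", ~ x, "binomial", size = "size", random = "g")
  f1 <- fit_glmm(spec, d, options = list(compute_vcov = FALSE))
  set.seed(2)
  f2 <- fit_glmm(spec, d[sample(nrow(d)), ],
                 options = list(compute_vcov = FALSE))
  expect_lt(abs(f1$loglik - f2$loglik), 1e-6)
})

test_that("likelihood-ratio tests behave on identical and nested models", {
  d <- toy_binomial_data(n_groups = 12, per_group = 4, seed = 3)
  spec <- glmm_spec("y", ~ x, "binomial", size = "size", random = "g")
  fit <- fit_glmm(spec, d, options = list(compute_vcov = FALSE))
  same <- lr_test(fit, fit)
  expect_equal(same$statistic, 0)
  expect_equal(same$df, 0)
  expect_equal(same$p_value, 1)

  spec0 <- glmm_spec("y", ~ 1, "binomial", size = "size", random = "g")
  fit0 <- fit_glmm(spec0, d, options = list(compute_vcov = FALSE))
  t1 <- lr_test(fit, fit0)
  expect_equal(t1$df, 1)
  expect_gte(t1$statistic, 0)
  expect_true(t1$p_value >= 0 && t1$p_value <= 1)

  # non-nested: different response transform columns
  d$z <- rnorm(nrow(d))
  specz <- glmm_spec("y", ~ z, "binomial", size = "size", random = "g")
  fitz <- fit_glmm(specz, d, options = list(compute_vcov = FALSE))
  expect_error(lr_test(fit, fitz), class = "cueload_not_nested")
})

test_that("the LRT is invariant to raw versus orthogonal polynomial coding", {
  b <- scale_run_time(gen_behavior(behavior_design(n_trials = 5, runs = 4),
                                   seed = 6))
  b <- b[b$time_index <= 5, ]  # keep the fixture small
  mk <- function(form) {
    fit_glmm(glmm_spec("n_on_uninfested", form, "binomial",
                       size = "n_females", random = "trial_id"),
             b, options = list(compute_vcov = FALSE))
  }
  full_orth <- mk(~ treatment + poly(run_c, 2))
  red_orth <- mk(~ treatment)
  full_raw <- mk(~ treatment + run_c + I(run_c^2))
  t_orth <- lr_test(full_orth, red_orth)
  t_raw <- lr_test(full_raw, red_orth)
  expect_equal(t_orth$df, t_raw$df)
  expect_lt(abs(t_orth$statistic - t_raw$statistic), 1e-6)
})
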