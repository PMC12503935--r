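# Selection transformations: viability back-transform, fitness costs,
# egg-weighted selection coefficients, inbreeding depression, and the
# care-survival ellipse.

test_that("viability back-transform matches hand-computed inverse logits", {
  # all coefficients zero: probability one half at any level
  dr0 <- fake_survival_draws(survival_coef_row(0, 0, 0, 0))
  expect_equal(unname(viability_at(dr0, "inbred", 3)), 0.5)
  expect_equal(unname(viability_at(dr0, "outbred", 0)), 0.5)

  # intercept 1, slope -0.3 at c = 6: inverse-logit(-0.8)
  dr <- fake_survival_draws(survival_coef_row(1, 0, -0.3, 0))
  expect_equal(unname(viability_at(dr, "outbred", 6)), plogis(-0.8),
               tolerance = 1e-12)
  expect_equal(round(unname(viability_at(dr, "outbred", 6)), 4), 0.31)

  # extreme predictors stay strictly inside (0, 1)
  dr_lo <- fake_survival_draws(survival_coef_row(-40, 0, 0, 0))
  v <- unname(viability_at(dr_lo, "outbred", 0))
  expect_gt(v, 0)
  expect_gte(v, 1e-15)

  expect_error(viability_at(dr, "inbred", 7),
               class = "cueload_invalid_competition")
  expect_error(viability_at(dr, "inbred", -1),
               class = "cueload_invalid_competition")
})

test_that("delta_omega arithmetic, signs and guards", {
  expect_equal(as.numeric(delta_omega(0.8, 0.8)), 0)
  expect_equal(as.numeric(delta_omega(0.4, 0.8)), 0.5)
  neg <- delta_omega(0.9, 0.6)
  expect_equal(as.numeric(neg), -0.5)
  expect_true(attr(neg, "negative_cost"))
  expect_error(delta_omega(0.5, 0), class = "cueload_undefined_ratio")
  # scale invariance
  expect_equal(as.numeric(delta_omega(0.2, 0.5)),
               as.numeric(delta_omega(0.2 * 3, 0.5 * 3)))
  # strictly decreasing in v_inbred at fixed v_outbred
  vi <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(as.numeric(delta_omega(vi, 0.95))) < 0))
})

test_that("posterior delta_omega handles degenerate and constructed draws", {
  # identical inbred/outbred coefficients in every draw: zero cost exactly
  m <- survival_coef_row(1.2, 0, -0.3, 0)[rep(1, 50), , drop = FALSE]
  est0 <- delta_omega_posterior(fake_survival_draws(m), 4)
  expect_equal(est0$mean, 0)
  expect_equal(unname(diff(est0$ci)), 0)

  # constructed draws with v_I = 0.16, v_O = 0.20 in every draw
  b0 <- qlogis(0.20)
  bi <- qlogis(0.16) - qlogis(0.20)
  m2 <- survival_coef_row(b0, bi, 0, 0)[rep(1, 50), , drop = FALSE]
  est <- delta_omega_posterior(fake_survival_draws(m2), 0)
  expect_equal(est$mean, 0.2, tolerance = 1e-12)
})

test_that("expected fitness weights eggs by seed-class survival", {
  expect_equal(as.numeric(expected_fitness(10, 0, 0.9, 0.5)), 9)
  expect_equal(as.numeric(expected_fitness(6, 4, 0.9, 0.5)), 7.4)
  zero <- expected_fitness(0, 0, 0.9, 0.5)
  expect_equal(as.numeric(zero), 0)
  expect_true(attr(zero, "degenerate"))
  expect_error(expected_fitness(-1, 0, 0.9, 0.5),
               class = "cueload_invalid_params")
  expect_error(expected_fitness(1, 0, 1.2, 0.5),
               class = "cueload_invalid_params")
  # when v0 = v3, the egg split is irrelevant
  expect_equal(as.numeric(expected_fitness(10, 0, 0.7, 0.7)),
               as.numeric(expected_fitness(3, 7, 0.7, 0.7)))
})

test_that("selection coefficients reproduce the printed worked examples", {
  expect_equal(selection_coefficient(1, 1), 0)
  expect_equal(selection_coefficient(0.52, 1.0), 0.48)
  expect_equal(selection_coefficient(0.36, 1.0), 0.64)
  expect_error(selection_coefficient(0.5, 0),
               class = "cueload_undefined_ratio")
  # scale invariance
  expect_equal(selection_coefficient(0.3, 0.6),
               selection_coefficient(0.3 * 7, 0.6 * 7))
})

make_egg_expectation <- function(eu, ei, n_draws = 10,
                                 treatments = c("none", "reliable",
                                                "unreliable")) {
  # eu/ei: matrices treatments x cross (outbred, inbred)
  arr <- function(m) {
    a <- array(NA_real_, c(n_draws, nrow(m), 2),
               dimnames = list(NULL, treatments, c("outbred", "inbred")))
    for (j in seq_len(nrow(m))) for (k in 1:2) a[, j, k] <- m[j, k]
    a
  }
  structure(list(uninfested = arr(eu), infested = arr(ei),
                 treatments = treatments),
            class = "cueload_egg_expectation")
}

test_that("treatment selection reduces correctly on constructed fixtures", {
  # identical egg draws across treatments: all contrasts zero, p = 1
  eu <- matrix(c(5, 3), 3, 2, byrow = TRUE)
  ei <- matrix(c(5, 3), 3, 2, byrow = TRUE)
  eggs <- make_egg_expectation(eu, ei)
  surv <- fake_survival_draws(
    survival_coef_row(2.2, -1.25, -0.35, -0.21)[rep(1, 10), , drop = FALSE])
  ts <- treatment_selection(eggs, surv)
  expect_true(all(abs(ts$contrasts$mean) < 1e-12))
  expect_true(all(ts$contrasts$p_mcmc == 1))

  # fixture engineered so every draw gives s = (0.48, 0.60, 0.64) exactly:
  # all eggs on uninfested seeds, v0_O = 0.8, omega_O = 10 * 0.8 = 8
  b0 <- qlogis(0.8)
  s_target <- c(none = 0.64, reliable = 0.48, unreliable = 0.60)
  # choose inbred viability 0.4: omega_I = eu_I * 0.4 = 8 (1 - s)
  bi <- qlogis(0.4) - b0
  eu2 <- cbind(rep(10, 3), 8 * (1 - s_target) / 0.4)
  ei2 <- matrix(0, 3, 2)
  eggs2 <- make_egg_expectation(eu2, ei2,
                                treatments = names(s_target))
  surv2 <- fake_survival_draws(
    survival_coef_row(b0, bi, 0, 0)[rep(1, 10), , drop = FALSE])
  ts2 <- treatment_selection(eggs2, surv2)
  expect_equal(ts2$estimates$none$mean, 0.64, tolerance = 1e-12)
  expect_equal(ts2$estimates$reliable$mean, 0.48, tolerance = 1e-12)
  expect_equal(ts2$estimates$unreliable$mean, 0.60, tolerance = 1e-12)
  d_nr <- ts2$contrasts[ts2$contrasts$treatment_a == "none" &
                          ts2$contrasts$treatment_b == "reliable", ]
  expect_equal(d_nr$mean, 0.16, tolerance = 1e-12)

  # draw-count mismatch signals unless thinning is allowed
  surv3 <- fake_survival_draws(
    survival_coef_row(b0, bi, 0, 0)[rep(1, 7), , drop = FALSE])
  expect_error(treatment_selection(eggs2, surv3),
               class = "cueload_draw_mismatch")
  ts3 <- treatment_selection(eggs2, surv3, match_draws = TRUE)
  expect_equal(nrow(ts3$s_draws), 7)
})

test_that("inbreeding depression estimates and guards", {
  f <- data.frame(
    cross_label = rep(c("line1-inbred", "cross1-outbred"), each = 4),
    hatched_eggs = c(40, 40, 40, 40, 100, 100, 100, 100))
  est <- inbreeding_depression(f, n_boot = 50, seed = 1)
  expect_equal(est$estimate[1], 0.6)
  f0 <- transform(f, hatched_eggs = rep(c(50, 50), each = 4))
  expect_equal(inbreeding_depression(f0, n_boot = 50, seed = 1)$estimate[1], 0)
  fz <- transform(f, hatched_eggs = ifelse(grepl("outbred", cross_label),
                                           0, 40))
  expect_error(inbreeding_depression(fz, n_boot = 10, seed = 1),
               class = "cueload_undefined_ratio")
})

test_that("care-survival ellipse matches the direct covariance formula", {
  # constructed points with known covariance
  care <- c(10, 20, 30, 40, 50, 60)
  surv <- 5 + 0.4 * care + c(1, -1, 2, -2, 0.5, -0.5)
  gm <- data.frame(care = care, survival = surv)
  ell <- care_survival_ellipse(gm)
  # brute-force covariance
  cov_hand <- sum((care - mean(care)) * (surv - mean(surv))) / 5
  expect_equal(ell$cov[1, 2], cov_hand, tolerance = 1e-10)
  expect_false(ell$degenerate)
  expect_equal(sort(ell$semi_axes^2, decreasing = TRUE),
               sort(eigen(cov(cbind(care, surv)))$values, decreasing = TRUE),
               tolerance = 1e-10)

  # collinear points: perfect correlation, zero minor axis, flagged
  gm2 <- data.frame(care = c(0, 1, 2), survival = c(0, 1, 2))
  ell2 <- care_survival_ellipse(gm2)
  expect_equal(ell2$correlation, 1)
  expect_equal(ell2$semi_axes[2], 0)
  expect_true(ell2$degenerate)

  # identical points: zero matrix, degenerate
  gm3 <- data.frame(care = rep(5, 4), survival = rep(7, 4))
  ell3 <- care_survival_ellipse(gm3)
  expect_equal(unname(ell3$cov), matrix(0, 2, 2))
  expect_true(ell3$degenerate)

  expect_error(care_survival_ellipse(gm3[1:2, ]),
               class = "cueload_invalid_data")
})

test_that("competition ordering of the fitness cost follows the interaction sign", {
  set.seed(55)
  n <- 30
  m <- cbind(`(Intercept)` = rnorm(n, 2, 0.2),
             cross_typeinbred = rnorm(n, -1, 0.2),
             C = rnorm(n, -0.3, 0.05),
             `cross_typeinbred:C` = -abs(rnorm(n, 0.2, 0.05)))
  dr <- fake_survival_draws(m)
  d0 <- delta_omega_posterior(dr, 0)
  d6 <- delta_omega_posterior(dr, 6)
  # negative interaction in every draw: cost at c = 6 exceeds cost at c = 0
  expect_true(all(d6$draws > d0$draws))
})
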