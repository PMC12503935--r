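# Generators: design arithmetic, determinism, bounds, and null behaviour.

test_that("design arithmetic matches the study dimensions", {
  expect_equal(n_female_observations(behavior_design()), 66000)
  expect_equal(n_female_observations(behavior_design(
    n_trials = 18, cross_types = c("inbred", "outbred"))), 27000)

  d <- behavior_design(n_trials = 4, runs = 3, obs_per_run = 7)
  b <- gen_behavior(d, seed = 1)
  expect_equal(nrow(b), 4 * 3 * 3 * 7)

  # egg experiment: one five-female group per trial
  e <- gen_eggs(behavior_design(n_trials = 96), seed = 1)
  expect_equal(length(unique(e$trial_id)) * 5, 480)
  expect_equal(nrow(e), 96 * 5)

  s <- gen_survival(survival_design(), seed = 1)
  expect_equal(nrow(s), 2450)
  expect_equal(length(unique(s$duo_id)), 60)

  f <- gen_fecundity(15, seed = 1)
  expect_equal(nrow(f), 105)
  expect_equal(length(unique(f$cross_label)), 7)
})

test_that("invalid designs and parameters are rejected", {
  expect_error(behavior_design(n_trials = 0), class = "cueload_invalid_design")
  expect_error(behavior_design(treatments = "sometimes"),
               class = "cueload_invalid_design")
  expect_error(behavior_params(sd_trial = -1),
               class = "cueload_invalid_params")
  expect_error(egg_params(uninfested = list(intercept = NA)),
               class = "cueload_invalid_params")
  expect_error(survival_params(p_focal = c(0.5, 0.6)),
               class = "cueload_invalid_params")
  expect_error(survival_design(beans_total = 10),
               class = "cueload_invalid_design")
  expect_error(fecundity_params(reduction = 1.2),
               class = "cueload_invalid_params")
})

test_that("identical seeds reproduce tables exactly; different seeds differ", {
  d <- behavior_design(n_trials = 3)
  expect_identical(gen_behavior(d, seed = 9), gen_behavior(d, seed = 9))
  expect_false(identical(gen_behavior(d, seed = 9),
                         gen_behavior(d, seed = 10)))
  sd_ <- survival_design(beans_total = 300)
  expect_identical(gen_survival(sd_, seed = 4), gen_survival(sd_, seed = 4))
  expect_identical(gen_eggs(d, seed = 2), gen_eggs(d, seed = 2))
  expect_identical(gen_fecundity(10, seed = 3), gen_fecundity(10, seed = 3))
})

test_that("generated counts respect their binomial bounds", {
  for (seed in 1:5) {
    b <- gen_behavior(behavior_design(n_trials = 2), seed = seed)
    expect_true(all(b$n_on_uninfested >= 0 & b$n_on_uninfested <= b$n_females))
    s <- gen_survival(survival_design(beans_total = 200), seed = seed)
    expect_true(all(s$n_focal_emerged >= 0 &
                      s$n_focal_emerged <= s$n_focal_eggs))
    expect_true(all(s$n_competitor_eggs %in% 0:4))
  }
})

test_that("null parameters give a pooled patch occupancy near one half", {
  p0 <- behavior_params(intercept = 0, time1 = 0, time2 = 0, run1 = 0,
                        run2 = 0,
                        treatment = c(reliable = 0, unreliable = 0),
                        treatment_time1 = c(reliable = 0, unreliable = 0),
                        treatment_time2 = c(reliable = 0, unreliable = 0),
                        treatment_run1 = c(reliable = 0, unreliable = 0),
                        treatment_run2 = c(reliable = 0, unreliable = 0),
                        treatment_run_time = c(reliable = 0, unreliable = 0),
                        line = c(line2 = 0, line3 = 0), inbred = 0,
                        inbred_treatment = c(reliable = 0, unreliable = 0),
                        inbred_run = 0, sd_trial = 0, sd_group = 0)
  b <- gen_behavior(behavior_design(n_trials = 10), p0, seed = 21)
  n <- sum(b$n_females)
  phat <- sum(b$n_on_uninfested) / n
  # 4 binomial standard errors around 0.5 (false-alarm rate ~6e-5)
  expect_lt(abs(phat - 0.5), 4 * sqrt(0.25 / n))
})

test_that("degenerate and symmetric egg rates behave as stated", {
  d <- behavior_design(n_trials = 12)
  # zero infested rate: every egg lands on uninfested seeds
  p_zero <- egg_params(infested = list(
    intercept = -Inf, treatment = c(reliable = 0, unreliable = 0),
    run1 = 0, inbred = 0,
    inbred_treatment = c(reliable = 0, unreliable = 0)))
  e <- gen_eggs(d, p_zero, seed = 3)
  expect_true(all(e$eggs_infested == 0))
  expect_true(sum(e$eggs_uninfested) > 0)

  # equal rates, zero effects: fraction on uninfested near one half
  p_eq <- egg_params(
    uninfested = list(intercept = log(5),
                      treatment = c(reliable = 0, unreliable = 0),
                      run1 = 0, inbred = 0,
                      inbred_treatment = c(reliable = 0, unreliable = 0)),
    infested = list(intercept = log(5),
                    treatment = c(reliable = 0, unreliable = 0),
                    run1 = 0, inbred = 0,
                    inbred_treatment = c(reliable = 0, unreliable = 0)),
    sd_trial = 0)
  e2 <- gen_eggs(behavior_design(n_trials = 200, runs = 1), p_eq, seed = 8)
  frac <- sum(e2$eggs_uninfested) /
    sum(e2$eggs_uninfested + e2$eggs_infested)
  expect_lt(abs(frac - 0.5), 0.03)
})

test_that("survival generator recovers its null and sign structure", {
  # null slopes: mean emergence near inverse-logit of the intercept
  p_null <- survival_params(intercept = 1, inbred = 0, competition = 0,
                            inbred_competition = 0, sd_duo = 0)
  s <- gen_survival(survival_design(beans_total = 2000), p_null, seed = 13)
  s <- s[s$n_focal_eggs > 0, ]
  rate <- sum(s$n_focal_emerged) / sum(s$n_focal_eggs)
  expect_lt(abs(rate - stats::plogis(1)), 0.03)

  # negative competition slope: survival lower at level 4 than level 0
  s2 <- gen_survival(survival_design(beans_total = 2450),
                     survival_params(), seed = 14)
  s2 <- s2[s2$n_focal_eggs > 0, ]
  lev <- s2$n_competitor_eggs
  r0 <- sum(s2$n_focal_emerged[lev == 0]) / sum(s2$n_focal_eggs[lev == 0])
  r4 <- sum(s2$n_focal_emerged[lev == 4]) / sum(s2$n_focal_eggs[lev == 4])
  expect_gt(sum(lev %in% c(0, 4)), 500)
  expect_lt(r4, r0)
})

test_that("fecundity generator recovers the inbreeding reduction", {
  # zero reduction: inbred and outbred means indistinguishable
  f0 <- gen_fecundity(300, fecundity_params(reduction = 0), seed = 31)
  inb <- grepl("-inbred$", f0$cross_label)
  outb <- grepl("-outbred$", f0$cross_label)
  expect_lt(abs(mean(f0$hatched_eggs[inb]) / mean(f0$hatched_eggs[outb]) - 1),
            0.05)

  # reduction 0.575 recovered within 0.05 at large n
  f <- gen_fecundity(1000, fecundity_params(reduction = 0.575), seed = 32)
  est <- inbreeding_depression(f, n_boot = 200, seed = 1)
  pooled <- est$estimate[est$line == "pooled"]
  expect_lt(abs(pooled - 0.575), 0.05)
})
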