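# Transformations from fitted/posterior model quantities to selection
# estimates: inbreeding fitness cost at a given competition level
# (delta_omega), egg-weighted expected offspring production (omega) and the
# per-treatment genome-wide selection coefficient s = 1 - omega_I/omega_O,
# fecundity-based inbreeding depression, and the genotype-level covariance
# between maternal care and offspring survival (the indirect-genetic-effect
# summary).

#' Container for a posterior selection estimate
#'
#' @param label quantity name (e.g. `"delta_omega_c0"` or `"s_reliable"`).
#' @param draws numeric vector of per-posterior-draw values.
#' @return object of class `cueload_selection_estimate` with the draws,
#'   their posterior mean and the equal-tail 95% credible interval.
#' @export
selection_estimate <- function(label, draws) {
  draws <- as.numeric(draws)
  structure(
    list(label = label, draws = draws, mean = mean(draws),
         ci = stats::quantile(draws, c(0.025, 0.975), names = FALSE)),
    class = "cueload_selection_estimate"
  )
}

#' @export
print.cueload_selection_estimate <- function(x, ...) {
  cat(sprintf("%s = %.3f (95%% CI: %.3f-%.3f; %d draws)\n",
              x$label, x$mean, x$ci[1], x$ci[2], length(x$draws)))
  invisible(x)
}

#' Per-draw survival probability at a competition level
#'
#' Back-transforms each posterior draw of the survival model to the
#' probability scale at a given cross type and competition level `c`
#' (the number of other eggs sharing the focal egg's seed). Probabilities
#' are clamped into `(1e-15, 1 - 1e-15)` so downstream ratios stay finite.
#'
#' @param draws survival-model `cueload_draws` (fixed effects must include
#'   intercept, inbreeding, competition `C` and their interaction).
#' @param cross_type `"inbred"` or `"outbred"`.
#' @param c competition level; must lie in `[0, c_max]`.
#' @param c_max admissible upper bound (default 6, the observed maximum).
#' @return numeric vector, one probability per stored draw.
#' @export
viability_at <- function(draws, cross_type = c("inbred", "outbred"), c,
                         c_max = 6) {
  cross_type <- match.arg(cross_type)
  if (!is.numeric(c) || length(c) != 1 || c < 0 || c > c_max)
    stop_cueload(sprintf("competition level must lie in [0, %g]", c_max),
                 "cueload_invalid_competition")
  nd <- data.frame(cross_type = factor(cross_type,
                                       levels = draws$design$xlevels$cross_type
                                       %||% c("outbred", "inbred")),
                   C = c)
  eta <- drop(posterior_linpred(draws, nd))
  invlogit(eta)
}

#' Relative fitness cost of inbreeding
#'
#' `1 - v_inbred / v_outbred`: the proportional viability deficit of inbred
#' offspring. Negative values (inbred superiority) are returned unclamped.
#'
#' @param v_inbred,v_outbred viabilities (vectors are paired elementwise);
#'   `v_outbred` must be positive.
#' @return numeric; carries attribute `negative_cost = TRUE` if any value
#'   is negative.
#' @export
delta_omega <- function(v_inbred, v_outbred) {
  if (any(v_outbred == 0))
    stop_cueload("delta_omega undefined at v_outbred = 0",
                 "cueload_undefined_ratio")
  out <- 1 - v_inbred / v_outbred
  if (any(out < 0)) attr(out, "negative_cost") <- TRUE
  out
}

#' Posterior inbreeding fitness cost at a competition level
#'
#' Applies [delta_omega()] to each posterior draw's inbred and outbred
#' viabilities at level `c` and summarises with the posterior mean and
#' equal-tail 95% credible interval.
#'
#' @inheritParams viability_at
#' @return a [selection_estimate()] labelled `delta_omega_c<c>`.
#' @export
delta_omega_posterior <- function(draws, c, c_max = 6) {
  v_i <- viability_at(draws, "inbred", c, c_max)
  v_o <- viability_at(draws, "outbred", c, c_max)
  selection_estimate(paste0("delta_omega_c", c),
                     as.numeric(delta_omega(v_i, v_o)))
}

#' Egg-weighted expected offspring production
#'
#' `omega = eggs_uninfested * v0 + eggs_infested * v3`: eggs on uninfested
#' seeds weighted by no-competition survival and eggs on infested seeds by
#' survival at three competitors (the mean competitor load on infested
#' seeds).
#'
#' @param eggs_uninfested,eggs_infested non-negative egg counts.
#' @param v0,v3 survival probabilities in `(0, 1)`.
#' @return numeric omega; carries attribute `degenerate = TRUE` where both
#'   egg counts are zero.
#' @export
expected_fitness <- function(eggs_uninfested, eggs_infested, v0, v3) {
  if (any(eggs_uninfested < 0) || any(eggs_infested < 0))
    stop_cueload("egg counts must be >= 0", "cueload_invalid_params")
  if (any(v0 <= 0 | v0 >= 1) || any(v3 <= 0 | v3 >= 1))
    stop_cueload("survival probabilities must lie in (0, 1)",
                 "cueload_invalid_params")
  out <- eggs_uninfested * v0 + eggs_infested * v3
  if (any(eggs_uninfested + eggs_infested == 0))
    attr(out, "degenerate") <- TRUE
  out
}

#' Genome-wide selection coefficient against revealed deleterious alleles
#'
#' `s = 1 - omega_inbred / omega_outbred`: the proportional reduction in
#' egg-weighted expected offspring production caused by genome-wide
#' homozygosity, per cue treatment.
#'
#' @param omega_inbred,omega_outbred expected offspring production;
#'   `omega_outbred` must be positive.
#' @return numeric selection coefficient(s).
#' @export
selection_coefficient <- function(omega_inbred, omega_outbred) {
  if (any(omega_outbred == 0))
    stop_cueload("selection coefficient undefined at omega_outbred = 0",
                 "cueload_undefined_ratio")
  1 - omega_inbred / omega_outbred
}

#' Posterior expected egg counts per treatment and cross type
#'
#' Evaluates the two egg-channel posteriors (Poisson models for eggs on
#' uninfested and on infested seeds) at every treatment x cross-type cell,
#' with any other covariates at reference values, giving per-draw expected
#' per-run egg counts. These are the egg weights entering
#' [treatment_selection()].
#'
#' @param draws_uninfested,draws_infested `cueload_draws` from the two
#'   Poisson egg models (same fixed-effect structure).
#' @param treatments treatment levels to evaluate.
#' @param at named list of reference values for further covariates in the
#'   egg models (default `run_c = 0`, the mid run).
#' @return object of class `cueload_egg_expectation`: arrays
#'   `uninfested` and `infested` of dimension draws x treatments x
#'   cross types.
#' @export
egg_expectation_draws <- function(draws_uninfested, draws_infested,
                                  treatments = c("none", "reliable",
                                                 "unreliable"),
                                  at = list(run_c = 0)) {
  cross_types <- c("outbred", "inbred")
  grid <- expand.grid(treatment = treatments, cross_type = cross_types,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (nm in names(at)) grid[[nm]] <- at[[nm]]
  make_arr <- function(draws) {
    lam <- exp(posterior_linpred(draws, grid))
    array(lam, dim = c(nrow(lam), length(treatments), length(cross_types)),
          dimnames = list(NULL, treatments, cross_types))
  }
  structure(list(uninfested = make_arr(draws_uninfested),
                 infested = make_arr(draws_infested),
                 treatments = treatments),
            class = "cueload_egg_expectation")
}

#' Per-treatment selection coefficients with pairwise contrasts
#'
#' For each posterior draw and cue treatment, builds the egg-weighted
#' fitness of inbred and outbred genotypes (eggs per seed class weighted by
#' survival at zero and three competitors from the survival posterior) and
#' the selection coefficient `s = 1 - omega_I / omega_O`; summarises each
#' treatment's s and every pairwise difference with its two-sided posterior
#' tail probability ([pmcmc()]).
#'
#' Draws of the egg and survival models are paired by index. If the chains
#' differ in length the longer one is thinned deterministically when
#' `match_draws = TRUE`; otherwise a mismatch is an error.
#'
#' @param egg_draws an [egg_expectation_draws()] object.
#' @param survival_draws survival-model `cueload_draws`.
#' @param match_draws thin the longer chain to the shorter one?
#' @param c_infested competition level assigned to eggs on infested seeds
#'   (default 3).
#' @return object of class `cueload_treatment_selection` with `estimates`
#'   (one [selection_estimate()] per treatment), `s_draws`, `omega_inbred`
#'   and `omega_outbred` (draws x treatment matrices), and `contrasts`
#'   (data frame with mean difference, 95% CI and `p_mcmc`).
#' @export
treatment_selection <- function(egg_draws, survival_draws,
                                match_draws = FALSE, c_infested = 3) {
  stopifnot(inherits(egg_draws, "cueload_egg_expectation"))
  n_egg <- dim(egg_draws$uninfested)[1]
  n_sur <- nrow(survival_draws$draws)
  if (n_egg != n_sur && !match_draws)
    stop_cueload(sprintf(
      "egg (%d) and survival (%d) draw counts differ; set match_draws = TRUE",
      n_egg, n_sur), "cueload_draw_mismatch")
  n <- min(n_egg, n_sur)
  idx_egg <- round(seq(1, n_egg, length.out = n))
  idx_sur <- round(seq(1, n_sur, length.out = n))

  v0_i <- viability_at(survival_draws, "inbred", 0)[idx_sur]
  v3_i <- viability_at(survival_draws, "inbred", c_infested)[idx_sur]
  v0_o <- viability_at(survival_draws, "outbred", 0)[idx_sur]
  v3_o <- viability_at(survival_draws, "outbred", c_infested)[idx_sur]

  treatments <- egg_draws$treatments
  dn <- list(NULL, treatments)
  omega_inbred <- omega_outbred <- matrix(NA_real_, n, length(treatments),
                                          dimnames = dn)
  for (j in treatments) {
    omega_inbred[, j] <- expected_fitness(
      egg_draws$uninfested[idx_egg, j, "inbred"],
      egg_draws$infested[idx_egg, j, "inbred"], v0_i, v3_i)
    omega_outbred[, j] <- expected_fitness(
      egg_draws$uninfested[idx_egg, j, "outbred"],
      egg_draws$infested[idx_egg, j, "outbred"], v0_o, v3_o)
  }
  s_draws <- matrix(selection_coefficient(omega_inbred, omega_outbred),
                    ncol = length(treatments), dimnames = dn)

  estimates <- lapply(treatments, function(j)
    selection_estimate(paste0("s_", j), s_draws[, j]))
  names(estimates) <- treatments

  pairs <- utils::combn(treatments, 2, simplify = FALSE)
  contrasts <- do.call(rbind, lapply(pairs, function(pr) {
    d <- s_draws[, pr[1]] - s_draws[, pr[2]]
    data.frame(treatment_a = pr[1], treatment_b = pr[2],
               mean = mean(d),
               q2.5 = stats::quantile(d, 0.025, names = FALSE),
               q97.5 = stats::quantile(d, 0.975, names = FALSE),
               p_mcmc = if (max(d) == min(d) && d[1] == 0) 1 else pmcmc(d),
               stringsAsFactors = FALSE)
  }))

  structure(list(estimates = estimates, s_draws = s_draws,
                 omega_inbred = omega_inbred, omega_outbred = omega_outbred,
                 contrasts = contrasts, c_infested = c_infested),
            class = "cueload_treatment_selection")
}

#' @export
print.cueload_treatment_selection <- function(x, ...) {
  for (e in x$estimates) print(e)
  cat("pairwise contrasts:\n")
  print(cbind(x$contrasts[1:2],
              round(x$contrasts[c("mean", "q2.5", "q97.5", "p_mcmc")], 4)))
  invisible(x)
}

#' Fecundity-based inbreeding depression
#'
#' Per line, `1 - mean(inbred) / mean(outbred)` from hatched-egg counts
#' (inbred line `i` against the corresponding between-line cross `i`), plus
#' a pooled estimate across lines, with seeded percentile-bootstrap
#' confidence intervals (females resampled within cross label).
#'
#' @param fecundity_table data frame with `cross_label` and `hatched_eggs`
#'   (as from [gen_fecundity()]); at least 2 females per cross.
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return data frame with columns `line`, `estimate`, `ci_lo`, `ci_hi`;
#'   the last row (`line = "pooled"`) pools all lines.
#' @export
inbreeding_depression <- function(fecundity_table, n_boot = 2000, seed = 1,
                                  conf = 0.95) {
  stopifnot(all(c("cross_label", "hatched_eggs") %in% names(fecundity_table)))
  inb_labels <- sort(grep("-inbred$", unique(fecundity_table$cross_label),
                          value = TRUE))
  out_labels <- sort(grep("-outbred$", unique(fecundity_table$cross_label),
                          value = TRUE))
  if (length(inb_labels) != length(out_labels) || !length(inb_labels))
    stop_cueload("need matching inbred and outbred cross labels",
                 "cueload_invalid_data")
  counts <- table(fecundity_table$cross_label)
  if (any(counts[c(inb_labels, out_labels)] < 2))
    stop_cueload("need >= 2 females per cross", "cueload_invalid_data")
  set.seed(seed)
  alpha <- (1 - conf) / 2
  one <- function(inb, outb) {
    xi <- fecundity_table$hatched_eggs[fecundity_table$cross_label %in% inb]
    xo <- fecundity_table$hatched_eggs[fecundity_table$cross_label %in% outb]
    if (mean(xo) == 0)
      stop_cueload("zero outbred mean fecundity", "cueload_undefined_ratio")
    est <- 1 - mean(xi) / mean(xo)
    boot <- replicate(n_boot, {
      1 - mean(sample(xi, replace = TRUE)) / mean(sample(xo, replace = TRUE))
    })
    c(est, stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE))
  }
  rows <- lapply(seq_along(inb_labels), function(i)
    one(inb_labels[i], out_labels[i]))
  rows <- c(rows, list(one(inb_labels, out_labels)))
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("estimate", "ci_lo", "ci_hi")
  out <- cbind(line = c(sub("-inbred$", "", inb_labels), "pooled"), out)
  rownames(out) <- NULL
  out
}

#' Genotype means of maternal care and expected offspring survival
#'
#' For each treatment x line x cross-type cell, maternal care is the
#' percentage of the cell's eggs laid on uninfested seeds, and expected
#' survival is that egg split weighted by the posterior-mean viabilities of
#' the cell's cross type at zero and `c_infested` competitors.
#'
#' @param egg_table egg records (as from [gen_eggs()]) covering both cross
#'   types.
#' @param survival_draws survival-model `cueload_draws`.
#' @param c_infested competition level for eggs on infested seeds.
#' @return data frame with columns `treatment, line_id, cross_type, care,
#'   survival` (both in percent).
#' @export
genotype_means <- function(egg_table, survival_draws, c_infested = 3) {
  v <- list(
    inbred = c(v0 = mean(viability_at(survival_draws, "inbred", 0)),
               v3 = mean(viability_at(survival_draws, "inbred", c_infested))),
    outbred = c(v0 = mean(viability_at(survival_draws, "outbred", 0)),
                v3 = mean(viability_at(survival_draws, "outbred", c_infested)))
  )
  agg <- stats::aggregate(
    cbind(eggs_uninfested, eggs_infested) ~ treatment + line_id + cross_type,
    data = egg_table, FUN = sum)
  tot <- agg$eggs_uninfested + agg$eggs_infested
  if (any(tot == 0))
    stop_cueload("a genotype cell laid no eggs", "cueload_invalid_data")
  phi <- agg$eggs_uninfested / tot
  vv <- do.call(rbind, v[agg$cross_type])
  agg$care <- 100 * phi
  agg$survival <- 100 * (phi * vv[, "v0"] + (1 - phi) * vv[, "v3"])
  agg[order(agg$treatment, agg$line_id, agg$cross_type),
      c("treatment", "line_id", "cross_type", "care", "survival")]
}

#' Care-survival covariance and confidence ellipse per treatment
#'
#' The sample covariance of (care, survival) across a treatment's genotype
#' means, and the one-standard-deviation ("68%") ellipse from its
#' eigendecomposition. The sign of the covariance is the direction of the
#' indirect genetic effect of maternal genotype on offspring survival.
#'
#' @param genotype_means data frame with columns `care` and `survival`
#'   (percentages), one row per genotype; at least 3 rows.
#' @return object of class `cueload_ellipse`: `center`, `cov`,
#'   `correlation`, `semi_axes` (major, minor), `angle` (radians of the
#'   major axis), `degenerate` flag.
#' @export
care_survival_ellipse <- function(genotype_means) {
  stopifnot(all(c("care", "survival") %in% names(genotype_means)))
  m <- as.matrix(genotype_means[, c("care", "survival")])
  if (nrow(m) < 3)
    stop_cueload("need >= 3 genotype means", "cueload_invalid_data")
  center <- colMeans(m)
  S <- stats::cov(m)
  ev <- eigen(S, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  degenerate <- vals[2] <= max(vals[1], 1) * 1e-12
  corr <- if (any(diag(S) == 0)) NA_real_ else stats::cov2cor(S)[1, 2]
  structure(
    list(center = center, cov = S, correlation = corr,
         semi_axes = sqrt(vals), angle = atan2(ev$vectors[2, 1],
                                               ev$vectors[1, 1]),
         degenerate = degenerate, n = nrow(m)),
    class = "cueload_ellipse"
  )
}

#' @export
print.cueload_ellipse <- function(x, ...) {
  cat(sprintf(
    "care-survival ellipse: center (%.1f, %.1f), cov %.2f, axes (%.2f, %.2f)%s\n",
    x$center[1], x$center[2], x$cov[1, 2], x$semi_axes[1], x$semi_axes[2],
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
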