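# Synthetic-data generators for the four experimental designs: grouped
# behavioural observations in an arena (counts of females on the
# uninfested-host patch), group-level egg placement on uninfested vs
# infested seeds, bean-level larval survival under interspecific
# competition, and female fecundity by cross type. Data are generated
# directly at the observation-model level (binomial/Poisson with Gaussian
# random intercepts on the link scale), i.e. with exactly the statistical
# structure the downstream mixed models assume.

#' Behavioural-trial design
#'
#' One trial assays `length(treatments)` groups of `females_per_group`
#' females (one group per cue treatment) over `runs` arena exposures with
#' `obs_per_run` location scans each. The default dimensions (44 trials, 3
#' treatments, 5 females, 5 runs, 20 scans) give 660 females and 66,000
#' female-observations. Lines cycle across trials; when both cross types are
#' requested, the first half of the trials uses inbred females and the
#' second half outbred (9 + 9 trials at the default for that experiment,
#' i.e. 270 females and 27,000 observations with `n_trials = 18`).
#'
#' @param n_trials number of trials (arenas x treatment triplets).
#' @param treatments environmental-cue treatments.
#' @param females_per_group females per arena group.
#' @param runs consecutive arena exposures per group.
#' @param obs_per_run location scans per run (20 = every 30 s for 10 min).
#' @param lines genetic line identifiers.
#' @param cross_types `"outbred"` only, or both `"inbred"` and `"outbred"`.
#' @return list of class `cueload_behavior_design`.
#' @export
behavior_design <- function(n_trials = 44,
                            treatments = c("none", "reliable", "unreliable"),
                            females_per_group = 5, runs = 5, obs_per_run = 20,
                            lines = c("line1", "line2", "line3"),
                            cross_types = "outbred") {
  n_trials <- assert_count(n_trials, "n_trials", 1L)
  females_per_group <- assert_count(females_per_group, "females_per_group", 1L)
  runs <- assert_count(runs, "runs", 1L)
  obs_per_run <- assert_count(obs_per_run, "obs_per_run", 1L)
  treatments <- unique(as.character(treatments))
  if (length(treatments) < 1 ||
      !all(treatments %in% c("none", "reliable", "unreliable")))
    stop_cueload("treatments must be drawn from none/reliable/unreliable",
                 "cueload_invalid_design")
  if (!all(cross_types %in% c("inbred", "outbred")) || !length(cross_types))
    stop_cueload("cross_types must be inbred and/or outbred",
                 "cueload_invalid_design")
  if (length(lines) < 1)
    stop_cueload("at least one line is required", "cueload_invalid_design")
  structure(list(n_trials = n_trials, treatments = treatments,
                 females_per_group = females_per_group, runs = runs,
                 obs_per_run = obs_per_run, lines = as.character(lines),
                 cross_types = unique(as.character(cross_types))),
            class = "cueload_behavior_design")
}

#' Total female-observations implied by a behavioural design
#' @param design a [behavior_design()].
#' @return integer: trials x treatments x females x runs x scans.
#' @export
n_female_observations <- function(design) {
  with(design, n_trials * length(treatments) * females_per_group *
         runs * obs_per_run)
}

#' Generator coefficients for the behavioural observation model
#'
#' Logit-scale coefficients of the probability that a female is on the
#' uninfested-host patch. Time within run and run number enter through the
#' centred, scaled covariates `time_c, run_c` in `[-1, 1]` (see
#' [scale_run_time()]). Treatment effects are relative to the no-cue
#' reference. The defaults qualitatively reproduce the published behaviour:
#' occupancy of the good patch rises and saturates within a run, improves
#' across runs (learning), is highest with a reliable cue, and the inbred
#' deficit shrinks across runs and under a reliable cue. They are
#' calibration defaults, not fitted values.
#'
#' @param intercept logit occupancy at treatment none, mid run, mid time.
#' @param time1,time2 linear/quadratic time-within-run trend.
#' @param run1,run2 linear/quadratic across-run (learning) trend.
#' @param treatment named main effects for `reliable`/`unreliable`.
#' @param treatment_time1,treatment_time2,treatment_run1,treatment_run2
#'   treatment x trend interactions (named like `treatment`).
#' @param treatment_run_time treatment x run_c x time_c interaction.
#' @param line named line effects (first line is the reference).
#' @param inbred inbreeding main effect (logit deficit of inbred females).
#' @param inbred_treatment named inbreeding x treatment interaction.
#' @param inbred_run inbreeding x run_c interaction (deficit shrinking
#'   across runs when positive).
#' @param sd_trial,sd_group standard deviations of the trial-level and
#'   trial-x-treatment-level random intercepts (logit scale, >= 0).
#' @return list of class `cueload_behavior_params`.
#' @export
behavior_params <- function(intercept = -0.8,
                            time1 = 1.2, time2 = -0.35,
                            run1 = 0.6, run2 = -0.1,
                            treatment = c(reliable = 0.45, unreliable = -0.25),
                            treatment_time1 = c(reliable = 0.25, unreliable = 0),
                            treatment_time2 = c(reliable = -0.15, unreliable = 0),
                            treatment_run1 = c(reliable = 0.3, unreliable = -0.05),
                            treatment_run2 = c(reliable = 0, unreliable = 0),
                            treatment_run_time = c(reliable = 0.1, unreliable = 0),
                            line = c(line2 = 0.1, line3 = -0.1),
                            inbred = -0.5,
                            inbred_treatment = c(reliable = 0.2, unreliable = 0),
                            inbred_run = 0.25,
                            sd_trial = 0.35, sd_group = 0.25) {
  p <- list(intercept = intercept, time1 = time1, time2 = time2,
            run1 = run1, run2 = run2, treatment = treatment,
            treatment_time1 = treatment_time1,
            treatment_time2 = treatment_time2,
            treatment_run1 = treatment_run1,
            treatment_run2 = treatment_run2,
            treatment_run_time = treatment_run_time,
            line = line, inbred = inbred,
            inbred_treatment = inbred_treatment, inbred_run = inbred_run,
            sd_trial = sd_trial, sd_group = sd_group)
  if (sd_trial < 0 || sd_group < 0)
    stop_cueload("random-effect sds must be >= 0", "cueload_invalid_params")
  structure(p, class = "cueload_behavior_params")
}

lookup0 <- function(v, keys) {
  out <- v[keys]
  out[is.na(out)] <- 0
  unname(out)
}

#' Centred, scaled run and time covariates
#'
#' Adds `run_c` and `time_c` columns mapping the observed `run` and
#' `time_index` ranges linearly onto `[-1, 1]` (midpoint 0). This is the
#' covariate coding the generators use, so fitting on these columns makes
#' fitted coefficients directly comparable with generator parameters.
#'
#' @param df data frame with `run` and (optionally) `time_index` columns.
#' @return `df` with `run_c` (and `time_c` if available) appended.
#' @export
scale_run_time <- function(df) {
  center_scale <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) return(rep(0, length(x)))
    2 * (x - r[1]) / (r[2] - r[1]) - 1
  }
  df$run_c <- center_scale(df$run)
  if (!is.null(df$time_index)) df$time_c <- center_scale(df$time_index)
  df
}

# per-trial line/cross assignment shared by gen_behavior and gen_eggs
trial_frame <- function(design) {
  n <- design$n_trials
  data.frame(
    trial_id = sprintf("T%03d", seq_len(n)),
    line_id = rep_len(design$lines, n),
    cross_type = if (length(design$cross_types) == 1) design$cross_types
                 else rep(design$cross_types,
                          times = c(ceiling(n / 2), floor(n / 2))),
    stringsAsFactors = FALSE
  )
}

behavior_linpred <- function(df, params) {
  tr <- df$treatment
  inb <- as.numeric(df$cross_type == "inbred")
  params$intercept +
    params$time1 * df$time_c + params$time2 * df$time_c^2 +
    params$run1 * df$run_c + params$run2 * df$run_c^2 +
    lookup0(params$treatment, tr) +
    lookup0(params$treatment_time1, tr) * df$time_c +
    lookup0(params$treatment_time2, tr) * df$time_c^2 +
    lookup0(params$treatment_run1, tr) * df$run_c +
    lookup0(params$treatment_run2, tr) * df$run_c^2 +
    lookup0(params$treatment_run_time, tr) * df$run_c * df$time_c +
    lookup0(params$line, df$line_id) +
    inb * (params$inbred +
             lookup0(params$inbred_treatment, tr) +
             params$inbred_run * df$run_c)
}

#' Generate behavioural arena observations
#'
#' One row per arena group x run x scan: the number of the group's females
#' found on the uninfested-host patch, drawn binomially with a logit-linear
#' success probability built from `params` plus trial-level and
#' trial-x-treatment-level Gaussian random intercepts. Identical
#' `(design, params, seed)` give an identical table.
#'
#' @param design a [behavior_design()].
#' @param params a [behavior_params()].
#' @param seed integer seed.
#' @return data frame with columns `trial_id, treatment, line_id,
#'   cross_type, run, time_index, n_on_uninfested, n_females`.
#' @export
gen_behavior <- function(design, params = behavior_params(), seed = 1) {
  stopifnot(inherits(design, "cueload_behavior_design"),
            inherits(params, "cueload_behavior_params"))
  set.seed(seed)
  trials <- trial_frame(design)
  df <- expand.grid(time_index = seq_len(design$obs_per_run),
                    run = seq_len(design$runs),
                    treatment = design$treatments,
                    trial_id = trials$trial_id,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[, c("trial_id", "treatment", "run", "time_index")]
  df <- merge(df, trials, by = "trial_id", sort = FALSE)
  df <- df[order(df$trial_id, df$treatment, df$run, df$time_index), ]
  rownames(df) <- NULL
  df <- scale_run_time(df)

  u_trial <- stats::rnorm(nrow(trials), 0, params$sd_trial)
  names(u_trial) <- trials$trial_id
  grp <- paste(df$trial_id, df$treatment, sep = "|")
  grp_levels <- unique(grp)
  u_group <- stats::rnorm(length(grp_levels), 0, params$sd_group)
  names(u_group) <- grp_levels

  eta <- behavior_linpred(df, params) + u_trial[df$trial_id] + u_group[grp]
  df$n_on_uninfested <- stats::rbinom(nrow(df), design$females_per_group,
                                      invlogit(eta))
  df$n_females <- design$females_per_group
  df[, c("trial_id", "treatment", "line_id", "cross_type", "run",
         "time_index", "n_on_uninfested", "n_females")]
}

#' Generator coefficients for group-level egg placement
#'
#' Log-linear Poisson rates for the number of eggs a five-female group lays
#' per run on uninfested (`uninfested`) and infested (`infested`) seeds.
#' Each channel has an intercept (log rate at treatment none, outbred, mid
#' run), treatment effects, a linear `run_c` slope, an inbreeding effect and
#' an inbreeding x treatment interaction; a shared trial-level Gaussian
#' random intercept acts on both channels. Counts are capped at
#' `max_eggs_per_female` per female per run (a generator convenience that
#' truncates unrealistic Poisson tails). The defaults are calibrated so
#' that, combined with the default survival coefficients, the egg-weighted
#' selection coefficients are about 0.50 (reliable), 0.61 (unreliable) and
#' 0.63 (no cue), mirroring the published ordering.
#'
#' @param uninfested,infested lists with `intercept`, `treatment`,
#'   `run1`, `inbred`, `inbred_treatment`.
#' @param sd_trial trial-level random-intercept sd (log scale).
#' @param max_eggs_per_female cap on eggs per female per run.
#' @return list of class `cueload_egg_params`.
#' @export
egg_params <- function(
    uninfested = list(
      intercept = log(4.5),
      treatment = c(reliable = 0.636, unreliable = 0.105),
      run1 = 0.25, inbred = -0.831,
      inbred_treatment = c(reliable = 0.388, unreliable = 0.059)),
    infested = list(
      intercept = log(5.5),
      treatment = c(reliable = -1.299, unreliable = -0.095),
      run1 = -0.15, inbred = -0.087,
      inbred_treatment = c(reliable = 0.113, unreliable = 0.022)),
    sd_trial = 0.15, max_eggs_per_female = 20) {
  if (sd_trial < 0)
    stop_cueload("sd_trial must be >= 0", "cueload_invalid_params")
  for (ch in list(uninfested, infested)) {
    # -Inf encodes a degenerate zero rate for one channel; NA/NaN/+Inf are
    # parameter errors
    if (is.na(ch$intercept) || ch$intercept == Inf)
      stop_cueload("egg-rate intercepts must be < Inf and non-missing",
                   "cueload_invalid_params")
  }
  structure(list(uninfested = uninfested, infested = infested,
                 sd_trial = sd_trial,
                 max_eggs_per_female = assert_count(max_eggs_per_female,
                                                    "max_eggs_per_female", 1L)),
            class = "cueload_egg_params")
}

egg_rate <- function(df, ch) {
  inb <- as.numeric(df$cross_type == "inbred")
  exp(ch$intercept +
        lookup0(ch$treatment, df$treatment) +
        (ch$run1 %||% 0) * df$run_c +
        inb * ((ch$inbred %||% 0) +
                 lookup0(ch$inbred_treatment %||% numeric(0), df$treatment)))
}

#' Generate group-level egg-placement records
#'
#' One row per trial group x run with Poisson counts of eggs laid on
#' uninfested and infested seeds (complementary channels of the group's
#' output). In the egg experiments each trial is a single five-female group
#' under one cue treatment (the published 96 trials hold 480 females), so
#' treatments cycle across trials. Rates are log-linear in treatment, run
#' and inbreeding with a trial random intercept; see [egg_params()].
#'
#' @param design a [behavior_design()] (e.g. `n_trials = 96` for the
#'   480-female egg experiment).
#' @param params an [egg_params()].
#' @param seed integer seed.
#' @return data frame with columns `trial_id, treatment, line_id,
#'   cross_type, run, eggs_uninfested, eggs_infested`.
#' @export
gen_eggs <- function(design, params = egg_params(), seed = 1) {
  stopifnot(inherits(design, "cueload_behavior_design"),
            inherits(params, "cueload_egg_params"))
  set.seed(seed)
  trials <- trial_frame(design)
  trials$treatment <- rep_len(design$treatments, nrow(trials))
  # lines rotate once per treatment cycle so treatment x line x cross cells
  # are filled evenly rather than confounded
  trials$line_id <- design$lines[
    ((seq_len(nrow(trials)) - 1) %/% length(design$treatments)) %%
      length(design$lines) + 1]
  df <- expand.grid(run = seq_len(design$runs),
                    trial_id = trials$trial_id,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[, c("trial_id", "run")]
  df <- merge(df, trials, by = "trial_id", sort = FALSE)
  df <- df[order(df$trial_id, df$treatment, df$run), ]
  rownames(df) <- NULL
  df <- scale_run_time(df)

  u_trial <- stats::rnorm(nrow(trials), 0, params$sd_trial)
  names(u_trial) <- trials$trial_id
  mult <- exp(u_trial[df$trial_id])
  cap <- params$max_eggs_per_female * design$females_per_group
  df$eggs_uninfested <- pmin(
    stats::rpois(nrow(df), egg_rate(df, params$uninfested) * mult), cap)
  df$eggs_infested <- pmin(
    stats::rpois(nrow(df), egg_rate(df, params$infested) * mult), cap)
  df[, c("trial_id", "treatment", "line_id", "cross_type", "run",
         "eggs_uninfested", "eggs_infested")]
}

#' Larval-survival experiment design
#'
#' Female duos are assigned factorially to line x cross type x competitor
#' infestation level x replicate block; each duo lays on its own set of
#' beans, pre-infested with the duo's competitor-egg level. The defaults (3
#' lines x 2 cross types x 5 levels x 2 replicates = 60 duos, 2450 beans)
#' match the published experiment's totals.
#'
#' @param lines,cross_types,infestation_levels factorial axes.
#' @param replicates duos per cell.
#' @param beans_total beans spread as evenly as possible over duos.
#' @return list of class `cueload_survival_design`.
#' @export
survival_design <- function(lines = c("line1", "line2", "line3"),
                            cross_types = c("inbred", "outbred"),
                            infestation_levels = 0:4,
                            replicates = 2, beans_total = 2450) {
  replicates <- assert_count(replicates, "replicates", 1L)
  beans_total <- assert_count(beans_total, "beans_total", 1L)
  if (!length(lines) || !length(cross_types) || !length(infestation_levels))
    stop_cueload("empty design axis", "cueload_invalid_design")
  if (any(infestation_levels < 0 | infestation_levels != round(infestation_levels)))
    stop_cueload("infestation levels must be non-negative integers",
                 "cueload_invalid_design")
  n_duos <- length(lines) * length(cross_types) *
    length(infestation_levels) * replicates
  if (beans_total < n_duos)
    stop_cueload("fewer beans than duos", "cueload_invalid_design")
  structure(list(lines = as.character(lines),
                 cross_types = as.character(cross_types),
                 infestation_levels = as.integer(infestation_levels),
                 replicates = replicates, beans_total = beans_total,
                 n_duos = n_duos),
            class = "cueload_survival_design")
}

#' Generator coefficients for bean-level larval survival
#'
#' Egg-to-adult survival of focal eggs is binomial per bean with logit
#' probability `intercept + inbred*I + competition*C +
#' inbred_competition*I*C + duo intercept`, where `C` is the competition
#' level experienced by a focal egg (total eggs on its seed minus one).
#' `p_focal` is the distribution of the number of focal eggs per bean
#' (indices 0..4; one egg most common, three rare, more than three very
#' rare). The defaults put outbred no-competition survival near 0.90 and
#' imply an inbreeding fitness cost of about 0.20 at C = 0 and 0.84 at
#' C = 6, the published pattern.
#'
#' @param intercept,inbred,competition,inbred_competition logit-scale
#'   coefficients.
#' @param sd_duo duo-level random-intercept sd (>= 0).
#' @param p_focal probability vector over 0..(length-1) focal eggs per bean.
#' @return list of class `cueload_survival_params`.
#' @export
survival_params <- function(intercept = 2.2, inbred = -1.25,
                            competition = -0.35, inbred_competition = -0.21,
                            sd_duo = 0.3,
                            p_focal = c(0.32, 0.44, 0.16, 0.06, 0.02)) {
  if (sd_duo < 0)
    stop_cueload("sd_duo must be >= 0", "cueload_invalid_params")
  if (any(p_focal < 0) || abs(sum(p_focal) - 1) > 1e-8)
    stop_cueload("p_focal must be a probability vector",
                 "cueload_invalid_params")
  structure(list(intercept = intercept, inbred = inbred,
                 competition = competition,
                 inbred_competition = inbred_competition,
                 sd_duo = sd_duo, p_focal = p_focal),
            class = "cueload_survival_params")
}

#' Generate bean-level larval-survival records
#'
#' One row per bean with the focal-species egg count, the pre-laid
#' competitor egg count (the duo's assigned level) and the number of focal
#' eggs that emerged as adults, drawn binomially under the model in
#' [survival_params()].
#'
#' @param design a [survival_design()].
#' @param params a [survival_params()].
#' @param seed integer seed.
#' @return data frame with columns `duo_id, line_id, cross_type,
#'   n_focal_eggs, n_competitor_eggs, n_focal_emerged`.
#' @export
gen_survival <- function(design, params = survival_params(), seed = 1) {
  stopifnot(inherits(design, "cueload_survival_design"),
            inherits(params, "cueload_survival_params"))
  set.seed(seed)
  duos <- expand.grid(replicate = seq_len(design$replicates),
                      infestation = design$infestation_levels,
                      cross_type = design$cross_types,
                      line_id = design$lines,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  duos$duo_id <- sprintf("D%03d", seq_len(nrow(duos)))
  beans_per_duo <- rep(design$beans_total %/% design$n_duos, design$n_duos)
  extra <- design$beans_total %% design$n_duos
  if (extra > 0) beans_per_duo[seq_len(extra)] <- beans_per_duo[seq_len(extra)] + 1

  df <- duos[rep(seq_len(nrow(duos)), beans_per_duo), ]
  rownames(df) <- NULL
  df$n_focal_eggs <- sample(seq_along(params$p_focal) - 1L, nrow(df),
                            replace = TRUE, prob = params$p_focal)
  df$n_competitor_eggs <- df$infestation

  u_duo <- stats::rnorm(nrow(duos), 0, params$sd_duo)
  names(u_duo) <- duos$duo_id
  inb <- as.numeric(df$cross_type == "inbred")
  C <- pmax(df$n_focal_eggs + df$n_competitor_eggs - 1, 0)
  eta <- params$intercept + params$inbred * inb +
    params$competition * C + params$inbred_competition * inb * C +
    u_duo[df$duo_id]
  df$n_focal_emerged <- stats::rbinom(nrow(df), df$n_focal_eggs, invlogit(eta))
  df[, c("duo_id", "line_id", "cross_type", "n_focal_eggs",
         "n_competitor_eggs", "n_focal_emerged")]
}

#' Generator parameters for female fecundity
#'
#' Hatched-egg counts are negative-binomial with cross-specific means:
#' outbred line crosses at `outbred_mean` times a per-line multiplier,
#' inbred lines at the same multiplied mean reduced by proportion
#' `reduction`, and the stock population at `stock_mean`. The default
#' reduction 0.575 sits mid-way in the published 55-60% fecundity drop.
#'
#' @param outbred_mean mean hatched eggs of outbred line-cross females.
#' @param reduction proportionate inbred fecundity reduction in `[0, 1)`.
#' @param dispersion negative-binomial size parameter (> 0).
#' @param stock_mean mean for the stock population.
#' @param line_multipliers per-line multipliers on both cross types.
#' @return list of class `cueload_fecundity_params`.
#' @export
fecundity_params <- function(outbred_mean = 75, reduction = 0.575,
                             dispersion = 20, stock_mean = 75,
                             line_multipliers = c(1.05, 1, 0.95)) {
  if (outbred_mean <= 0 || stock_mean <= 0 || dispersion <= 0 ||
      any(line_multipliers <= 0))
    stop_cueload("means, multipliers and dispersion must be positive",
                 "cueload_invalid_params")
  if (reduction < 0 || reduction >= 1)
    stop_cueload("reduction must be in [0, 1)", "cueload_invalid_params")
  structure(list(outbred_mean = outbred_mean, reduction = reduction,
                 dispersion = dispersion, stock_mean = stock_mean,
                 line_multipliers = line_multipliers),
            class = "cueload_fecundity_params")
}

#' Generate female fecundity records
#'
#' `n_per_cross` females for each of the seven cross labels: three
#' within-line (inbred) crosses, three between-line (outbred) crosses and
#' the stock population.
#'
#' @param n_per_cross females per cross label (>= 1).
#' @param params a [fecundity_params()].
#' @param seed integer seed.
#' @return data frame with columns `female_id, cross_label, hatched_eggs`.
#' @export
gen_fecundity <- function(n_per_cross = 15, params = fecundity_params(),
                          seed = 1) {
  stopifnot(inherits(params, "cueload_fecundity_params"))
  n_per_cross <- assert_count(n_per_cross, "n_per_cross", 1L)
  set.seed(seed)
  k <- length(params$line_multipliers)
  labels <- c(paste0("line", seq_len(k), "-inbred"),
              paste0("cross", seq_len(k), "-outbred"), "stock")
  means <- c(params$outbred_mean * params$line_multipliers *
               (1 - params$reduction),
             params$outbred_mean * params$line_multipliers,
             params$stock_mean)
  df <- data.frame(
    cross_label = rep(labels, each = n_per_cross),
    mu = rep(means, each = n_per_cross),
    stringsAsFactors = FALSE
  )
  df$female_id <- sprintf("F%04d", seq_len(nrow(df)))
  df$hatched_eggs <- stats::rnbinom(nrow(df), size = params$dispersion,
                                    mu = df$mu)
  df[, c("female_id", "cross_label", "hatched_eggs")]
}
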