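# End-to-end orchestration: simulate -> prepare -> frequentist fits ->
# posterior sampling -> selection estimates -> load curves. All randomness
# derives from one global seed through a fixed per-stage splitting scheme
# (see derive_seed()), so an identical config gives byte-identical outputs.

#' Pipeline configuration
#'
#' Builds the nested configuration list driving [run_pipeline()]. Any
#' element can be overridden; unspecified entries keep the defaults below,
#' which reproduce the study dimensions (44-trial behavioural experiment,
#' 54 cross-typed egg trials, 60 duos on 2450 beans, 15 females per
#' fecundity cross) and the default MCMC schedule (100,000 iterations,
#' 50,000 burn-in, thinning 100: 1000 stored draws).
#'
#' @param seed global integer seed.
#' @param out_dir output directory (created if needed).
#' @param behavior,eggs arguments for [behavior_design()] (the egg design
#'   defaults to both cross types so selection can contrast them).
#' @param survival arguments for [survival_design()].
#' @param fecundity list with `n_per_cross`.
#' @param mcmc arguments for [mcmc_options()].
#' @param lrt_full full fixed-effect formula for the behavioural fit.
#' @param lrt_terms terms dropped one at a time for likelihood-ratio tests.
#' @param selection list with `c_levels` (competition levels for the
#'   inbreeding fitness cost) and `c_infested` (competitor load assigned to
#'   eggs on infested seeds).
#' @param load list with `U_values` and `B_ratios`; `B_ratios = "estimate"`
#'   uses the posterior-mean inbred-fitness ratio between the reliable-cue
#'   and no-cue treatments (alongside 1 for comparison).
#' @param glmm options passed to [fit_glmm()].
#' @param quiet suppress progress messages.
#' @return list of class `cueload_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = file.path(tempdir(), "cueload"),
                            behavior = list(), eggs = list(),
                            survival = list(), fecundity = list(),
                            mcmc = list(), lrt_full = NULL, lrt_terms = NULL,
                            selection = list(), load = list(),
                            glmm = list(), quiet = FALSE) {
  defaults <- list(
    seed = seed, out_dir = out_dir,
    behavior = list(n_trials = 44),
    eggs = list(n_trials = 54, cross_types = c("outbred", "inbred")),
    survival = list(),
    fecundity = list(n_per_cross = 15),
    mcmc = list(n_iterations = 100000, burn_in = 50000, thin = 100),
    lrt_full = n_on_uninfested ~ treatment * (run_c + I(run_c^2)) +
      time_c + I(time_c^2) + line_id,
    lrt_terms = c("treatment", "treatment:run_c", "treatment:I(run_c^2)"),
    selection = list(c_levels = c(0, 6), c_infested = 3),
    load = list(U_values = c(1, 2), B_ratios = "estimate"),
    glmm = list(n_nodes = 15),
    quiet = quiet
  )
  cfg <- utils::modifyList(defaults, list(
    behavior = behavior, eggs = eggs, survival = survival,
    fecundity = fecundity, mcmc = mcmc, selection = selection,
    load = load, glmm = glmm))
  if (!is.null(lrt_full)) cfg$lrt_full <- lrt_full
  if (!is.null(lrt_terms)) cfg$lrt_terms <- lrt_terms
  cfg$seed <- seed
  cfg$out_dir <- out_dir
  structure(cfg, class = "cueload_config")
}

#' Read a pipeline configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON configuration overriding
#' [pipeline_config()] defaults. Formula fields may be given as strings.
#'
#' @param path config file.
#' @param seed optional seed override (takes precedence over the file).
#' @return a `cueload_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
         else stop_cueload("config must be YAML or JSON", "cueload_io_error")
  if (!is.null(raw$lrt_full)) raw$lrt_full <- stats::as.formula(raw$lrt_full)
  args <- raw[intersect(names(raw),
                        names(formals(pipeline_config)))]
  cfg <- do.call(pipeline_config, args)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

pl_msg <- function(quiet, ...) if (!quiet) message("[cueload] ", ...)

#' Run the full simulate-fit-estimate-load pipeline
#'
#' Executes every stage in dependency order: synthetic-data generation for
#' the four datasets, bean cleaning, the behavioural mixed-model fit with
#' drop-one likelihood-ratio tests, posterior sampling for the survival and
#' egg models, the selection estimates (inbreeding fitness cost at the
#' requested competition levels, per-treatment selection coefficients with
#' pairwise contrasts, genotype-level care-survival ellipses, fecundity
#' inbreeding depression), and the metapopulation load curves. All CSV and
#' JSON artifacts are written under `config$out_dir`; a stage failure
#' aborts with the stage name after persisting the manifest so far.
#'
#' @param config a [pipeline_config()].
#' @return the run report (list) invisibly; also serialized as
#'   `run_report.json`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "cueload_config"))
  quiet <- isTRUE(config$quiet)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  report <- list(package = "cueload",
                 version = as.character(utils::packageVersion("cueload")),
                 r_version = paste(R.version$major, R.version$minor, sep = "."),
                 seed = config$seed, stages = list())
  current_stage <- "init"
  emit <- function(name) {
    manifest <<- c(manifest, name)
    file.path(config$out_dir, name)
  }
  persist <- function() {
    jsonlite::write_json(
      list(completed = names(report$stages), files = manifest),
      file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE)
  }
  run_stage <- function(name, fun) {
    current_stage <<- name
    pl_msg(quiet, "stage: ", name)
    tryCatch(fun(), error = function(e) {
      persist()
      stop_cueload(paste0("pipeline stage '", name, "' failed: ",
                          conditionMessage(e)), "cueload_stage_failure")
    })
  }

  datasets <- new.env(parent = emptyenv())
  run_stage("simulate", function() {
    bd <- do.call(behavior_design, config$behavior)
    datasets$behavior <- gen_behavior(bd, behavior_params(),
                                      seed = derive_seed(config$seed, "behavior"))
    ed <- do.call(behavior_design, config$eggs)
    datasets$eggs <- gen_eggs(ed, egg_params(),
                              seed = derive_seed(config$seed, "eggs"))
    sd_ <- do.call(survival_design, config$survival)
    datasets$beans <- gen_survival(sd_, survival_params(),
                                   seed = derive_seed(config$seed, "survival"))
    datasets$fecundity <- gen_fecundity(
      config$fecundity$n_per_cross %||% 15, fecundity_params(),
      seed = derive_seed(config$seed, "fecundity"))
    write_dataset(datasets$behavior, emit("behavior.csv"), "behavior")
    write_dataset(datasets$eggs, emit("eggs.csv"), "eggs")
    write_dataset(datasets$beans, emit("beans.csv"), "beans")
    write_dataset(datasets$fecundity, emit("fecundity.csv"), "fecundity")
    report$stages$simulate <<- list(
      rows = list(behavior = nrow(datasets$behavior),
                  eggs = nrow(datasets$eggs),
                  beans = nrow(datasets$beans),
                  fecundity = nrow(datasets$fecundity)))
  })

  run_stage("prepare", function() {
    prep <- prepare_survival(datasets$beans)
    datasets$beans_clean <- prep$data
    utils::write.csv(prep$filter_log, emit("survival_filter_log.csv"),
                     row.names = FALSE, quote = FALSE)
    report$stages$prepare <<- list(rows_in = prep$rows_in,
                                   rows_out = prep$rows_out,
                                   rows_removed = prep$rows_removed,
                                   filters = prep$filter_log)
  })

  run_stage("fit", function() {
    beh <- scale_run_time(datasets$behavior)
    fixed <- stats::as.formula(paste("~",
      paste(deparse(config$lrt_full[[3]]), collapse = " ")))
    spec_full <- glmm_spec("n_on_uninfested", fixed, "binomial",
                           size = "n_females",
                           random = c("trial_id", "trial_id:treatment"))
    fit_full <- fit_glmm(spec_full, beh,
                         options = utils::modifyList(config$glmm,
                                                     list(compute_vcov = FALSE)))
    tests <- lapply(config$lrt_terms, function(term) {
      reduced <- stats::update(fixed, paste("~ . -", term))
      spec_red <- glmm_spec("n_on_uninfested", reduced, "binomial",
                            size = "n_females",
                            random = c("trial_id", "trial_id:treatment"))
      fit_red <- fit_glmm(spec_red, beh,
                          options = utils::modifyList(config$glmm,
                                                      list(compute_vcov = FALSE)))
      tst <- lr_test(fit_full, fit_red)
      list(term = term, statistic = tst$statistic, df = tst$df,
           p_value = tst$p_value)
    })
    report$stages$fit <<- list(
      loglik = fit_full$loglik, converged = fit_full$converged,
      random_sd = as.list(fit_full$sd), lr_tests = tests)
  })

  run_stage("posterior", function() {
    mk_opts <- function(stage) do.call(mcmc_options, utils::modifyList(
      config$mcmc, list(seed = derive_seed(config$seed, stage))))
    surv_spec <- glmm_spec("n_focal_emerged", ~ cross_type * C, "binomial",
                           size = "n_focal_eggs", random = "duo_id")
    beans <- datasets$beans_clean
    beans$cross_type <- factor(beans$cross_type,
                               levels = c("outbred", "inbred"))
    datasets$survival_draws <- sample_posterior(surv_spec, beans,
                                                mk_opts("mcmc_survival"))
    eggs <- scale_run_time(datasets$eggs)
    eggs$cross_type <- factor(eggs$cross_type,
                              levels = c("outbred", "inbred"))
    egg_fixed <- ~ treatment * cross_type + run_c
    datasets$eggs_u_draws <- sample_posterior(
      glmm_spec("eggs_uninfested", egg_fixed, "poisson",
                random = "trial_id"),
      eggs, mk_opts("mcmc_eggs_uninfested"))
    datasets$eggs_i_draws <- sample_posterior(
      glmm_spec("eggs_infested", egg_fixed, "poisson",
                random = "trial_id"),
      eggs, mk_opts("mcmc_eggs_infested"))
    for (nm in c("survival_draws", "eggs_u_draws", "eggs_i_draws")) {
      utils::write.csv(as.data.frame(datasets[[nm]]$draws),
                       emit(paste0(nm, ".csv")), row.names = FALSE)
    }
    report$stages$posterior <<- list(
      stored_draws = nrow(datasets$survival_draws$draws),
      acceptance = list(
        survival = as.list(round(datasets$survival_draws$accept, 3)),
        eggs_uninfested = as.list(round(datasets$eggs_u_draws$accept, 3)),
        eggs_infested = as.list(round(datasets$eggs_i_draws$accept, 3))))
  })

  run_stage("selection", function() {
    sd_draws <- datasets$survival_draws
    c_levels <- config$selection$c_levels %||% c(0, 6)
    dw <- lapply(c_levels, function(cl) delta_omega_posterior(sd_draws, cl))
    names(dw) <- paste0("c", c_levels)

    treatments <- intersect(c("none", "reliable", "unreliable"),
                            unique(datasets$eggs$treatment))
    eggs_exp <- egg_expectation_draws(datasets$eggs_u_draws,
                                      datasets$eggs_i_draws,
                                      treatments = treatments)
    ts <- treatment_selection(eggs_exp, sd_draws, match_draws = TRUE,
                              c_infested = config$selection$c_infested %||% 3)
    gm <- genotype_means(datasets$eggs, sd_draws,
                         c_infested = config$selection$c_infested %||% 3)
    ellipses <- lapply(split(gm, gm$treatment), care_survival_ellipse)
    ibd <- inbreeding_depression(datasets$fecundity,
                                 seed = derive_seed(config$seed, "bootstrap"))
    datasets$ts <- ts

    sel_report <- list(
      delta_omega = lapply(dw, function(e)
        list(mean = e$mean, ci = e$ci)),
      s = lapply(ts$estimates, function(e)
        list(mean = e$mean, ci = e$ci)),
      contrasts = ts$contrasts,
      ige_covariance = lapply(ellipses, function(e)
        list(covariance = e$cov[1, 2], correlation = e$correlation,
             degenerate = e$degenerate)),
      inbreeding_depression = ibd
    )
    jsonlite::write_json(sel_report, emit("selection_report.json"),
                         auto_unbox = TRUE, digits = 10, dataframe = "rows")
    report$stages$selection <<- sel_report
  })

  run_stage("load", function() {
    ts <- datasets$ts
    s_j <- ts$estimates[["reliable"]]$mean
    s_k <- ts$estimates[["none"]]$mean
    br_cfg <- config$load$B_ratios %||% "estimate"
    b_est <- mean(ts$omega_inbred[, "reliable"]) /
      mean(ts$omega_inbred[, "none"])
    B_ratios <- if (identical(br_cfg, "estimate")) c(b_est, 1)
                else as.numeric(br_cfg)
    lc <- load_curve(load_params(s_j = s_j, s_k = s_k),
                     U_values = config$load$U_values %||% c(1, 2),
                     B_ratios = B_ratios)
    utils::write.csv(lc, emit("load_curve.csv"), row.names = FALSE,
                     quote = FALSE)
    report$stages$load <<- list(s_j = s_j, s_k = s_k,
                                s_ratio = s_k / s_j, B_ratios = B_ratios,
                                n_scenarios = length(unique(lc$U)) *
                                  length(unique(lc$B_ratio)))
  })

  current_stage <- "report"
  report$files <- data.frame(
    name = manifest,
    md5 = vapply(file.path(config$out_dir, manifest),
                 function(p) as.character(tools::md5sum(p)), character(1)),
    row.names = NULL)
  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = 10, dataframe = "rows")
  persist()
  pl_msg(quiet, "done: ", length(manifest) + 2, " files in ", config$out_dir)
  invisible(report)
}
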