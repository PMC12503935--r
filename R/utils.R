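# Internal numeric helpers shared across modules.

# Inverse logit with clamping away from exact 0/1 so that log-likelihoods
# and ratios stay finite even for extreme linear predictors.
invlogit <- function(eta, eps = 1e-15) {
  p <- 1 / (1 + exp(-eta))
  pmin(pmax(p, eps), 1 - eps)
}

logit <- function(p) log(p / (1 - p))

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cueload <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "cueload_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# Deterministic derivation of stage seeds from one global seed.  Offsets are
# fixed per stage name so that adding stages never perturbs earlier ones.
# Results are kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  offsets <- c(
    behavior = 101L, eggs = 211L, survival = 307L, fecundity = 401L,
    glmm = 503L, mcmc_survival = 601L, mcmc_eggs_uninfested = 701L,
    mcmc_eggs_infested = 809L, selection = 907L, bootstrap = 1009L
  )
  off <- offsets[[stage]]
  if (is.null(off)) stop_cueload(paste0("unknown stage '", stage, "'"),
                                 "cueload_invalid_argument")
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483629)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != round(x) || x < min)
    stop_cueload(sprintf("'%s' must be a single integer >= %d", name, min),
                 "cueload_invalid_design")
  as.integer(x)
}
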