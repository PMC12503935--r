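# Independent oracles and small fixture builders shared across tests.

# brute-force marginal log-likelihood for a single scalar random intercept:
# fixed-grid trapezoid integration over +-10 sd per group
oracle_marginal_loglik <- function(y, size, eta0, group, sd,
                                   family = "binomial", n_grid = 10001) {
  ll_fun <- if (family == "binomial") {
    function(uu, idx) sum(stats::dbinom(y[idx], size[idx],
                                        stats::plogis(eta0[idx] + uu),
                                        log = TRUE))
  } else {
    function(uu, idx) sum(stats::dpois(y[idx], exp(eta0[idx] + uu),
                                       log = TRUE))
  }
  us <- seq(-10 * sd, 10 * sd, length.out = n_grid)
  h <- us[2] - us[1]
  tot <- 0
  for (g in unique(group)) {
    idx <- which(group == g)
    lls <- vapply(us, function(uu) ll_fun(uu, idx) +
                    stats::dnorm(uu, 0, sd, log = TRUE), numeric(1))
    mx <- max(lls)
    tot <- tot + mx + log(sum(exp(lls - mx)) * h)
  }
  tot
}

# dense-grid posterior for a 2-parameter logistic regression with
# independent Normal(0, 100) priors; returns marginal medians and
# equal-tail 95% intervals per coordinate
oracle_grid_posterior <- function(y, size, x, b0_range, b1_range, n = 401) {
  b0 <- seq(b0_range[1], b0_range[2], length.out = n)
  b1 <- seq(b1_range[1], b1_range[2], length.out = n)
  lp <- outer(b0, b1, Vectorize(function(a, b)
    sum(stats::dbinom(y, size, stats::plogis(a + b * x), log = TRUE)) +
      stats::dnorm(a, 0, 10, log = TRUE) +
      stats::dnorm(b, 0, 10, log = TRUE)))
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  qfun <- function(grid, marg) {
    cm <- cumsum(marg)
    keep <- !duplicated(cm)
    stats::approx(cm[keep], grid[keep], xout = c(0.025, 0.5, 0.975),
                  rule = 2)$y
  }
  list(b0 = qfun(b0, rowSums(w)), b1 = qfun(b1, colSums(w)))
}

# small single-factor binomial dataset with known structure
toy_binomial_data <- function(n_groups = 10, per_group = 2, size = 5,
                              beta = c(-0.3, 0.7), sd_u = 0.8, seed = 42) {
  set.seed(seed)
  g <- factor(rep(seq_len(n_groups), each = per_group))
  x <- stats::rnorm(n_groups * per_group)
  u <- stats::rnorm(n_groups, 0, sd_u)
  eta <- beta[1] + beta[2] * x + u[as.integer(g)]
  data.frame(y = stats::rbinom(length(eta), size, stats::plogis(eta)),
             x = x, g = g, size = size)
}

# fabricate a cueload_draws object with given fixed-effect draws on the
# survival-model design (used to test the posterior transformations with
# exactly known coefficients)
fake_survival_draws <- function(coef_matrix) {
  d <- data.frame(
    n_focal_emerged = c(1, 1, 0, 1),
    n_focal_eggs = c(2, 2, 1, 2),
    cross_type = factor(c("outbred", "inbred", "outbred", "inbred"),
                        levels = c("outbred", "inbred")),
    C = c(0, 2, 4, 6),
    duo_id = c("a", "a", "b", "b")
  )
  spec <- glmm_spec("n_focal_emerged", ~ cross_type * C, "binomial",
                    size = "n_focal_eggs", random = "duo_id")
  design <- build_design(spec, d)
  stopifnot(identical(colnames(coef_matrix), colnames(design$X)))
  draws <- cbind(coef_matrix, sd_duo_id = 0.1)
  structure(list(draws = draws, design = design,
                 labels = colnames(draws)),
            class = "cueload_draws")
}

survival_coef_names <- c("(Intercept)", "cross_typeinbred", "C",
                         "cross_typeinbred:C")

# coefficient row: intercept b0, inbred effect bi, slope bc, interaction bic
survival_coef_row <- function(b0, bi, bc, bic) {
  matrix(c(b0, bi, bc, bic), nrow = 1,
         dimnames = list(NULL, survival_coef_names))
}
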