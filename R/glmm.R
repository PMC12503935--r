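# Maximum-likelihood fitting of binomial/Poisson random-intercept models.
#
# The marginal likelihood integrates the Gaussian random intercepts out of
# the conditional GLM likelihood. With a single grouping factor the integral
# factorises over groups and is computed by adaptive Gauss-Hermite
# quadrature (AGQ) centred and scaled at the conditional mode of each group;
# one node reduces to the Laplace approximation. With two or more grouping
# factors the groups of different factors overlap, the likelihood no longer
# factorises, and we use a joint Laplace approximation whose Hessian is
# taken block-diagonal across factors (a conditional-independence
# approximation; each factor's curvature is evaluated at the joint mode).

gh_cache <- new.env(parent = emptyenv())

gh_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(gh_cache[[key]])) {
    if (n == 1) {
      gh_cache[[key]] <- list(x = 0, w = sqrt(pi))
    } else {
      gh_cache[[key]] <- pracma::gaussHermite(n)
    }
  }
  gh_cache[[key]]
}

# family kernels: conditional log-likelihood, its first derivative in eta,
# and the (positive) curvature weight -d2/deta2
family_funs <- function(family) {
  if (family == "binomial") {
    list(
      ll = function(eta, y, size) {
        p <- invlogit(eta)
        lchoose(size, y) + y * log(p) + (size - y) * log1p(-p)
      },
      d1 = function(eta, y, size) y - size * invlogit(eta),
      wt = function(eta, y, size) {
        p <- invlogit(eta)
        size * p * (1 - p)
      },
      # derivative and curvature from one inverse-link evaluation
      d1wt = function(eta, y, size) {
        p <- invlogit(eta)
        list(d1 = y - size * p, wt = size * p * (1 - p))
      }
    )
  } else {
    list(
      ll = function(eta, y, size) y * eta - exp(eta) - lgamma(y + 1),
      d1 = function(eta, y, size) y - exp(eta),
      wt = function(eta, y, size) exp(eta),
      d1wt = function(eta, y, size) {
        mu <- exp(eta)
        list(d1 = y - mu, wt = mu)
      }
    )
  }
}

check_eta <- function(eta) {
  bad <- which(!is.finite(eta))
  if (length(bad))
    stop_cueload(paste0("non-finite linear predictor at row ", bad[1]),
                 "cueload_nonfinite_predictor", row = bad[1])
  eta
}

# Newton maximisation of the penalised objective for one grouping factor,
# vectorised over groups: h_g(u) = sum_{i in g} ll_i(eta0_i + u) - u^2/(2 s^2)
group_modes <- function(eta0, y, size, g, sd, fam, u = NULL,
                        tol = 1e-10, max_iter = 40) {
  ng <- nlevels(g)
  gi <- as.integer(g)
  if (is.null(u) || length(u) != ng) u <- numeric(ng)
  hess <- NULL
  for (it in seq_len(max_iter)) {
    dw <- fam$d1wt(eta0 + u[gi], y, size)
    d1 <- rowsum(dw$d1, gi, reorder = TRUE)[, 1] - u / sd^2
    hess <- rowsum(dw$wt, gi, reorder = TRUE)[, 1] + 1 / sd^2
    step <- d1 / hess
    step <- pmin(pmax(step, -5), 5)  # damp huge logistic steps
    u <- u + step
    if (max(abs(step)) < tol) break
  }
  list(u = u, hess = hess)
}

# penalised objective per group, including the Gaussian normaliser
group_h <- function(eta0, y, size, gi, u_obs, u_grp, sd, fam) {
  llg <- rowsum(fam$ll(eta0 + u_obs, y, size), gi, reorder = TRUE)[, 1]
  llg - u_grp^2 / (2 * sd^2) - 0.5 * log(2 * pi * sd^2)
}

# marginal log-likelihood for a built design at fixed parameters; `state`
# (an environment) carries the latent-mode vectors between successive calls
# so that optimizer steps re-solve the mode equations from a warm start
loglik_design <- function(design, beta, sd, n_nodes = 15, state = NULL) {
  fam <- family_funs(design$spec$family)
  eta0 <- check_eta(drop(design$X %*% beta))
  y <- design$y
  size <- design$size
  active <- which(sd > 1e-8)
  groups <- design$groups[active]
  sd <- sd[active]

  if (length(groups) == 0) return(sum(fam$ll(eta0, y, size)))

  if (length(groups) == 1) {
    g <- groups[[1]]
    gi <- as.integer(g)
    m <- group_modes(eta0, y, size, g, sd[1], fam,
                     u = if (!is.null(state)) state$u1)
    if (!is.null(state)) state$u1 <- m$u
    tau <- 1 / sqrt(m$hess)
    nodes <- gh_nodes(n_nodes)
    K <- length(nodes$x)
    hmat <- matrix(0, nlevels(g), K)
    for (k in seq_len(K)) {
      uk <- m$u + sqrt(2) * tau * nodes$x[k]
      hmat[, k] <- group_h(eta0, y, size, gi, uk[gi], uk, sd[1], fam)
    }
    lw <- sweep(hmat, 2, log(nodes$w) + nodes$x^2, `+`)
    mx <- apply(lw, 1, max)
    return(sum(log(sqrt(2) * tau) + mx + log(rowSums(exp(lw - mx)))))
  }

  # >= 2 factors: joint mode by block coordinate ascent, then block-diagonal
  # Laplace across factors
  nf <- length(groups)
  us <- if (!is.null(state) && !is.null(state$us)) state$us
        else lapply(groups, function(g) numeric(nlevels(g)))
  gis <- lapply(groups, as.integer)
  offset_all <- function(skip = 0) {
    out <- eta0
    for (j in seq_len(nf)) if (j != skip) out <- out + us[[j]][gis[[j]]]
    out
  }
  for (sweep_i in seq_len(100)) {
    delta <- 0
    for (j in seq_len(nf)) {
      m <- group_modes(offset_all(skip = j), y, size, groups[[j]], sd[j],
                       fam, u = us[[j]])
      delta <- max(delta, max(abs(m$u - us[[j]])))
      us[[j]] <- m$u
    }
    if (delta < 1e-10) break
  }
  if (!is.null(state)) state$us <- us
  eta <- offset_all()
  ll <- sum(fam$ll(eta, y, size))
  for (j in seq_len(nf)) {
    hess <- rowsum(fam$wt(eta, y, size), gis[[j]], reorder = TRUE)[, 1] +
      1 / sd[j]^2
    ll <- ll + sum(-us[[j]]^2 / (2 * sd[j]^2) - 0.5 * log(sd[j]^2 * hess))
  }
  ll
}

#' Marginal log-likelihood of a mixed model
#'
#' Integrates the scalar random intercepts out of the conditional likelihood
#' by adaptive Gauss-Hermite quadrature (one grouping factor; `n_nodes = 1`
#' gives the Laplace approximation) or by a joint Laplace approximation with
#' block-diagonal curvature when several grouping factors are present (in
#' which case `n_nodes` is ignored and one node per factor is used). With all
#' random-effect standard deviations at zero this is exactly the GLM
#' log-likelihood.
#'
#' @param spec a [glmm_spec()].
#' @param data data frame.
#' @param params list with `beta` (fixed-effect vector, in model-matrix
#'   column order) and `sd` (one non-negative standard deviation per random
#'   factor).
#' @param n_nodes number of quadrature nodes (default 15).
#' @return a single finite numeric value.
#' @export
marginal_loglik <- function(spec, data, params, n_nodes = 15) {
  design <- build_design(spec, data)
  if (length(params$beta) != ncol(design$X))
    stop_cueload("beta length does not match the design matrix",
                 "cueload_invalid_params")
  sd <- params$sd %||% numeric(0)
  if (length(sd) != length(design$groups))
    stop_cueload("one sd per random factor is required",
                 "cueload_invalid_params")
  if (any(sd < 0))
    stop_cueload("random-effect sds must be >= 0", "cueload_invalid_params")
  assert_count(n_nodes, "n_nodes", min = 1L)
  loglik_design(design, params$beta, sd, n_nodes)
}

num_grad <- function(f, par, h = 1e-5) {
  vapply(seq_along(par), function(j) {
    hj <- h * (abs(par[j]) + 1)
    pp <- par; pp[j] <- pp[j] + hj
    pm <- par; pm[j] <- pm[j] - hj
    (f(pp) - f(pm)) / (2 * hj)
  }, numeric(1))
}

#' Fit a binomial or Poisson random-intercept model
#'
#' Maximises the marginal log-likelihood over the fixed effects and the
#' log-transformed random-effect standard deviations with quasi-Newton
#' (BFGS) search, warm-started from the corresponding fixed-effects-only
#' GLM. Convergence is declared when the infinity norm of the numerically
#' estimated score, relative to `max(1, |logLik|)`, falls below `grad_tol`.
#' Standard errors come from the observed information (numerical Hessian of
#' the marginal log-likelihood at the optimum).
#'
#' @param spec a [glmm_spec()].
#' @param data data frame.
#' @param options list; recognised entries `n_nodes` (default 15),
#'   `compute_vcov` (default TRUE), `start` (named list `beta`, `log_sd`),
#'   `max_iter` (default 500), `grad_tol` (default 1e-4; the score is
#'   estimated by central differences, so a tighter tolerance would mostly
#'   measure differentiation noise).
#' @return object of class `cueload_glmm` with coefficients, standard
#'   errors, covariance, variance components (as standard deviations),
#'   maximised log-likelihood, convergence flag and gradient norm.
#' @export
fit_glmm <- function(spec, data, options = list()) {
  n_nodes <- options$n_nodes %||% 15
  design <- build_design(spec, data)
  nf <- length(design$groups)
  fam_glm <- if (spec$family == "binomial") stats::binomial()
             else stats::poisson()

  if (spec$family == "binomial") {
    warm <- stats::glm.fit(design$X, design$y / design$size,
                           weights = design$size, family = fam_glm)
  } else {
    warm <- stats::glm.fit(design$X, design$y, family = fam_glm)
  }
  beta0 <- ifelse(is.finite(warm$coefficients), warm$coefficients, 0)
  start <- options$start %||% list()
  beta0 <- start$beta %||% beta0
  ls0 <- start$log_sd %||% rep(log(0.3), nf)
  par <- c(beta0, ls0)
  p <- ncol(design$X)

  mode_state <- new.env(parent = emptyenv())
  negll <- function(par) {
    sd <- pmin(exp(pmax(par[p + seq_len(nf)], -30)), 1e4)
    out <- tryCatch(
      -loglik_design(design, par[seq_len(p)], sd, n_nodes,
                     state = mode_state),
      cueload_error = function(e) Inf
    )
    if (!is.finite(out)) 1e10 else out
  }

  # forward-difference gradient reusing the cached objective value at the
  # current point (optim calls fn before gr at the same par)
  last <- new.env(parent = emptyenv())
  negll_cached <- function(par) {
    v <- negll(par)
    last$par <- par
    last$value <- v
    v
  }
  grad_fd <- function(par) {
    f0 <- if (!is.null(last$par) && identical(par, last$par)) last$value
          else negll(par)
    vapply(seq_along(par), function(j) {
      hj <- 1e-6 * (abs(par[j]) + 1e-2)
      pp <- par
      pp[j] <- pp[j] + hj
      (negll(pp) - f0) / hj
    }, numeric(1))
  }
  grad_tol <- options$grad_tol %||% 1e-4
  check_conv <- function(opt) {
    loglik <- -opt$value
    grad <- num_grad(negll, opt$par)
    grad_norm <- max(abs(grad)) / max(1, abs(loglik))
    converged <- opt$convergence == 0 && grad_norm < grad_tol
    # a variance component estimated at the boundary flattens the profile
    # in its log-sd direction; judge convergence on the fixed effects there
    at_boundary <- nf > 0 && any(opt$par[p + seq_len(nf)] < log(0.02))
    if (!converged && at_boundary) {
      grad_fixed <- max(abs(grad[seq_len(p)])) / max(1, abs(loglik))
      converged <- opt$convergence == 0 && grad_fixed < grad_tol
    }
    list(converged = converged, grad_norm = grad_norm)
  }
  ctrl <- list(maxit = options$max_iter %||% 500, reltol = 1e-11)
  opt <- stats::optim(par, negll_cached, gr = grad_fd, method = "BFGS",
                      control = ctrl)
  cv <- check_conv(opt)
  if (!cv$converged) {
    # restart once from the located optimum; BFGS curvature estimates go
    # stale on flat stretches and a fresh start usually polishes the score
    opt2 <- stats::optim(opt$par, negll_cached, gr = grad_fd,
                         method = "BFGS", control = ctrl)
    if (opt2$value <= opt$value) {
      opt <- opt2
      cv <- check_conv(opt)
    }
  }
  loglik <- -opt$value
  converged <- cv$converged
  grad_norm <- cv$grad_norm

  beta <- opt$par[seq_len(p)]
  names(beta) <- colnames(design$X)
  sd_hat <- exp(opt$par[p + seq_len(nf)])
  names(sd_hat) <- names(design$groups)

  if (any(abs(beta) > 15))
    warning("possible separation: |coefficient| > 15 on the link scale",
            call. = FALSE)

  vcov <- se <- NULL
  if (options$compute_vcov %||% TRUE) {
    H <- tryCatch(stats::optimHess(opt$par, negll), error = function(e) NULL)
    if (!is.null(H)) {
      vcov_all <- tryCatch(solve(H), error = function(e) {
        ev <- eigen(H, symmetric = TRUE)
        pos <- pmax(ev$values, max(ev$values) * 1e-10)
        ev$vectors %*% diag(1 / pos, length(pos)) %*% t(ev$vectors)
      })
      vcov_all <- (vcov_all + t(vcov_all)) / 2
      vcov <- vcov_all[seq_len(p), seq_len(p), drop = FALSE]
      dimnames(vcov) <- list(names(beta), names(beta))
      se <- sqrt(pmax(diag(vcov), 0))
    }
  }

  structure(
    list(coefficients = beta, se = se, vcov = vcov,
         sd = sd_hat, variance_components = sd_hat^2,
         loglik = loglik, converged = converged, grad_norm = grad_norm,
         n_nodes = if (nf > 1) 1L else as.integer(n_nodes),
         n_obs = design$n, n_fixed = p,
         design = design, spec = spec, optim = opt[c("counts", "convergence")]),
    class = "cueload_glmm"
  )
}

#' @export
print.cueload_glmm <- function(x, ...) {
  cat("GLMM fit [", x$spec$family, "], logLik = ",
      formatC(x$loglik, digits = 6, format = "f"),
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  tab <- data.frame(estimate = x$coefficients)
  if (!is.null(x$se)) tab$se <- x$se
  print(round(tab, 4))
  if (length(x$sd)) {
    cat("random-effect sd:\n")
    print(round(x$sd, 4))
  }
  invisible(x)
}

#' @export
logLik.cueload_glmm <- function(object, ...) {
  structure(object$loglik, df = object$n_fixed + length(object$sd),
            class = "logLik")
}

#' Likelihood-ratio test between nested mixed-model fits
#'
#' The statistic is twice the difference in maximised marginal
#' log-likelihood, clamped at zero; the degrees of freedom are the
#' difference in free fixed-effect parameters; the p-value is the upper
#' chi-square tail. The reduced model's fixed terms must be a subset of the
#' full model's, on the same data and random structure.
#'
#' @param fit_full,fit_reduced converged `cueload_glmm` fits.
#' @return object of class `cueload_lrt` with `statistic`, `df`, `p_value`.
#' @export
lr_test <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "cueload_glmm"),
            inherits(fit_reduced, "cueload_glmm"))
  if (!fit_full$converged || !fit_reduced$converged)
    stop_cueload("both fits must have converged", "cueload_not_converged")
  # order within an interaction label is irrelevant (a:b == b:a)
  canon <- function(labels) vapply(strsplit(labels, ":", fixed = TRUE),
                                   function(x) paste(sort(x), collapse = ":"),
                                   character(1))
  tf <- canon(fit_full$design$term_labels)
  tr <- canon(fit_reduced$design$term_labels)
  same_random <- identical(fit_full$spec$random, fit_reduced$spec$random)
  if (!all(tr %in% tf) || !same_random ||
      fit_full$spec$family != fit_reduced$spec$family ||
      fit_full$n_obs != fit_reduced$n_obs)
    stop_cueload("models are not nested on the same data",
                 "cueload_not_nested")
  stat <- max(0, 2 * (fit_full$loglik - fit_reduced$loglik))
  df <- fit_full$n_fixed - fit_reduced$n_fixed
  if (df < 0) stop_cueload("reduced model has more parameters than full",
                           "cueload_not_nested")
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p),
            class = "cueload_lrt")
}

#' @export
print.cueload_lrt <- function(x, ...) {
  cat(sprintf("LRT: chisq(%d) = %.2f, p = %.4g\n",
              x$df, x$statistic, x$p_value))
  invisible(x)
}
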