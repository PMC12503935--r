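#' Specify a binomial or Poisson mixed model
#'
#' A model specification couples a GLM family with a fixed-effect formula and
#' a set of scalar random-intercept grouping factors. Fixed effects are given
#' as a one-sided formula evaluated against the data; second-degree
#' polynomial trends (e.g. in run or observation time) are written with
#' [stats::poly()] and are fitted on an orthogonal basis by default. Each
#' entry of `random` names a grouping column, or an interaction of columns
#' written `"a:b"`, contributing one Gaussian random-intercept variance
#' component on the linear-predictor scale.
#'
#' @param response name of the response column (successes for binomial,
#'   counts for Poisson).
#' @param fixed one-sided formula of fixed-effect terms.
#' @param family `"binomial"` or `"poisson"`.
#' @param size for binomial models, the column holding the number of trials
#'   per row (e.g. females per arena group, eggs per bean).
#' @param random character vector of grouping factors, e.g.
#'   `c("trial_id", "trial_id:treatment")`.
#' @return an object of class `cueload_spec`.
#' @examples
#' glmm_spec("n_on_uninfested", ~ treatment * poly(run, 2), "binomial",
#'           size = "n_females", random = "trial_id")
#' @export
glmm_spec <- function(response, fixed, family = c("binomial", "poisson"),
                      size = NULL, random = character()) {
  family <- match.arg(family)
  stopifnot(inherits(fixed, "formula"), length(fixed) == 2)
  if (family == "binomial" && is.null(size))
    stop_cueload("binomial models need a 'size' column (number of trials)",
                 "cueload_invalid_spec")
  structure(
    list(response = response, fixed = fixed, family = family,
         size = size, random = as.character(random)),
    class = "cueload_spec"
  )
}

#' @export
print.cueload_spec <- function(x, ...) {
  cat("GLMM spec [", x$family, "]\n", sep = "")
  cat("  response:", x$response,
      if (!is.null(x$size)) paste0("/ ", x$size), "\n")
  cat("  fixed:   ", deparse(x$fixed), "\n")
  cat("  random:  ",
      if (length(x$random)) paste(x$random, collapse = ", ") else "(none)",
      "\n")
  invisible(x)
}

random_group_factor <- function(name, data) {
  cols <- strsplit(name, ":", fixed = TRUE)[[1]]
  missing <- setdiff(cols, names(data))
  if (length(missing))
    stop_cueload(paste0("random grouping column(s) not in data: ",
                        paste(missing, collapse = ", ")),
                 "cueload_unknown_column")
  f <- interaction(data[cols], drop = TRUE, sep = ":")
  if (nlevels(f) < 2)
    stop_cueload(paste0("random factor '", name, "' has a single level"),
                 "cueload_invalid_design")
  f
}

#' Build design matrices for a model specification
#'
#' Expands the fixed-effect formula into a model matrix (treatment-contrast
#' coding for factors, orthogonal polynomial basis for `poly()` terms unless
#' `raw = TRUE` is requested in the formula) and maps each random grouping
#' factor onto row indices. The returned object carries the `terms` metadata
#' needed to rebuild the matrix for new data on the identical basis, and the
#' term-to-column assignment used for likelihood-ratio-test degree-of-freedom
#' bookkeeping.
#'
#' @param spec a [glmm_spec()].
#' @param data data frame containing every column the spec references.
#' @return an object of class `cueload_design` with elements `X`, `y`,
#'   `size`, `groups`, `terms`, `assign`, `term_labels`.
#' @export
build_design <- function(spec, data) {
  stopifnot(inherits(spec, "cueload_spec"), is.data.frame(data))
  needed <- c(spec$response, spec$size, all.vars(spec$fixed))
  missing <- setdiff(needed, names(data))
  if (length(missing))
    stop_cueload(paste0("column(s) not in data: ",
                        paste(missing, collapse = ", ")),
                 "cueload_unknown_column")
  for (v in all.vars(spec$fixed)) {
    col <- data[[v]]
    if ((is.character(col) || is.factor(col) || is.logical(col)) &&
        length(unique(col[!is.na(col)])) < 2)
      stop_cueload(paste0("fixed-effect factor '", v, "' has a single level"),
                   "cueload_invalid_design")
    if (is.character(col) || is.logical(col)) data[[v]] <- factor(col)
  }

  mf <- stats::model.frame(spec$fixed, data, na.action = stats::na.fail)
  tt <- stats::terms(mf)
  X <- stats::model.matrix(tt, mf)

  y <- data[[spec$response]]
  if (anyNA(y)) stop_cueload("missing values in response",
                             "cueload_invalid_data")
  size <- NULL
  if (spec$family == "binomial") {
    size <- data[[spec$size]]
    if (any(y < 0 | y > size))
      stop_cueload("binomial response outside [0, size]",
                   "cueload_invalid_data")
  } else if (any(y < 0)) {
    stop_cueload("negative Poisson response", "cueload_invalid_data")
  }

  groups <- lapply(spec$random, random_group_factor, data = data)
  names(groups) <- spec$random

  structure(
    list(X = X, y = as.numeric(y),
         size = if (!is.null(size)) as.numeric(size),
         groups = groups, terms = tt,
         assign = attr(X, "assign"),
         term_labels = attr(tt, "term.labels"),
         xlevels = stats::.getXlevels(tt, mf),
         spec = spec, n = nrow(X)),
    class = "cueload_design"
  )
}

# Rebuild the fixed-effect matrix for new data on the basis stored in a
# design (poly() predvars and factor levels are carried by `terms`).
design_matrix_for <- function(design, newdata) {
  tt <- stats::delete.response(design$terms)
  mf <- stats::model.frame(tt, newdata, xlev = design$xlevels,
                           na.action = stats::na.fail)
  stats::model.matrix(tt, mf)
}
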