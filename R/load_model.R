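# Equilibrium genetic load at mutation-selection balance in a two-habitat
# metapopulation under soft selection. Habitats j (predictable) and k
# (unpredictable) occur at frequencies p_j and p_k = 1 - p_j and contribute
# offspring in proportion to frequency x productivity (reproductive-value
# weights w_i = p_i B_i / sum p B). The effective selection felt by a
# deleterious allele is the contribution-weighted average
# s_bar = w_j s_j + w_k s_k; with multiplicative loci at equilibrium the
# genome-wide deleterious-allele pressure is U / s_bar, so habitat mean
# fitness is W_i = exp(-U s_i / s_bar) and its load L_i = 1 - W_i. In a
# homogeneous habitat (s_i = s_bar) this reduces to the classical
# Haldane-Muller result W = exp(-U), independent of s; heterogeneity in s
# redistributes the load towards the habitat where selection is stronger.
# The dominance coefficient cancels from this genome-wide equilibrium,
# which is why it is not a parameter.

#' Two-habitat load-model parameters
#'
#' @param U genomic deleterious mutation rate per generation (>= 0).
#' @param s_j,s_k strength of selection per unit load in the predictable
#'   (j) and unpredictable (k) habitat; both positive. The default
#'   calibration is `s_j = 0.48` with `s_k = 1.33 * s_j`, the
#'   reliable-cue/no-cue contrast.
#' @param p_j frequency of the predictable habitat in `[0, 1]`
#'   (`p_k = 1 - p_j`).
#' @param B_j,B_k habitat productivities (> 0); the default ratio 1.96 is
#'   the inbred-fitness ratio between the reliable-cue and no-cue regimes.
#' @return list of class `cueload_load_params`.
#' @export
load_params <- function(U = 1, s_j = 0.48, s_k = 1.33 * s_j, p_j = 0.5,
                        B_j = 1.96, B_k = 1) {
  if (U < 0) stop_cueload("U must be >= 0", "cueload_invalid_params")
  if (s_j <= 0 || s_k <= 0)
    stop_cueload("selection strengths must be > 0", "cueload_invalid_params")
  if (p_j < 0 || p_j > 1)
    stop_cueload("p_j must lie in [0, 1]", "cueload_invalid_params")
  if (B_j <= 0 || B_k <= 0)
    stop_cueload("productivities must be > 0", "cueload_invalid_params")
  structure(list(U = U, s_j = s_j, s_k = s_k, p_j = p_j,
                 B_j = B_j, B_k = B_k),
            class = "cueload_load_params")
}

#' Soft-selection contribution weights of the two habitats
#'
#' `w_i = p_i B_i / (p_j B_j + p_k B_k)`: each habitat's share of the
#' metapopulation's offspring under reproductive-value weighting.
#'
#' @param p_j frequency of habitat j in `[0, 1]`.
#' @param B_j,B_k habitat productivities (> 0).
#' @return named numeric `c(w_j, w_k)` summing to 1.
#' @export
contribution_weights <- function(p_j, B_j, B_k) {
  if (any(p_j < 0 | p_j > 1))
    stop_cueload("p_j must lie in [0, 1]", "cueload_invalid_params")
  if (B_j <= 0 || B_k <= 0)
    stop_cueload("productivities must be > 0", "cueload_invalid_params")
  tot <- p_j * B_j + (1 - p_j) * B_k
  if (any(tot == 0))
    stop_cueload("both contribution weights are zero", "cueload_degenerate")
  c(w_j = p_j * B_j / tot, w_k = (1 - p_j) * B_k / tot)
}

#' Effective (contribution-weighted) strength of selection
#'
#' @param weights `c(w_j, w_k)` summing to 1 (from
#'   [contribution_weights()]).
#' @param s_j,s_k habitat-specific selection strengths.
#' @return scalar `s_bar = w_j s_j + w_k s_k`.
#' @export
effective_selection <- function(weights, s_j, s_k) {
  if (abs(sum(weights) - 1) > 1e-8)
    stop_cueload("weights must sum to 1", "cueload_invalid_params")
  unname(weights[1] * s_j + weights[2] * s_k)
}

#' Habitat mean fitness and load at mutation-selection balance
#'
#' `W_i = exp(-U s_i / s_bar)` and `L_i = 1 - W_i` under multiplicative
#' loci and soft selection. With `s_i = s_bar` (homogeneous habitat) this
#' is the Haldane-Muller limit `W = exp(-U)`.
#'
#' @param U genomic deleterious mutation rate.
#' @param s_i selection strength in the focal habitat.
#' @param s_bar effective selection across habitats (> 0 when U > 0).
#' @return named numeric `c(W, L)`.
#' @export
habitat_load <- function(U, s_i, s_bar) {
  if (U < 0) stop_cueload("U must be >= 0", "cueload_invalid_params")
  if (s_bar <= 0 && U > 0)
    stop_cueload("load diverges as effective selection vanishes",
                 "cueload_degenerate")
  W <- if (U == 0) 1 else exp(-U * s_i / s_bar)
  c(W = W, L = 1 - W)
}

#' Equilibrium load curves over habitat frequency
#'
#' Evaluates weights, effective selection, habitat mean fitnesses and loads
#' across a grid of predictable-habitat frequencies for each (U, B-ratio)
#' scenario. The default scenarios are U in {1, 2} crossed with
#' `B_j/B_k` in {1.96, 1}, the four published curves.
#'
#' @param params a [load_params()] providing `s_j`, `s_k` and the
#'   productive `B_j`, `B_k` pair (its `U`, `p_j` are ignored in favour of
#'   the grid/scenarios).
#' @param p_grid habitat-frequency grid in `[0, 1]`.
#' @param U_values mutation rates to scan.
#' @param B_ratios productivity ratios `B_j/B_k` to scan (with `B_k = 1`).
#' @return data frame with columns `p_j, U, B_ratio, w_j, s_bar, W_j, W_k,
#'   L_j, L_k`.
#' @export
load_curve <- function(params = load_params(),
                       p_grid = seq(0, 1, by = 0.01),
                       U_values = c(1, 2), B_ratios = c(1.96, 1)) {
  stopifnot(inherits(params, "cueload_load_params"))
  if (any(p_grid < 0 | p_grid > 1))
    stop_cueload("p_grid must lie in [0, 1]", "cueload_invalid_params")
  rows <- list()
  for (U in U_values) for (br in B_ratios) for (p in p_grid) {
    w <- contribution_weights(p, br, 1)
    s_bar <- effective_selection(w, params$s_j, params$s_k)
    lj <- habitat_load(U, params$s_j, s_bar)
    lk <- habitat_load(U, params$s_k, s_bar)
    rows[[length(rows) + 1]] <- data.frame(
      p_j = p, U = U, B_ratio = br, w_j = unname(w[1]), s_bar = s_bar,
      W_j = lj[["W"]], W_k = lk[["W"]], L_j = lj[["L"]], L_k = lk[["L"]])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
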