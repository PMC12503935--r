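---
title: "Methods: from behavioural trials to metapopulation genetic load"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from behavioural trials to metapopulation genetic load}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Seed-beetle females provide a simple form of maternal care: they
preferentially lay eggs on uninfested host seeds, sparing their larvae
competition. How well they do this depends on the environmental information
available to them — a pre-trial cue that accurately signals the presence of
uninfested hosts ("reliable cue"), a misleading cue ("unreliable cue"), or
no cue at all. Because effective care shields offspring from competition, it
also shields deleterious recessive alleles from selection. `cueload`
implements the full inference chain for this system:

1. grouped behavioural observations and egg placement under three cue
   treatments (binomial and Poisson mixed models, likelihood-ratio tests);
2. bean-level larval survival of inbred vs outbred offspring under
   interspecific competition (binomial mixed model, refit in a Bayesian
   framework);
3. posterior transformations to selection estimates — the inbreeding
   fitness cost $\Delta\omega_c = 1 - v_I(c)/v_O(c)$ at competition level
   $c$, and the egg-weighted genome-wide selection coefficient
   $s_j = 1 - \omega_{I,j}/\omega_{O,j}$ per cue treatment $j$, where
   $\omega = E_u v_0 + E_i v_3$ weights eggs on uninfested and infested
   seeds by survival at zero and three competitors;
4. the across-genotype covariance between maternal care and offspring
   survival (the indirect-genetic-effect summary, with one-standard-
   deviation "68%" ellipses);
5. a two-habitat metapopulation model of genetic load at mutation–selection
   balance, contrasting predictable (reliable-cue-like) and unpredictable
   (no-cue-like) environments.

Because the original raw data live in an external repository, a
synthetic-data module generates datasets with exactly the statistical
structure the analyses assume, at the study's design dimensions, so that
every downstream stage is testable end to end.

## The synthetic-data generators

`gen_behavior()` draws, for each arena group × run × 30-second scan, the
number of the group's five females found on the uninfested-host patch from
a binomial whose logit-scale mean combines second-degree trends in
within-run time and across-run learning, treatment effects and their
interactions with both trends, line effects, inbreeding effects, and
Gaussian random intercepts at the trial and trial × treatment levels. The
default dimensions are the study's: 44 trials × 3 treatments × 5 females ×
5 runs × 20 scans = 66,000 female-observations (and 18 trials → 27,000 for
the inbreeding × cue experiment). The 20-scans-per-run choice is the one
consistent with that printed total.

Default coefficients (`behavior_params()`) are calibration values chosen to
reproduce the qualitative published pattern — occupancy rising and
saturating within runs, improving across runs, highest with a reliable cue,
an inbred deficit that shrinks across runs and under a reliable cue — not
fitted values from the original data.

`gen_eggs()` draws per-run counts of eggs laid on uninfested and infested
seeds from complementary Poisson channels, log-linear in treatment, run,
inbreeding and their interaction, with a trial random intercept. In the egg
experiments each trial is a single five-female group under one treatment
(96 trials ↔ 480 females), so treatments cycle across trials and lines
rotate once per treatment cycle to keep treatment × line × cross cells
filled. Counts are capped at 20 eggs per female per run, a generator
convenience that truncates unrealistic Poisson tails. The default rates are
calibrated so that, combined with the default survival coefficients, the
implied selection coefficients are near 0.50 (reliable), 0.61 (unreliable)
and 0.63 (no cue) — the published ordering and approximate magnitudes.

`gen_survival()` assigns 60 female duos factorially to line × cross type ×
competitor infestation level (0–4) × replicate. The source reports "three
replicates … for a total of 60 female duos", but 3 × 2 × 5 × 3 = 90; we
follow the printed total of 60 (two replicates). 2,450 beans are spread
evenly across duos; focal egg counts per bean follow a distribution
concentrated on one egg (three rare, more than three very rare, so the
published >3-egg cleaning rule has work to do); emergence is binomial with
logit survival linear in inbreeding, the competition level
$C = \text{focal} + \text{competitor} - 1$ experienced by each focal egg,
and their interaction, plus a duo random intercept. The default
coefficients (intercept 2.2, inbred −1.25, competition −0.35, interaction
−0.21) put outbred no-competition survival near 0.90 and imply inbreeding
fitness costs of ≈0.20 at $C=0$ and ≈0.84 at $C=6$, the published pattern.

`gen_fecundity()` draws negative-binomial hatched-egg counts for the seven
cross labels; the default inbred reduction of 0.575 sits mid-way in the
published 55–60% fecundity drop.

What the generators do *not* emulate: spatial arena dynamics (behaviour is
generated directly at the observation-model level), overdispersion beyond
the stated families, observer effects, temporal drift across blocks, and
competitor-species emergence. Passing tests therefore demonstrate that the
inference machinery recovers the assumed data-generating process, not that
real beetle data satisfy those assumptions.

## Likelihood machinery

The frequentist fits maximise the *marginal* likelihood of binomial/Poisson
models with scalar Gaussian random intercepts. With one grouping factor the
likelihood factorises over groups and each one-dimensional integral is
computed by adaptive Gauss–Hermite quadrature: the integrand is re-centred
at the group's conditional mode and re-scaled by its curvature, then
evaluated at 15 Hermite nodes by default (one node is exactly the Laplace
approximation). Tests pin the quadrature to a brute-force 10,001-point
trapezoid oracle at 1e-6 on small fixtures, and to `lme4::glmer` with
`nAGQ = 15` on moderate ones.

With two or more grouping factors (the behavioural model's trial and
trial × treatment intercepts) the integral no longer factorises. We locate
the joint conditional mode by block coordinate ascent (vectorised
per-group Newton steps) and apply a Laplace approximation whose Hessian is
taken block-diagonal across factors — a conditional-independence
approximation; each factor's curvature is evaluated at the joint mode. This
is the same approximation family `glmer` uses by default (Laplace) for such
models, and it is documented on the fit object via `n_nodes = 1`.

Optimisation is quasi-Newton (BFGS) over the fixed effects and
log-transformed standard deviations, warm-started from the
fixed-effects-only GLM, with forward-difference gradients that reuse the
conditional modes of the previous evaluation as starting values (this
warm-start is what makes the 66,000-observation fit run in about a minute).
Convergence is declared when the infinity norm of the numerically estimated
score, relative to `max(1, |logLik|)`, falls below 1e-4 — a central
finite-difference score on log-likelihoods of magnitude $10^3$ cannot
meaningfully certify a tighter bound. Variance components are parameterised
on the log scale with an effective floor of 1e-8; a component estimated at
the boundary flattens the profile in its direction, so convergence is then
judged on the fixed-effect score. Standard errors come from the observed
information (numerical Hessian at the optimum).

Likelihood-ratio tests follow the drop-one scheme against the full model:
the statistic is twice the log-likelihood difference clamped at zero, the
degrees of freedom are the difference in fixed-effect columns, and the
p-value is the upper chi-square tail. The statistic is invariant (to 1e-6)
to raw versus orthogonal polynomial coding of the same trend terms.

## Posterior sampling

`sample_posterior()` re-fits the same models by Metropolis-within-Gibbs:

* fixed effects — one block random-walk update per iteration. The proposal
  covariance starts from the GLM standard errors and is replaced during
  burn-in by the chain's empirical covariance (adaptive Metropolis), with a
  global scale adapted towards 23.4% acceptance;
* latent intercepts — per-group scalar random-walk updates (groups of one
  factor are conditionally independent given everything else, so a whole
  factor is proposed and accepted/rejected in one vectorised step), adapted
  towards 44% acceptance;
* variance components — exact conjugate inverse-gamma draws given the
  latent intercepts.

Priors default to Normal(0, 100) on fixed effects and
Inverse-Gamma(0.001, 0.001) on variances — one concrete reading of "flat
and weak" priors; both are configurable, and no claim is made of numerical
equality with the original study's posteriors. Adaptation stops at the end
of burn-in, so all stored draws come from a fixed-kernel chain (detailed
balance holds). The default schedule is 100,000 iterations after 50,000
burn-in, storing every 100th draw: exactly 1,000 stored draws. Tests check
the sampler against a dense-grid posterior oracle on a two-parameter
logistic model (agreement within 0.02 on medians and interval endpoints),
against the prior in the no-data limit, and against the closed-form
inverse-gamma conditional (Kolmogorov–Smirnov).

Point estimates for derived quantities are posterior means with equal-tail
2.5–97.5% credible intervals (the source does not state mean versus mode;
the mean is the convention adopted throughout). Two-sided posterior tail
probabilities are $p_{\mathrm{MCMC}} = 2\min(\Pr>0, \Pr<0)$, floored at
$2/n_{\text{draws}}$.

## Selection estimates

The printed definition of the inbreeding fitness cost appears as
"$\Delta\omega_c = 1- v_{c,I}(v_{c,O})$", which we read as the ratio form
$1 - v_I(c)/v_O(c)$, consistent with the selection-coefficient definition
$s_j = 1 - \omega_{I,j}/\omega_{O,j}$ used alongside it. The competition
covariate of a focal egg is the total number of eggs on its seed minus one,
so a lone egg on an uninfested seed has $C = 0$ and the observed design
maximum (3 focal + 4 competitor) is $C = 6$. Beans with more than three
focal eggs are discarded before fitting (the published cleaning rule),
with removals logged by cross type.

For treatment-level selection, expected per-run egg numbers per treatment ×
cross type come from the two egg-channel posteriors evaluated at the mid
run (pooled per treatment × cross type, since the original per-genotype
allocation is not fully specified); survival enters at $c = 0$ for
uninfested and $c = 3$ for infested seeds (the mean competitor load on
infested seeds). Egg and survival draws are paired by index; if chain
lengths differ, the longer is thinned deterministically (uncertainty
propagation across the two models is not specified in the source; pairing
independent chains by index treats them as independent posteriors, which
they are).

Genotype means for the care–survival covariance use each treatment ×
line × cross cell's realised egg split (care, % eggs on uninfested seeds)
and that split weighted by posterior-mean viabilities (expected survival,
%). The "68%" ellipse is the one-standard-deviation contour of the sample
covariance across the (up to six) genotype means, from its
eigendecomposition; collinear or coincident points set a degeneracy flag.

## The load model

At mutation–selection balance with multiplicative loci and genomic
deleterious mutation rate $U$, a homogeneous population's mean fitness is
the Haldane–Muller limit $e^{-U}$, independent of the selection strength.
In a two-habitat metapopulation under soft selection, habitats contribute
offspring in proportion to frequency × productivity,
$w_i = p_i B_i / \sum p B$, and the effective selection on an allele is the
contribution-weighted average $\bar{s} = w_j s_j + w_k s_k$. The
equilibrium allele pressure is then $U/\bar{s}$, giving habitat mean
fitness $W_i = \exp(-U s_i/\bar{s})$ and load $L_i = 1 - W_i$. Dominance
cancels from this genome-wide equilibrium, which is why it is not a
parameter. The exact equations of the original supplementary treatment are
not available in the source text, so this concrete form is isolated behind
`habitat_load()` where an alternative could be swapped in; only the
published qualitative orderings (load in the unpredictable habitat rising
with the predictable habitat's frequency, with $U$, and with the
productivity ratio) are claimed, and those hold analytically here.

Default calibration: $s_j = 0.48$, $s_k = 1.33 s_j$ (the published
reliable-cue/no-cue contrast), $U \in \{1, 2\}$ (the plausible eukaryote
range), $B_j/B_k \in \{1.96, 1\}$. In the pipeline, $s_j, s_k$ and the
productivity ratio are instead taken from the run's own posterior
estimates.

## Orchestration, determinism, problem sizes

`run_pipeline()` executes simulate → prepare → fit → posterior → selection
→ load from a single global seed; per-stage seeds derive from it through a
fixed affine splitting scheme, so an identical configuration is
byte-reproducible (verified at the CSV-hash level in the tests). All
tabular artifacts are header-checked CSV; reports are JSON; configurations
are YAML or JSON with a `--seed` override. A thin command-line wrapper
(`inst/cli/cueload.R`) exposes `simulate`, `fit`, `posterior`, `selection`,
`load-curve` and `all` subcommands over these functions.

Test problem sizes are chosen to exercise each property at desk scale: the
coefficient-recovery fit runs at the full 44-trial design; interval
coverage (100 replicates) uses 400-bean survival datasets with shortened
chains; treatment-ordering recovery (100 seeds) uses egg data at the
combined scale of the two egg experiments (108 five-female groups over
five runs) with the full 2450-bean survival design, at which a sign error
in the reliable-vs-no-cue contrast is a ~2.4-sigma event. The likelihood-ratio null calibration
(1,000 simulations) uses a design whose replication unit carries the
tested factor — the Poisson egg model with one group per trial and 100
trials — because that is where the chi-square reference distribution
applies; the within-trial treatment contrast on the behavioural binomial
design is genuinely conservative at small trial counts (a property shared
exactly by `lme4::glmer` on the same data, not an artifact of this
implementation). The acceptance script runs the full pipeline once at the
study dimensions with the default MCMC schedule.

## Known limitations

* Multi-factor marginal likelihoods use the block-diagonal Laplace
  approximation — no quadrature refinement — and no REML-style correction;
  variance components in small samples are mildly biased, as with any
  Laplace-based fit.
* The sampler is a random-walk scheme; for strongly correlated posteriors
  the effective sample size per stored draw degrades and the schedule, not
  the kernel, must compensate.
* Pooled-per-treatment egg weighting and index-paired uncertainty
  propagation are conventions, stated above, not derivations.
* The load model is an equilibrium statement under soft selection with
  homogeneous selection across loci within a habitat; drift,
  migration–selection polymorphism and antagonistic pleiotropy are out of
  scope.
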