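---
title: "Two-part spatial-temporal modelling of under-reported event counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-part spatial-temporal modelling of under-reported event counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hurdlemap)
```

## The problem

Police-reported counts of domestic violence (and of under-reported offences
generally) are the outcome of two coupled processes: whether a victim files a
report at all, and how many incidents occur. Because the decision to report
correlates with unobservables that also drive incidence — *endogenous
selection* — the recorded counts cannot be de-biased by standardisation or
weighting. `hurdlemap` implements the standard small-area answer: a two-part
(hurdle) hierarchical model, fitted jointly, on an unbalanced panel of census
tracts observed over several annual periods.

## The model

Let $Y_{it}$ be the report count in tract $i$ ($i = 1,\dots,n$) and period
$t$ ($t = 1,\dots,T$), and $n_i$ the tract's population at risk.

**Reporting part** (binomial):
$$Y_{it} \mid P_{it} \sim \mathrm{Binomial}(n_i, P_{it}), \qquad
\operatorname{logit}(P_{it}) = \beta_0 + x_i'\beta + \eta_i + S(x_i) + \tau_t.$$

**Count part** (Poisson, not truncated — appropriate when zero-count
tract-periods are rare):
$$Y_{it} \mid \theta_{it} \sim \mathrm{Poisson}(\theta_{it}), \qquad
\log(\theta_{it}) = \beta_0^\ast + x_i'\beta^\ast +
\alpha\,(\eta_i + S(x_i) + \tau_t).$$

The two parts are estimated **together** as a stacked likelihood sharing the
three random effects: $\eta_i \sim N(0, \sigma_\eta^2)$ i.i.d. tract
heterogeneity; $\tau_t$ a first-order random walk with innovation variance
$\sigma_\tau^2$, constrained to sum to zero; and $S(\cdot)$ a zero-mean
Gaussian field with Matérn covariance

$$\operatorname{Cov}(S(x_i), S(x_{i'})) =
\frac{\sigma^2}{2^{\nu-1}\Gamma(\nu)} (\kappa\|x_i - x_{i'}\|)^\nu
K_\nu(\kappa\|x_i - x_{i'}\|),$$

with $K_\nu$ the modified Bessel function of the second kind and practical
range $\rho = \sqrt{8\nu}/\kappa$, the distance at which the correlation has
fallen to about 0.1. The sharing scale $\alpha$ defaults to 1 (fully shared
latents) and can be estimated. Each part carries its own fixed-effect vector;
$e^\beta$ is the odds ratio (reporting part) or rate ratio (count part) of a
covariate.

Two interpretations of the binomial response coexist in practice and both are
supported via `fit_hurdle(..., response = )`:

* `"count"` (default): the report count out of the tract population, the
  model exactly as the link functions are written;
* `"indicator"`: the binary any-report outcome. This is the Bernoulli
  likelihood of the *reporting gate* in the generative hurdle (below), and is
  the configuration in which the reporting part's coefficients equal the
  gate's generative coefficients — which is why the package's
  parameter-recovery experiments use it.

## Covariates and the deprivation index

Covariates are tract-level constants from a single census: six deprivation
indicators (unemployment, manual workers, temporary workers, incomplete
compulsory schooling, incomplete schooling among the young, no internet
access), two small-housing percentages, and four foreign-population
percentages. The composite deprivation index is the first principal component
of the six standardised indicators, sign-oriented so that higher = more
deprived; this is the standard construction when the original published index
weights are unavailable, and it is flagged as such.

Quintile coding follows the conventional small-area scheme:
deprivation and adult schooling enter as a single Q4–Q5 dummy (reference
Q1–Q3), young-population schooling as a Q1–Q3 dummy (reference Q4–Q5),
unemployment as four dummies Q2–Q5 (reference Q1), and the remaining nine
covariates as raw percentages — 16 design columns in all
(`design_columns()`). Quintile boundaries are the 20/40/60/80th percentiles;
intervals are left-closed with ties to the lower quintile (chosen for
determinism; with all-equal values every tract lands in the reference
category).

## The synthetic-data generator

No public accession of the motivating study's data exists, so the package
generates its own study conditions (`synthetic_scenario()`), and these
defaults *are* the conditions under which the package's claims are tested:

* **Geography** — 100 tracts as Voronoi cells of uniform points on a 10 km
  square (census-tract-like contiguous irregular polygons), populations
  log-uniform in [500, 3000] (the size range of Spanish census tracts).
* **Covariates** — the six indicators share one latent deprivation factor
  (loading 0.7) plus indicator noise, so the index is meaningful; marginal
  means/SDs are calibrated to a deprived mid-sized city (unemployment
  24.46 (9.47), etc.); foreign-origin subgroups are Dirichlet shares of the
  foreign total, so they can never exceed it; everything is clipped to
  [0, 100].
* **Latents** — Matérn field with $\sigma^2 = 0.3$, $\nu = 1$, range 3 km
  (a third of the domain — visible but not domain-filling structure);
  $\sigma_\eta^2 = \sigma_\tau^2 = 0.05$.
* **Counts** — the generative model is gate-then-count: a Bernoulli reporting
  gate with probability $\operatorname{logistic}(\ell^1_{it})$, then, if the
  gate is open, a Poisson count with rate $\exp(\ell^2_{it})$, both
  predictors sharing all latents. This reproduces exactly the endogenous
  selection the two-part model addresses; it is simulator semantics, not a
  claim about how the fitted likelihood factorises.
* **Reporting level** — the default gate intercept (2.2, gate probability
  ≈ 0.9 at reference covariates, lowered by the deprivation odds ratio
  0.573) keeps zero-count tract-periods rare. This mirrors the observed
  regime of the motivating study (few zero tracts, the stated justification
  for a non-truncated Poisson count part). It matters: when gates close
  often, the structural zeros masquerade as tract-level overdispersion in
  the stacked Poisson part and are absorbed by $\eta$ — a model-mismatch
  regime, not the regime the method targets.
* **Panel** — 7 annual periods; 5% of tract-periods removed completely at
  random (unbalanced panel); zero rows either explicit or absent via a flag.

What the generator does **not** emulate: the real joint distribution of
census covariates (only marginals and one shared factor), real tract
adjacency structure, time-varying covariates, or spatially structured
missingness. Passing tests therefore demonstrate internal coherence of the
method under realistic magnitudes, not performance on any particular city's
data.

## Priors

All unreported in the motivating work, so weakly-informative defaults are
used and fully exposed (`prior_config()`): $N(0, 5^2)$ on every coefficient;
half-normal(1) on $\sigma_\eta$, $\sigma_\tau$, $\sigma$; log-normal on the
range $\rho$ with median 20% of the study-area diameter and log-SD 0.7;
$\nu$ fixed (default 1, the customary choice at areal scale) because it is
only weakly identifiable; $N(1, 0.5^2)$ on $\alpha$ when estimated.

## Inference

The posterior targets `joint_loglik()` plus the log-priors. Nested-Laplace
approximation schemes fit this model class well, but the package uses its own
documented MCMC so that the target density — not any particular
approximation — is the contract:

* **Latent block.** $\eta$, $S$, $\tau$ are sampled in a non-centred
  parameterisation (standard-normal innovations scaled by their hyper-
  parameters; $S = \sigma L_\kappa z$ with $L_\kappa$ the Cholesky factor of
  the Matérn correlation) by **elliptical slice sampling** — tuning-free and
  exact for Gaussian-prior blocks.
* **Coefficient blocks.** Each part's $(\beta_0, \beta)$ uses adaptive
  random-walk Metropolis, preconditioned by the prior-regularised IRLS
  covariance $(X'WX + I/\mathrm{sd}^2)^{-1}$ (bounded even under separation)
  and refined during warmup (Haario adaptation plus acceptance-rate tuning
  to 0.234); three sweeps per iteration.
* **Hyperparameters.** A joint adaptive Metropolis block on the log scale
  with the latent innovations held fixed, **interwoven** (ASIS) with centred
  updates given the natural latent values — the standard cure for the
  funnel-shaped coupling between a variance and its field.
* **The $\eta$/$S$ split.** The likelihood sees only $\eta_i + S_i$, so the
  decomposition is resampled exactly from its conjugate normal conditional
  each iteration — without this Gibbs step the two fields and their
  variances mix extremely slowly.
* **Confounding moves.** Tract-level covariates and the latent fields span
  overlapping directions. A dedicated likelihood-invariant "shift" move
  proposes $\beta \to \beta + \delta$, $\beta^\ast \to \beta^\ast +
  \alpha\delta$, $\eta \to \eta - (\delta_0 + X\delta)$ and accepts on the
  prior ratio alone, walking along the flat direction that blocked updates
  cannot traverse.

$\tau$ keeps its sum-to-zero constraint (it is exactly collinear with the
intercepts otherwise). $\eta$ and $S$ are *not* sum-to-zero constrained:
their proper priors already pin their means (the prior variance of
$\bar\eta$ is $\sigma_\eta^2/n$), the exact-split and shift moves require
proper densities, and leaving them unconstrained keeps the centred ASIS
updates conjugate. This is a deliberate design choice; the intercept-level
confounding it tolerates is handled by the shift move.

Chains are initialised at jittered prior-regularised IRLS estimates — a
data-driven starting point that does not alter the target. Convergence is
monitored by split-$\widehat R$ and effective sample size on every stored
scalar (`diagnostics()`); a warning fires when any core (non-latent) scalar
exceeds $\widehat R > 1.05$. Runs are deterministic given `(data, config,
seed)`; all sub-streams derive from the single seed by a fixed affine map.

## Risk surfaces and hotspots

The mapped quantity is the model-unexplained residual risk,
$RR_i = \exp(S_i + \eta_i)$ per posterior draw — spatial plus unstructured
components, time-aggregated (the temporal effect is excluded by default; a
switch folds in mean-centred covariate contributions for a full-risk map).
By default the reporting part's latent scale is mapped; `part = "poisson"`
rescales by $\alpha$. The exceedance probability
$PRP_i = \Pr(RR_i > 1 \mid \text{data})$ is the fraction of draws strictly
above 1, and the conventional 80/20 interpretation rule labels tracts
`hotspot` ($PRP > 0.8$), `coldspot` ($PRP < 0.2$), or `uncertain` —
boundary values resolve to `uncertain`. Note one degenerate corner: a
posterior point mass exactly at $RR = 1$ has $PRP = 0$ under the strict
inequality, and is labelled coldspot; with any posterior spread the label is
`uncertain`, which is the behaviour that matters in practice.

## Numerical choices

* Matérn evaluation on the log scale (stable prefactor); exact $\sigma^2$ at
  zero lag; covariance matrices get a diagonal jitter of
  $10^{-8}\sigma^2$, escalated threefold by factors of 10 before a
  factorisation failure is reported.
* Binomial log-likelihood via `log1p(exp(·))` with a linear tail above 35,
  finite for predictors up to $|700|$.
* Point-in-polygon assignment (ray casting with an on-edge test); a point on
  a shared boundary goes to the lexicographically smallest tract id.
* Simulated Poisson predictors above 30 abort with a rescaling hint rather
  than overflowing.
* Quintile ties go to the lower quintile; see above.

## Problem sizes used by the test suite

The package's empirical claims are checked at sizes a reviewer can rerun at a
desk: likelihood identities on a 3-tract × 2-period fixture against
term-by-term oracles; GLM-limit equivalence on 200 tracts with latent
variances pinned to zero; parameter recovery on 20 replicate studies of 100
tracts × 7 periods (95% interval coverage and posterior-mean bias of the
deprivation reporting effect); hotspot calibration on three null studies and
detection of one doubled-risk region of a 100-tract study; Monte-Carlo checks
of the field's marginal variance (2000 widely-spaced tracts) and of the
range-correlation convention. Sampler settings in these experiments are
reduced (hundreds of kept draws per chain) — enough for the interval-level
statements tested; production analyses should run longer chains and watch
`diagnostics()`.

## Known limitations

* Dense Cholesky factorisations bound practical problem sizes to a few
  hundred tracts — appropriate for single-city analyses; no SPDE/mesh
  approximation is provided.
* The stacked two-part likelihood evaluates both parts on every observation;
  no zero-truncated or zero-inflated mixture variant is offered.
* No model comparison (WAIC/DIC), no cross-validation utilities.
* The count-response variant entangles gate and intensity effects when data
  are generated by a gate-then-count mechanism with frequent closed gates;
  in that regime the indicator variant is the interpretable one.
* Geographic coordinates must be projected (metres) upstream; the package
  computes Euclidean distances only.
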