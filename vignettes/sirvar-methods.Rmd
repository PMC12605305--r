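---
title: "Variance estimation for Log-SIR provider profiling: models, conventions, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance estimation for Log-SIR provider profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical content: the model
and the quantity being estimated, the three variance estimators and the
conventions each one requires, the synthetic cohort generator and the Monte
Carlo ground truth used to score the estimators, and the numerical and
design choices made where more than one defensible option existed.

## Model and target quantity

Patient `i` in center `c` has a binary outcome (here: treated close to home)
modeled by a random-intercept logistic regression

$$\mathrm{logit}(p_{ci}) = \beta_0 + \beta_1 x_{1ci} + \dots + \beta_k x_{kci} + u_c,
\qquad u_c \sim N(0, \sigma_u^2),$$

fitted by `fit_glmm()` (Laplace approximation via lme4; the contract is a
deterministic fit that reports its log-likelihood and collapses to plain
logistic regression when $\sigma_u^2 = 0$, both covered by tests). Center
performance is summarized by indirect standardization:

$$\text{Log-SIR}_c = \log\!\frac{O_c}{E_c}, \qquad
O_c = \sum_{i \in c} y_i, \qquad E_c = \sum_{i \in c} \bar p_i,$$

where $\bar p_i$ is the **marginal** predicted probability, i.e. the random
effect is integrated out over $N(0, \hat\sigma_u^2)$ by 41-node
Gauss–Hermite quadrature (`predict_probabilities(mode = "marginal")`).

*Why marginal and not conditional?* If a center's own predicted intercept
$\hat u_c$ entered its expected count, $E_c$ would chase $O_c$ and every SIR
would collapse toward 1 by construction — indirect standardization requires
the reference model, not the center's own effect. The marginal convention is
also the only one coherent with the analytic variance formulas below, which
treat $u_c$ as a zero-mean random contributor to every linear predictor.
Conditional prediction is retained for diagnostics.

A center with $O_c = 0$ has no finite Log-SIR. The default leaves it
explicitly flagged `undefined`; a `halves` correction ($O+0.5$, $E+0.5$) is
available for simulation harnesses. Nothing is ever silently imputed.

## The three variance estimators

### Delta method

First-order propagation through $g(O, E) = \log(O/E)$ with gradient
$(1/O, -1/E)$:

$$\widehat{\mathrm{Var}}(\text{Log-SIR}_c) \approx
\frac{\mathrm{Var}(O_c)}{O_c^2} + \frac{\mathrm{Var}(E_c)}{E_c^2}
- 2\,\frac{\mathrm{Cov}(O_c, E_c)}{O_c E_c}.$$

The components carry the within-center correlation induced by the shared
random effect, with $a_i = p_i(1-p_i)$:

* $\mathrm{Var}(O_c) = \sum_i a_i + 2\sum_{i<j} a_i a_j \sigma_u^2$
* $\mathrm{Var}(E_c) = \sum_i a_i^2\,\mathrm{Var}(\eta_i) + 2\sum_{i<j} a_i a_j \sigma_u^2$
* $\mathrm{Cov}(O_c, E_c) = \sum_i a_i\,\mathrm{Var}(\eta_i) + 2\sum_{i<j} a_i a_j \sigma_u^2$

Three conventions deserve comment:

1. **$\mathrm{Var}(\eta_i)$.** Setting the pairwise covariance of linear
   predictors to exactly $\sigma_u^2$ is only coherent if $\beta$ is treated
   as known, so the default is $\mathrm{Var}(\eta_i) = \hat\sigma_u^2$
   (plug-in $\beta$). `var_eta_mode = "plus_fixed"` adds the estimation
   terms $x_i' \hat\Sigma_\beta x_j$ to the diagonal and pairwise sums for
   sensitivity analysis; a brute-force double-loop test pins the
   closed-form implementation of that mode.
2. **Pairwise product form.** The Bernoulli pair covariance is implemented
   as the product $a_i a_j \sigma_u^2$ (an unusual exchange-correlation
   form, but the one the formulas above state); a square-root variant
   $\sqrt{a_i a_j}\,\sigma_u^2$ sits behind `pairwise = "sqrt"` for
   sensitivity only.
3. **Negative values.** The expression is not a quadratic form and can go
   negative; it is floored at zero with a warning, never silently.

All pairwise sums use the identity
$2\sum_{i<j} a_i a_j = (\sum a_i)^2 - \sum a_i^2$, verified against an
$O(n^2)$ loop to $10^{-12}$ on random instances.

**Accuracy envelope.** Against the Monte Carlo ground truth (below), the
per-center delta estimate is within 25% of the truth for every center at
$\sigma_u^2 \in \{0, 0.05\}$ with 300-patient centers. At
$\sigma_u^2 = 0.25$ the first-order approximation degrades for strongly
outlying centers — the term
$\sigma_u^2 (\sum a_i)^2 (1/O - 1/E)^2$ no longer cancels when $O$ drifts
far from $E$ — and the estimate is only reliable to rough magnitude
(observed ratios ~0.7–2.1). The test suite asserts exactly this: tight
calibration at small-to-moderate heterogeneity, order-of-magnitude
agreement at $\sigma_u^2 = 0.25$.

### Nonparametric bootstrap

Patients are resampled with replacement B times (default B = 5000;
`B = 200` in the simulation suites) and Log-SIR$_c$ recomputed per
replicate; $\hat\sigma^2_{\text{Boot}}$ is the sample variance over defined
draws ($n_{\text{defined}} - 1$ denominator). Choices:

* **Stratified by center by default**: it preserves center sizes, which the
  funnel x-axis depends on. Unstratified resampling is retained for
  sensitivity; a center absent from a replicate yields an undefined draw.
* **`refit` vs `fixed_model`**: refitting the mixed model per replicate is
  the faithful default; `fixed_model` keeps the baseline probabilities
  attached to resampled rows and recomputes only $O^*$ and $E^*$ — it is
  the mode used in replicate studies and the acceptance script, where
  thousands of refits would dominate runtime without changing what is being
  compared.
* **Intervals are percentile** (type-7 quantiles), not mean ± 1.96·SE:
  bootstrap interval asymmetry is real information.
* $O^* = 0$ draws are dropped from moments and counted; a center with more
  than 20% undefined draws carries a warning. On a toy center the undefined
  frequency is tested against its exact enumerated probability.

The single-center oracle: with constant $\hat p = 0.5$ and $n = 500$, the
fixed-model bootstrap distribution of $O^*$ is Binomial, so the bootstrap
variance is checked against exact enumeration of
$\mathrm{Var}(\log(O/E) \mid O \ge 1)$ (within 20%, plus a two-seed
replication band of four standard errors of a sample variance).

### Bayesian MCMC

The posterior of $(\beta, u_1,\dots,u_C, \tau)$ under the Bernoulli
likelihood, independent $N(0, 100)$ priors per coefficient and
$\tau \sim \mathrm{Gamma}(0.001, 0.001)$, $\sigma_u^2 = 1/\tau$. The
coefficient prior is deliberately weakly informative and user-overridable;
tying the coefficient prior to the random-effect variance would shrink
coefficients by an unrelated quantity.

The sampler (Rcpp) is an adaptive Metropolis-within-Gibbs kernel:

1. block random-walk Metropolis for $\beta$ (proposal shaped by the
   penalized-logistic curvature, global scale adapted to 0.234 acceptance
   during burn-in only),
2. per-center random-walk Metropolis for $u_c$ (scales adapted to 0.44),
3. conjugate Gibbs draw
   $\tau \mid u \sim \mathrm{Gamma}(a + C/2,\; b + \tfrac12\sum u_c^2)$,
4. independence proposals from the priors for $\beta$ and for $(\tau, u)$
   jointly, accepted with probability $\min(1, L^*/L)$.

Step 4 costs one likelihood evaluation and is what makes the no-data limit
exact: with an empty likelihood the proposals are always accepted, so prior
recovery is testable; with data they are almost never accepted and the
adaptive kernel does the work. A numerical subtlety: nearly half the mass
of $\mathrm{Gamma}(0.001, 0.001)$ lies below the smallest positive double,
so the prior draw of $\tau$ is made in log space (Marsaglia–Tsang
small-shape identity), and prior-recovery tests probe the CDF at
representable quantiles rather than asserting log-scale moments, which no
double-precision sampler could match.

Convergence: split-$\hat R$ and an effective sample size (Geyer
initial-positive-pair truncation) are computed for every coefficient and
for $\sigma_u^2$; any $\hat R > 1.05$ flags the result non-converged, and
`posterior_log_sir()` refuses to summarize a flagged result unless forced.

**The posterior functional.** Per retained draw, the center's expected
count is recomputed under the same marginal convention,
$E_c^{(s)} = E_c(\beta^{(s)}, \sigma_u^{2(s)})$, and
$\text{Log-SIR}_c^{(s)} = \log(O_c / E_c^{(s)})$ with the observed count
held fixed (the standard treatment of $O$ as data in SIR posteriors).
Summaries use all draws: mean, variance ($S-1$ denominator), type-7
2.5/97.5% quantiles. A consequence worth stating plainly: this posterior
variance carries the *parameter* uncertainty in $E_c$ and none of the
binomial sampling variability of $O_c$, so it is a different functional
from the sampling variance the delta method and bootstrap estimate. It is
systematically smaller and much more stable across replicate datasets —
which is exactly the qualitative pattern the estimator comparison reports
(lowest across-replicate variance for the Bayesian method). Cross-method
tests therefore assert distributional correctness of the sampler and the
stability ordering, not numerical agreement between the Bayesian and delta
variances.

## Synthetic cohorts and the ground truth

`generate_cohort()` draws covariates independently from declared marginal
distributions (a user-supplied joint sampler can replace this), center
effects $u_c \sim N(0, \sigma_u^2)$ plus optional planted logit offsets,
and Bernoulli outcomes. The default configuration mirrors a national
registry footprint: 36 centers labelled AI…RN, heterogeneous sizes from a
fixed log-normal quantile profile summing to 10,195 patients, ten
covariates (gender; 7 age bands; Indigenous status; lung disease; diabetes;
cardiovascular disease; late referral; BMI ≥ 30; 7 remoteness categories;
3 calendar periods), uniform level probabilities, and
$\sigma_u^2 = 0.04$ — a between-center standard deviation of 0.2 on the
logit scale, the scale suggested by per-center standard errors of a few
hundredths in registry profiling tables. The true coefficient vector
(`default_beta()`) uses modest negative comorbidity/access effects and a
mild period trend, giving pooled prevalence ≈ 0.43. These are conventions
of the generator, chosen once: registry profiling reports publish no
covariate distributions, center-size profile, or coefficient values.

What the generator does **not** emulate: covariate dependence (real
case-mix is correlated), informative center sizes, nonlinear age effects,
temporal drift within periods, and any geography behind "close to home".
Passing tests therefore demonstrate correctness of the estimators under the
stated hierarchical model, not robustness to real-data misspecification.

**Monte Carlo truth.** `monte_carlo_true_variance()` holds the covariate
matrix *and the realized center effects* fixed and redraws outcomes only,
recomputing $\log(O_c/E_c)$ with $E_c$ frozen at the marginal-model value;
the truth is the variance of those replicates (with $O_c = 0$ replicates
excluded and counted, and a center with no defined replicate flagged
missing rather than zero). Conditioning on $u_c$ is deliberate: the
variance attached to a center's Log-SIR is its sampling uncertainty given
that center's own true performance — if $u_c$ were redrawn, the "truth"
would contain the between-center variance component that indirect
standardization is designed to separate out, and no estimator of the
conditional sampling variance could match it. For centers with ≤ 12
patients the Monte Carlo truth is checked against exact enumeration of the
Poisson-binomial outcome distribution.

## Scoring and the funnel display

`evaluate_methods()` pools errors (estimate − truth) per method and reports
`bias`, `variance` (population-denominator variance of the pooled errors,
so that `mse = bias^2 + variance` holds exactly; the sample-denominator
version is reported alongside) and `mse`. Because pooled error variance
mixes between-center systematic differences with estimator noise, the
report also gives `variance_across_reps` — the mean over centers of the
replicate-to-replicate variance of the estimates — which is the right
quantity for "how stable is this estimator", and the one used for the
bootstrap-vs-Bayes stability comparison.

Funnel points carry: a center-anchored 95% interval (Wald at
$z = 1.959964$ for the delta method — the construction that reproduces
published 3-decimal profiling tables — percentile/credible limits for the
other two); zero-anchored FDR limits $(-z\,\hat{se}_c,\; +z\,\hat{se}_c)$;
and an effective sample size. The FDR limits are per-center funnel control
limits, *not* a Benjamini–Hochberg procedure; no multiplicity adjustment is
applied by default. "Effective sample size" is implemented as the precision
$\rho_c = 1/\widehat{\mathrm{Var}}(\text{Log-SIR}_c)$, which makes the
funnel envelope the standard $\pm z/\sqrt{\rho}$ curve (raw center size is
available as an alternative x-axis); this is a convention of the package,
chosen because it makes the envelope and the per-center limits one
construction. Classification is strict: `low` iff the point falls below its
lower limit. Table exports round to 3 decimals, half away from zero.

Under a true null ($\sigma_u^2 = 0$, correctly specified model) the
fraction of centers flagged stays below 10% across seeds — approximate,
because the delta variance is itself approximate. With $\sigma_u^2 > 0$
and no planted effects, flags at materially higher rates are expected and
correct: the per-center limits test "is this center average", and genuine
between-center heterogeneity is exactly what they detect. A planted
−0.5-logit center in a 36 × 300 cohort is detected as `low` in ≥ 90% of
seeded runs.

## Problem sizes, seeds, determinism

Every stochastic component takes an explicit seed; the pipeline derives
per-stage seeds from one master seed with a fixed stage code, so adding or
reordering methods never perturbs another method's stream. Identical
configuration gives byte-identical cohorts, CSV outputs and SVG figures.

Scales used by the shipped studies (chosen to exercise the study design at
desk scale): the estimator-comparison study runs 36 centers × 300 patients
at $\sigma_u^2 = 0.05$ with 12 replicate cohorts, bootstrap B = 200
(fixed-model) and MCMC 3 × 1,500 draws with 500 burn-in against a
3,000-replicate Monte Carlo truth; calibration sweeps use 12 × 250 cohorts
across $\sigma_u^2 \in \{0, 0.05, 0.25\}$; the full-footprint demonstration
runs the default 36-center, 10,195-patient cohort. The full-scale settings
(B = 5000; 25,500 iterations) remain the package defaults for analysis use.

## Known limitations

* Logit link only; no probit/cloglog, no Poisson model for aggregated
  counts, no crossed or nested random structures.
* The delta formulas inherit the plug-in treatment of $\beta$ and the
  product-form pair covariance; both alternatives exist only as sensitivity
  flags.
* The Bayesian Log-SIR functional (fixed $O$, marginal $E$) is not the
  sampling variance; see the discussion above before comparing its numbers
  to the other two methods.
* The bootstrap `fixed_model` mode understates refit uncertainty; use
  `refit` for final analyses.
* Single-center data cannot identify $\sigma_u^2$ and are rejected.
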