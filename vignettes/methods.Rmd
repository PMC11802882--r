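---
title: "Models and methods behind intertempo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind intertempo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the design choices that were genuinely open,
and what its simulation-based tests do and do not establish.

## The decision model

A trial offers a smaller-sooner amount $A_{SS}$ at delay $t_{SS}$ and a
larger-later amount $A_{LL}$ at delay $t_{LL}$ (delays in days, amounts
in USD). Two discount functions are implemented:

* hyperbolic, $SV = A/(1 + k\,t)$, with $k = e^{\log k}$ in units of
  1/days. Lower $\log k$ means more patience. The log transform
  normalizes the heavily skewed distribution of rates.
* constant-sensitivity (Ebert–Prelec), $SV = A\,e^{-(a t)^b}$:
  $a \ge 0$ (1/days) is impatience, $b > 0$ is dimensionless time
  sensitivity; $b = 1$ recovers exponential discounting and $a = 0$
  means no discounting at any horizon. The supplement describing the
  original parameterization was not available to us, so the
  conventional form above with $t$ in days was fixed as the package's
  definition.

Choice is stochastic through a lapse/acuity psychometric rule,
$p(\mathrm{LL}) = \varepsilon + (1 - 2\varepsilon)\,
\Phi\!\big((SV_{LL} - SV_{SS})/\alpha\big)$, with lapse rate
$\varepsilon \in [0, 0.5)$ and acuity scale $\alpha > 0$ in USD (the
units of a value difference). At a subjective-value tie the rule gives
0.5 regardless of the noise parameters, and the probability is bounded
in $[\varepsilon, 1 - \varepsilon]$.

## The choice set

The deployed 144-trial layout is reconstructed from its stated ranges:
smaller-sooner amounts \$15–\$85 on whole dollars; relative premiums
$A_{LL}/A_{SS} - 1$ spanning 2–100%; smaller-sooner delays of today,
2 weeks or 1 month (0, 14, 30 days); larger-later delays of 1 week to
6 months, always strictly later. The exact trial table is not public,
so the default grid crosses nine premiums with the sixteen admissible
delay pairs drawn from {7, 14, 30, 60, 90, 120, 180} days — an
approximation, documented as such. Calendar conventions are week = 7,
month = 30, year = 365 days. Rounding $A_{LL}$ to whole dollars can
undershoot the 2% premium floor for large $A_{SS}$; the constructor
enforces the floor with a ceiling correction. `balance_diagnostic()`
verifies the design intent: at the reference $\log k = -5.3$ roughly
half the trials favor the larger-later option (0.49 for the default
set), which maximizes the information carried by choices.

Catch trials place the larger reward at an equal-or-shorter delay, so
one option dominates on both attributes; they are flagged and excluded
from the likelihood, and used only for compliance screening.

## The hierarchical fit

The hierarchy is only partially pinned down by the source protocol, so
the remaining pieces are the package's design:

* $\log k_p \sim N(\mu, \sigma)$;
  $\mu \sim N(-5.3, 2.5)$ (the documented prior, centered so the
  choice set evenly samples preferences);
  $\sigma \sim \text{half-}N(0, 2.5)$;
* $\varepsilon_p \sim \mathrm{Beta}(1.1, 10.9)$ (mode near 0.01, mild
  mass up to ~0.3) and $\alpha_p \sim \text{half-}N(0, 50)$ USD —
  weakly informative for a task whose value differences span roughly
  \$0.3–\$85;
* Ebert–Prelec variant: $a_p \sim N(\mu_a, \sigma_a)\,T(0,)$ and
  $b_p \sim N(\mu_b, \sigma_b)\,T(0.05,)$ with
  $\mu_a \sim N(0.01, 0.05)\,T(0,)$, $\mu_b \sim N(1, 0.5)\,T(0,)$ and
  half-normal scales. The $a$ scale reflects that $a$ plays the role
  of a per-day rate like $k$ (typical values 0.001–0.1), and the $b$
  prior brackets exponential discounting.

Sampling is Gibbs/slice MCMC via JAGS. Chains are initialized from a
coarse per-participant profile-likelihood grid over $\log k$ (or an
$(a, b)$ grid) with per-chain jitter: with diffuse initialization the
$\alpha_p$ parameters mix very slowly, and the crude-estimate warm
start removes that pathology without touching the posterior.

Full-scale settings are 4 chains × 25,000 samples with 1,000 burn-in
(96,000 retained draws) and are the function defaults. Everything in
the test suite and acceptance script runs at desk scale, chosen by
prototyping convergence: 4 × 6,000 (1,000 burn-in) for the 20-agent
recovery study, and a few hundred to a few thousand draws for
smaller fixtures. These sizes are stated here as the package's own
reduced defaults; the full protocol is restored with
`pipeline_config(paper_replica = TRUE)`.

Convergence is assessed with the split rank-normalized $\widehat R$
(maximum of the bulk and folded statistics) against the conventional
1.01 threshold. Finite-sample noise can push the raw ratio slightly
below 1, so the statistic is clamped at 1; exactly constant chains
return 1 by convention. Non-convergence flags the result
(`converged = FALSE`) rather than erroring, and all-SS/all-LL
responders are fitted but flagged `boundary` — their data carry no
interior information about $\log k$, and the hierarchy supplies the
shrinkage. With zero choice data the model reduces to its priors,
which the tests exploit as a prior-recovery check.

Model adequacy is summarized by posterior-predictive classification:
the fraction of observed choices matching the modal prediction at
per-participant posterior means. On cohorts simulated at plausible
noise ($\varepsilon \approx 0.03$, $\alpha \approx 4$) this lands in
the high 0.8s–low 0.9s, bracketing what a well-fitting model of this
type achieves on real data.

## Questionnaire scoring

EAT-26 coding follows the published instrument, including the
reverse-anchored item 26. The response scale is described in places as
5-point but carries six labels (Never … Always); the six-label set is
implemented. A score of exactly 20 is assigned to the high-symptom
group by default — standard referral guidance treats 20 as elevated,
and the "above 20 / below 20" phrasing leaves the tie undefined — with
both cutoff and tie rule configurable. The bulimia-sensitivity variant
excludes items 4, 9 and 25 before summing, and group assignment is
re-derived from the reduced total.

CFC reverses items 3–5 and 9–12 (total 12–60); the ZTPI future
subscale averages its 13 keyed items (9, 24, 56 reverse-keyed); PFE is
the fraction of listed thoughts labeled future. BDI sums 21 items
coded 0–3; STAI-T sums 20 items with the published 9-item reverse key.
The ATQ negative-affect short-form key ships as an editable default
(no reversals) because item memberships of licensed short forms vary
by distribution — replace it with the administered form's key when
scoring real data. The synthetic generator produces responses under
the shipped keys, so the pipeline is self-consistent either way.

## Latent factors

Both composites (future orientation from CFC, ZTPI-future and PFE;
dispositional negativity from BDI, STAI-T and ATQ-NA) are the first
principal component of the correlation matrix. With one retained
component a varimax rotation is the identity; the code still runs the
rotation and asserts the identity rather than assuming it. Loadings
are signed so the majority are positive (ties broken toward a positive
loading sum), making the orientation deterministic. Factor scores use
the regression method on standardized variables — unit-variance scores
proportional to the loading-weighted sum — with plain component scores
available as an option since the original scoring method is not
stated. Rows with any missing instrument are excluded listwise before
fitting, which is why analysis n's vary by analysis. The identity
"variance explained = $\sum \lambda^2 / p$" for standardized
single-component solutions is exposed as `variance_from_loadings()`
and used to check published loading tables against their printed
variance figures.

## Temporal-accuracy tasks

Volle scoring is the per-condition mean signed error (estimate −
target, seconds) over the complete four-trial blocks; a wholly absent
condition is returned as NA and flagged rather than erroring, so
partial administrations remain scoreable. Zauberman growth ratios
divide subjective growth (relative slider change from the 1-week
anchor) by objective growth (relative calendar change); the anchor
slider must be positive. The horizon list beyond the anchor and the
10-year maximum is not public; the default grid is 1 week, 1 month,
3 months, 6 months, 1 year, 3, 5 and 10 years, and the per-participant
summary is the mean of per-trial ratios — both configurable, both
stated aggregation choices of this package. The ratio is invariant to
rescaling the slider but not to shifting it, a property the tests pin
down because it constrains how slider anchoring artifacts propagate.

## Inference

Group contrasts use pooled-variance Student t-tests with
$df = n_A + n_B - 2$ (the df convention the printed statistics
follow), one-tailed where a direction was pre-registered. The
between-group effect size is computed as
$d = t\sqrt{1/n_A + 1/n_B}$, which reproduces the scale of the
printed values; the original label for it ($d_z$) is conventionally a
within-subject quantity, so this identification is an interpretation,
documented here. Covariate-adjusted group effects use partial
(type-III style) F tests via `car::Anova` with sum contrasts.

Mediation is OLS with the predictor a 0/1 group indicator: $a$ from
the mediator equation, $b$ and $c'$ from the outcome equation, $c$
from the total-effect equation, covariates (when supplied) entering
both the mediator and outcome equations. Effects are reported
partially standardized — the mediator standardized, the outcome in SD
units, the binary predictor untouched — so the indirect effect is
$ab/\mathrm{SD}(Y)$ and $c = c' + ab$ makes total = direct + indirect
an exact algebraic identity. The bootstrap is a percentile interval
over participant resamples (default 10,000), the default interval type
of the PROCESS macro this mirrors. Rows are canonically sorted before
resampling so the interval is invariant to input row order under a
fixed seed; fewer than 1,000 resamples is allowed but recorded as a
warning in the result object.

## The synthetic cohort

The generator emulates the study's assumed statistical structure, not
its data: three latent traits — symptom severity $S$, future
orientation $F$, dispositional negativity $D$ — are multivariate
normal, item responses are graded (thresholded) functions of the
relevant trait with item-specific difficulty offsets, and true
$\log k$ is a linear function of $S$ and $F$ plus noise. Group
membership is *not* assigned directly: it is derived by scoring the
generated EAT-26 items and applying the cutoff, so the scoring path
and tie rule are genuinely exercised.

The default effect map is the study-scale set of effects: group
$d(\log k) = 0.314$ (high group lower), group $d(F) = 0.451$,
$r(F, \log k) = -0.26$, $r(S, D) = 0.314$, $r(F, D) = -0.290$, with a
high-symptom fraction of 57/152 and $n = 152$. A small solver
translates these into structural coefficients using closed-form
moments of the threshold-split standard normal (solving the
$d$-to-coefficient maps by one-dimensional root finding and the
correlations by linear algebra), erroring when the requested map
implies a non-positive-definite latent covariance. EAT-26 item
discrimination (2) and difficulty spread (±1.5, threshold steps of
1.5) were chosen so group totals resemble a screened community sample
(high/low means near 31/9) while keeping assignment close to the
latent boundary; the residual misclassification attenuates the
realized group effects by roughly 0.01–0.02 in $d$, well inside the
±0.05 calibration band verified at $n = 5{,}000$. Marginal $\log k$
is $N(-4.1, 1.5)$, matching the scale of the reported group means and
SDs; lapse rates are Beta(3, 97) (mean 0.03) and acuities
log-normal(log 4, 0.2), the plausible-noise regime. Temporal-task
data are generated with no group effects, matching the null results
for those tasks; demographics are age (weakly correlated with $S$),
gender and income.

What the generator does **not** emulate: real item-level responses
(actual EAT-26 items differ in content and difficulty far more than a
smooth offset grid), response times, recruitment-arm differences,
missingness mechanisms, or any causal structure — the planted
"mediation" is merely the correlational pattern. Passing tests
therefore show that the pipeline recovers known structure from data
generated under its own assumptions; they cannot certify behavior on
real cohorts.

Cleaning defaults (the pre-registered thresholds are not public):
exclude participants below 50% catch-trial accuracy or with incomplete
required instruments, with every exclusion logged by reason.

## Numerical choices and degenerate inputs

* Premium floors are enforced after rounding by a ceiling correction.
* The crude initialization grids span $\log k \in [-9, 1]$ and
  $a \in [5\times10^{-4}, 0.2]$, $b \in [0.4, 1.8]$ — wider than any
  behaviorally plausible value for this task's horizons.
* Stage seeds derive deterministically from one master seed
  (`seed * 1009 + stage * 9973 mod 2^31 - 1`), so pipelines are
  idempotent and each stage is independently reproducible.
* Zero pooled variance, constant correlation inputs, zero-variance
  factor variables, missing factor cells, rank-deficient designs and a
  zero anchor slider are all hard errors naming the offending input;
  empty cleaned datasets are allowed and logged.

## Known limitations

The Ebert–Prelec priors and the exact original trial grid, horizon
list, cleaning thresholds and ATQ key are reconstructions, flagged
above. The $\widehat R$ threshold is a convention, not a guarantee of
convergence. The mediation model is single-mediator and
cross-sectional; no causal claims attach to it. Real-cohort statistics
(the observed group means and test statistics) depend on the deposited
data and are outside what desk-scale simulation can or should
reproduce; the package checks the qualitative pattern end-to-end on
synthetic cohorts instead.
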