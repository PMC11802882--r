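# intertempo

Tools for studying **intertemporal choice** — the trade-off between
smaller-sooner and larger-later rewards — in relation to eating-disorder
symptomatology and future-oriented cognition. The package implements, as
a tested and reusable pipeline, the full analysis chain of a
community-sample delay-discounting study: behavioral task construction,
hierarchical Bayesian estimation of discount rates, questionnaire and
temporal-task scoring, latent-factor extraction, and bootstrap mediation
— together with a calibrated synthetic-cohort generator so that every
stage can be exercised and validated without access to participant data.

It is intended for researchers in computational psychiatry and decision
neuroscience who want a self-contained, scriptable version of this
analysis style, or who want to power and validate similar designs by
simulation.

## The models

**Discounting.** Each choice pairs a smaller-sooner reward (amount
*A_SS*, delay *t_SS* in days) against a larger-later one (*A_LL*,
*t_LL*). Subjective value follows the hyperbolic discount function

    SV = A / (1 + k t)

with the discount rate *k* estimated on the log scale, or the
constant-sensitivity (Ebert–Prelec) function

    SV = A exp(-(a t)^b)

separating impatience *a* from time sensitivity *b*. Choices are
stochastic via a lapse/acuity psychometric rule

    p(choose LL) = ε + (1 − 2ε) Φ((SV_LL − SV_SS) / α)

where ε is the probability of random responding and α (USD) the acuity
of the value comparison.

**Hierarchy.** Participants' log(*k*) values share a normal population
distribution whose mean carries a N(−5.3, 2.5) prior — centered so the
144-trial choice set predicts roughly equal smaller-sooner and
larger-later preferences. Sampling is by MCMC (JAGS) with split
rank-normalized R-hat convergence checks (threshold 1.01) and
posterior-predictive classification of choices. Symptom groups are fit
separately, since pooling dissimilar populations into one hierarchy can
distort group contrasts.

**Psychometrics and inference.** EAT-26 (with a bulimia-item-excluded
variant and a clinical cutoff of 20 for group assignment), CFC,
ZTPI-future, PFE, BDI, STAI-T and ATQ-NA scoring; single-component
varimax PCA latent factors for future orientation and dispositional
negativity; Volle time-estimation and Zauberman growth-ratio scoring;
pooled-variance t-tests with pre-registered one-tailed directions;
Pearson correlations; covariate-adjusted ANOVA; and PROCESS-style OLS
mediation with a percentile bootstrap CI for the partially standardized
indirect effect (a·b / SD(Y)).

## Worked example

```r
library(intertempo)

cfg <- pipeline_config(spec = cohort_spec(n = 40, seed = 5),
                       chains = 2, samples = 800, burn = 200,
                       n_boot = 1000, seed = 5)
run_pipeline(cfg)
```

```
<it_pipeline> n = 40 ( 16 high / 24 low )
  log(k) by group: t(38) = -0.059, one-tailed p = 0.4767
  future orientation by group: t(38) = 4.632, p = 0.0000
  r(F, log k) = -0.070 (p = 0.6667)
  indirect effect = -0.122, 95% CI [-0.694, 0.278]
```

The manifest reports, for a synthetic cohort of 40: the high/low
symptom split produced by EAT-26 scoring (16/24); the one-tailed pooled
t-test of posterior-mean log(*k*) by group (at n = 40 the planted
d = 0.314 group effect is well below detectability, hence p = 0.48);
the group test of the future-orientation factor score; the correlation
between the factor score and log(*k*); and the partially standardized
indirect effect of group on log(*k*) through future orientation with
its bootstrap CI. At the full design size (n = 152) the planted effect
pattern — lower log(*k*) and higher future orientation in the
high-symptom group, negative indirect effect — emerges in the majority
of seeds (see `tests/testthat/test-pipeline.R`).

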