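---
title: "Models and simulation design in ssripgx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and simulation design in ssripgx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssripgx)
```

ssripgx implements a complete pharmacogenomic analysis of SSRI treatment
response by CYP2C19 metaboliser status: genotype-to-phenotype translation,
a calibrated synthetic-cohort generator, the association model battery, and
a simulation-based power analysis. This vignette explains the models, the
defaults and why they were chosen, and what the synthetic data can and
cannot establish.

## Genotype-to-phenotype translation

CYP2C19 activity is summarised by star alleles. The package handles the
tier-1 panel: `*2` (rs4244285, loss of function), `*3` (rs4986893, loss of
function) and `*17` (rs12248560, increased expression), with `*1` as the
reference haplotype. Imputed dosages in $[0, 2]$ are converted to hard
calls when within a tolerance (default 0.1, the common hard-call
convention) of an integer; anything further from an integer becomes a
missing call, and participants missing any of the three sites are excluded
from analysis with an explicit count, never silently dropped.

Phasing uses the standard star-allele assumption that the three
variant-defining alleles are mutually exclusive in cis: each haplotype
carries at most one of them. A `*2`/`*17` double heterozygote is therefore
called in trans as `*2/*17`. Genotypes with more than two variant alleles
in total admit no phase-consistent haplotype pair and are reported as
indeterminate. Over all 27 possible genotype patterns this rule is total:
every pattern maps to exactly one diplotype or to indeterminate (an
exhaustively enumerated test asserts this).

Diplotypes translate to the five CPIC phenotypes:
`*17/*17` ultrarapid; `*1/*17` rapid; `*1/*1` normal; one loss-of-function
allele with `*1` or `*17` intermediate (the CPIC "likely intermediate"
sub-label for `*2/*17` and `*3/*17` is collapsed into intermediate, which
matches the five categories used throughout); two loss-of-function alleles
poor.

## The synthetic cohort generator

No individual-level data are distributed with this problem, so every
downstream stage is exercised on synthetic cohorts with known ground
truth. The generator's defaults describe a large adult depression cohort:

* **Genotypes.** Two independent haplotype draws per participant from
  $\{*1, *2, *3, *17\}$ at frequencies $(0.6458, 0.14, 0.0002, 0.214)$.
  Random mating implies Hardy–Weinberg diplotype frequencies, e.g.
  ultrarapid $p_{17}^2 = 4.58\%$ and poor $(p_2 + p_3)^2 = 1.97\%$. The
  observed cohort prevalences (4.7% and 2.1%) sit within sampling error of
  these; the observed normal and rapid prevalences deviate from
  Hardy–Weinberg expectation by about one percentage point, which a
  random-mating generator cannot and does not try to reproduce.
* **Demographics.** Age is normal with mean 42.8 y and SD 15.1 y,
  truncated to $[18, 90]$; because one-sided truncation would bias the
  realised mean upward by about 1.6 y, the latent location is calibrated
  by root finding so the truncated mean equals the target. Sex is
  Bernoulli with 76% female.
* **Drug exposure.** The number of SSRIs taken (1, 2 or 3 of sertraline,
  citalopram, escitalopram) is drawn with probabilities 0.69/0.25/0.06,
  then that many distinct drugs are chosen with probability proportional
  to the observed per-drug sample sizes. Independent per-drug Bernoulli
  draws at the observed marginals cannot reproduce the reported exposure
  overlap (about a quarter of participants on two drugs, 6% on three), so
  the two-stage scheme calibrated to the overlap is used instead.
* **Outcomes.** Each participant carries a latent intercept
  $u_i \sim N(0, \sigma^2)$ shared by all of their drug records
  ($\sigma = 1$ by default; the value is not identified by any published
  quantity, and $\sigma = 0$ is the documented degenerate point at which
  the mixed models must coincide with the fixed ones). Ordinal efficacy
  (1 = not at all well, 2 = moderately well, 3 = very well) follows a
  proportional-odds model against per-drug thresholds set to the observed
  normal-metaboliser splits (37/36/28% for sertraline, 36/39/25% for
  citalopram, 32/38/30% for escitalopram). Discontinuation-due-to-side-
  effects and any-side-effect are logistic with per-drug intercepts at the
  observed normal-metaboliser rates (46/45/38% and 70/65/71%). Twenty-
  three named specific side effects are exchangeable Bernoullis (default
  rate 0.15) sharing $u_i$; only three of the names (weight loss, fatigue,
  drowsiness) are anchored in reported results, the rest are plausible
  SSRI side-effect labels. Metaboliser effects enter every linear
  predictor as configurable log-odds offsets against normal; covariate
  effects default to zero (the study adjusts for age and sex but reports
  no estimates).

Two calibration caveats are deliberate. With $\sigma = 1$ the *marginal*
outcome rates are attenuated towards one half relative to the intercepts
(logistic-normal mixing), so the printed marginals are reproduced exactly
only at $\sigma = 0$ — which is how the calibration tests are run. And
`any_side_effect` is simulated from its own model rather than as the union
of the 23 specific binaries, so its marginal can be calibrated directly;
the two are therefore not deterministically consistent record by record.

What passing tests on these cohorts shows: the estimators recover known
generating effects, the type-I error is nominal, and the pipeline is
deterministic and complete. What they cannot show: robustness to recall
bias, dosage titration, phenoconversion from co-medication, linkage
beyond the three typed sites, or any real-data idiosyncrasy — none of
which the generator attempts to model.

## Association models

All inference is by maximum likelihood with Wald standard errors from the
observed information, matching the `OR [95% CI], p` reporting style of the
field; confidence bounds are $\exp(\hat\beta \pm 1.96\,\mathrm{SE})$.

**Proportional odds.** Efficacy uses the cumulative-logit model
$\mathrm{logit}\,P(y \le k) = \theta_k - x'\beta$ with $\theta_1 <
\theta_2$, fitted by Newton iteration with step-halving (likelihood never
decreases), convergence at gradient sup-norm $10^{-8}$, at most 100
iterations. Starting values are the marginal cumulative logits with
$\beta = 0$. Rank-deficient designs are an error; separation and
non-convergence are flagged on the returned object rather than raised, so
a scan over many small strata cannot die mid-way. A two-level ordinal fit
reproduces logistic regression exactly, which is tested.

**Logistic.** Binary outcomes (discontinuation, any side effect, each
specific side effect) use standard ML logistic regression with the same
flagging contract; constant outcomes are returned as non-identifiable.

**Random intercepts for pooled analyses.** Analyses pooling records
across drugs include a participant-level random intercept to account for
repeated measures, with drug, age and sex as fixed effects. The marginal
likelihood integrates the latent intercept by adaptive Gauss–Hermite
quadrature (15 nodes by default, the standard accuracy/cost point for a
single scalar random effect): the rule is recentred per participant at
the posterior mode of $u_i$ with scale from the curvature there, both
found by a vectorised inner Newton step. The analytic parameter gradient
is evaluated at the recentred nodes; the dependence of the adaptive
centre and scale on the parameters contributes only at the order of the
quadrature error and is omitted, which is accurate to far below the
optimiser's tolerance at 15 nodes. Tests verify the quadrature against
brute-force trapezoid integration (to $10^{-5}$ on a small fixture),
against an independent implementation (`lme4::glmer` with `nAGQ = 15`,
agreeing to about $10^{-4}$), and for stability under node doubling
(15 to 31 nodes moves fixed effects by less than $10^{-4}$). Data with no
repeated measures reduce to the fixed-effect model with $\sigma = 0$.

**Families and multiple testing.** Each of the four main families
(efficacy, discontinuation, any side effect, number of side effects)
compares four statuses against normal, so their Bonferroni threshold is
$0.05/4 = 0.0125$. The number of side effects is binned 0 / 1–2 / 3+ and
modelled with the same proportional-odds machinery — consistent with the
efficacy models and avoiding a count-distribution assumption; the bins
are configurable. The per-side-effect scan (specific side effects by drug
by status) uses $0.05/300$. In reports, `*` marks $p < 0.05$ and `**`
marks significance after the family correction.

**Crude odds ratios.** Two-by-two worked examples use the cross-product
ratio with the Woolf log-scale interval; zero cells trigger the
Haldane–Anscombe 0.5 correction and are flagged.

## Power analysis

The power study asks what log-odds effect each metaboliser group would
need for 80% power at nominal $p < 0.05$, given the observed group sizes
(199 poor, 2460 intermediate, 3869 normal, 2555 rapid, 448 ultrarapid).
For each effect on a grid corresponding to odds ratios of roughly 1.05 to
1.82, the two cumulative-logit threshold equations are built with the
target group carrying the effect and all others at zero, category
probabilities follow by inverse logit, one ordinal response is drawn per
observation, and the proportional-odds model with status, age and sex is
refitted; power is the rejection fraction over the replicates (1000 by
default, reducible for desk-scale runs). Non-convergent replicates count
conservatively as non-rejections and are tallied. The 80% threshold per
group is linearly interpolated along the grid. Baseline thresholds
default to $\mathrm{logit}(0.35)$ and $\mathrm{logit}(0.72)$, the pooled
normal-metaboliser efficacy split — the generating intercepts of the
original study are not published, so the observed baseline is the natural
stand-in. One observation per participant is simulated (the power
procedure is a plain ordered logistic regression, not a mixed model), and
effects are applied one status at a time because thresholds are reported
per status.

A caution on extreme effects: at very large simulated effects the target
group separates completely (all responses in the top category) and the
Wald statistic collapses (the Hauck–Donner effect), so estimated "power"
drops to zero. This is a property of Wald inference, not a bug; the
package's saturation tests therefore use large but Wald-regular effects.

## Numerical and design choices

* Wald inference throughout (the reporting style implies it; no test is
  named in the source material). Likelihood-ratio tests could be added
  but are not required by any output.
* Sex is coded female = 1; age is in years, uncentred — this affects only
  intercepts/thresholds, never the status contrasts.
* Participants missing an outcome for one drug still contribute to other
  drugs' models; each model uses its complete cases.
* Status levels unobserved in a model's stratum are dropped from that
  model's design rather than forcing a singular fit; the corresponding
  contrasts are simply absent from that model's rows.
* The pipeline derives per-stage seeds from the master seed as
  `seed + 1000 * stage_index`, so any stage can be rerun in isolation;
  identical configuration and seed give byte-identical output tables.
* Default problem sizes in the test-suite simulations are scaled to the
  question being asked: calibration checks use $10^4$–$2\times10^4$
  participants, parameter-recovery runs 100 replicates of 1200
  participants, the type-I-error check 500 replicates at $n = 400$, and
  the acceptance power runs 300 replicates at the full observed group
  sizes — enough for the Monte-Carlo error stated alongside each check.

## Limitations

The generator draws haplotypes under random mating and ignores linkage
disequilibrium with untyped alleles (`*4`–`*35` are out of scope, as is
imputation uncertainty beyond the dosage hard-call step). Ordinal
efficacy is assumed to satisfy proportional odds both in generation and
in fitting, so the tests cannot detect proportional-odds violations.
Adjusted odds ratios published for the real cohort are not reproducible
without the individual-level data; they are used here only as generating
effect sizes whose recovery is tested.
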