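---
title: "Valuing OxCAP-MH capability items from best-worst scaling data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing OxCAP-MH capability items from best-worst scaling data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capbws)
```

## The problem

The OxCAP-MH is a 16-item capability wellbeing questionnaire for mental
health, rated on 1--5 levels and conventionally scored with equal weights
across items (`equal_weight_score()`: the oriented level sum, 16--80, mapped
to 0--100). Capability items, however, are unlikely to matter equally: a
preference-weighted score needs relative importance weights for the items.
This package implements a complete valuation chain for eliciting such
weights from an object-case best-worst scaling (BWS, "MaxDiff") experiment:
respondents repeatedly see a subset of 6 of the 16 items and pick the one
most and the one least important to them. Because the items carry no levels
in the choice tasks, the design space is the set of item subsets rather than
the instrument's $5^{16} \approx 1.5\times10^{11}$ capability states.

The package covers: choice-task design, synthetic-respondent simulation,
hierarchical Bayes (HB) utility estimation with fit-based exclusion,
relative importance scores (RIS), cohort comparisons, jackknife robust
regressions, and construction of an anchored 0--1 preference weight set.

## Choice-task design

`generate_design()` builds questionnaire versions of 16 tasks with 6 items
each. Within a version every item appears $r = 16\cdot6/16 = 6$ times; a
strict balanced incomplete block design additionally has every unordered
pair co-occurring $\lambda = r(k-1)/(v-1) = 2$ times. The generator uses
random-restart pairwise-swap hill climbing: starts are exact in item
frequency, swap moves preserve it, and the objective minimises the sum of
squared pair co-occurrence counts, followed by a greedy pass balancing
display positions (lowest priority; a convention guarding against
reading-order bias). The search reports the achieved minimum alongside the
integer lower bound; a perfect $(16,6,2)$ design exists but hill climbing is
not guaranteed to find it, and near-balance (pair counts 1--3) is the
practically relevant outcome. Three versions are generated by independent
searches -- they share items, not tasks; whether a field study's blocks
re-randomise orderings instead is representable in the same design file.

```{r design, eval = FALSE}
design <- generate_design(16, 6, 16, n_versions = 3, n_iterations = 1000,
                          seed = 7)
validate_design(design)
```

## The choice model and its estimation

Each respondent $i$ holds a utility vector $\beta_i \in \mathbb{R}^{16}$
identified by sum-zero effects coding (15 free dimensions; utilities are
comparable across respondents and the importance transform is well
defined). A task showing set $S$ is answered sequentially:

$$P(\text{best} = j \mid S) = \frac{e^{\beta_j}}{\sum_{l\in S} e^{\beta_l}},
\qquad
P(\text{worst} = j \mid S, b) =
\frac{e^{-\beta_j}}{\sum_{l\in S\setminus\{b\}} e^{-\beta_l}}.$$

This sequential best-then-worst multinomial logit is the common default of
MaxDiff estimation tools; the paired (maxdiff-difference) alternative is
out of scope. The hierarchical model places
$\beta_i \sim \mathcal{N}(\mu, \Sigma)$ in the effects-coded space, with
weakly informative priors $\mu \sim \mathcal{N}(0, 100\,I)$ and
$\Sigma \sim \mathcal{IW}(d+3, I)$ ($d = 15$; `df_prior` defaults to
`n_items + 2`). `fit_hb()` alternates conjugate Gibbs draws of
$(\mu, \Sigma)$ with per-respondent random-walk Metropolis updates whose
isotropic step is adapted towards 30% acceptance during burn-in and then
frozen, so the post-burn-in chain is a valid fixed-kernel sampler. All
utilities start at 0; runs are deterministic given the seed. Defaults are
10,000 burn-in and 10,000 kept iterations with population draws thinned at
10; the package's tests use reduced profiles (2,000/2,000 for the full-size
fit, less for toys) chosen so that doubling the kept draws moves item-level
mean RIS by well under one score point.

### Fit statistic and exclusion

The root likelihood (RLH) of a respondent is the geometric mean of the 32
modelled choice probabilities (16 best + 16 worst picks); `fit_hb()` reports
it averaged over the kept draws, `compute_rlh()` evaluates it at any given
utility vector. For 6-item tasks a purely random responder has chance level
$\sqrt{1/6 \cdot 1/5} = 1/\sqrt{30} \approx 0.1826$. Following standard
MaxDiff practice, `filter_inconsistent()` excludes respondents with RLH
strictly below 0.2 (a value exactly at 0.2 is retained). Note the rule is a
rule of thumb sitting just above chance: a truly random responder's fitted
RLH concentrates *around* 0.18--0.21 (the 15 free parameters partially fit
noise), so it is excluded in most but not every realisation, and roughly 1%
of genuinely preference-driven but weak respondents can fall below the
threshold. This mirrors field experience, where single-respondent
exclusions are the typical outcome at moderate sample sizes.

### Relative importance scores

`compute_ris()` converts posterior-mean utilities by the probability
rescaling $p_k = e^{\beta_k} / (e^{\beta_k} + a - 1)$ with $a = 6$ the task
size -- the probability that item $k$ beats $a-1$ average items -- and
normalises to $\mathrm{RIS}_k = 100\, p_k / \sum_j p_j$. Each respondent's
16 scores are non-negative and sum to 100. The transform is *not* invariant
to adding a constant to all utilities; the sum-zero identification is what
anchors it. Items are ranked 1--16 by descending mean, ties broken by item
index.

## Cohort comparisons

`cohort_rank_table()` reports per-cohort means and rank orders;
`kruskal_wallis_by_cohort()` tests each item across cohorts on the
individual-level scores (the only level at which the rank test is valid;
cohort means alone would not support a test), using midranks with the
standard tie correction and the $\chi^2$ approximation. All 16 p-values are
always reported and deliberately not corrected for multiplicity. An
all-constant item -- possible in synthetic edge cases -- returns $H = 0$,
$p = 1$ rather than the 0/0 of the tie-corrected formula.
`pearson_matrix()` gives the between-item correlation structure of the
individual scores; constant columns yield flagged `NA`s, never silent
zeros.

## Jackknife robust regressions

Each item's RIS is regressed on a male indicator and two cohort contrasts
against the general-population (primary-care) reference, plus an intercept
($J = 4$). Because the scores are estimates with correlated errors, naive
OLS standard errors are not trusted; instead `jackknife_robust()` omits
each of the $n$ participants in turn, re-runs the supplied estimation
pipeline (`hb_fitter()`: full HB re-estimation with a recorded, reduced
MCMC profile and the inclusion set frozen from the full-sample fit so that
sample composition never depends on replicate-specific fit statistics;
`ols_fitter()`: direct re-regression), and sets

$$\hat v_{kj} = \frac{n-1}{n}\sum_{i=1}^n
\left(\tilde\beta_{kj}^{(-i)} - \hat\beta_{kj}\right)^2,$$

with $\hat s = \sqrt{\hat v}$, $t = \hat\beta/\hat s$, and two-sided
p-values from a $t$ distribution with $n - J - 1$ degrees of freedom (153
at $n = 158$). Significance stars are drawn at 0.05 / 0.01 / 0.001 without
multiplicity correction.

## The anchored preference weight set

`build_weight_set()` scales each item's mean RIS to a 0--1 contribution and
distributes it over the five answer levels with the multiplication factors
0, 0.25, 0.5, 0.75, 1 from worst to best capability -- the proportional-
levels assumption, implemented as stated but exposed through
`level_factors` in the instrument spec because level preferences are known
to be non-linear in related instruments and a future elicitation could
replace the factors. Eleven items are reverse coded (answer level 1 is the
best capability); their factor order is flipped, following the numeric
pattern of the published weight table (whose footnote text contains an
evident typo on orientation). `score_state()` sums the per-item level
weights: the all-worst state scores exactly 0 and the all-best state
$\sum_k \mathrm{RIS}_k / 100$, i.e. 1 up to the rounding of the published
means (which sum to 100.01). Weights are computed at full precision and
rounded to 4 decimals only on export; validation against the published
table reproduces 75 of its 80 cells cell-for-cell, the remainder being
half-ulp ties that the source evidently rounded from unrounded
(unpublished) means.

```{r weights, eval = FALSE}
ws <- build_weight_set(reference_ris()$ris_mean)
round(ws$weights[14, ], 4)   # Self-determination, reverse coded
score_state(ifelse(oxcap_mh_spec()$items$reversed, 1L, 5L), ws)  # all-best
```

## The synthetic respondent generator

The study's raw survey data are not deposited, so every downstream stage is
exercised on synthetic respondents whose generating process is exactly the
hierarchical MNL assumed by the estimator -- making parameter recovery a
well-posed check (a `scale` toggle in `simulate_responses()` mis-specifies
the logit scale for robustness experiments). The defaults encode the study
conditions: cohorts of 53 psychiatric patients, 50 primary-care patients
and 55 mental-healthcare experts (158 respondents), gender mixes of
60/64/55% female, and cohort mean utilities equal across cohorts except on
two items (*Freedom of expression* lower for psychiatric patients, *Having
suitable accommodation* lower for experts), shifted by one within-cohort
SD.

Two generator parameters are not pinned down by the published means and
were calibrated once, against pre-stated targets, then frozen:

* the consistency scale of the mean utilities (the importance transform is
  scale-free, so the published mean RIS fix only the *pattern* of
  $\mu$): set via a mean best-pick probability of 0.30, which reproduces
  the published spread of mean scores (0.76--15.72) and keeps genuine
  respondents clear of the 0.2 exclusion threshold;
* the between-respondent heterogeneity, $\Sigma = 1.2^2 I$, which matches
  the order of the published individual-level SDs.

What the generator does *not* emulate: item non-response, straight-lining,
attribute-order effects, non-MNL choice behaviour, and the empirical
correlation structure between items (the default $\Sigma$ is diagonal;
observed RIS correlations arise only through the sum-to-100 constraint).
Passing recovery tests therefore show the estimator is correct under its
own assumptions, not that those assumptions hold for any real survey.

## Numerical choices and limitations

* Likelihood evaluation is log-domain throughout; a zero probability can
  only arise from non-finite utilities and is reported, never underflowed.
* Ranks break ties by item index; the RLH exclusion boundary is strict
  ("below 0.2"), so 0.2 itself is retained.
* The degrees of freedom $n - J - 1$ follow the robust-variance
  construction; with leave-one-out HB re-estimation the jackknife is
  expensive ($n$ refits), which is why replicate profiles are reduced and
  recorded.
* Problem sizes in the shipped tests: one full-size fit (159 respondents,
  16 tasks, 2,000 + 2,000 iterations), toy designs with up to 8 items for
  enumeration oracles, 2,000 simulated nulls for rank-test calibration and
  100 replicates for power -- sizes chosen so the entire suite settles in
  well under a minute of sampling while leaving Monte-Carlo margins far
  from the asserted bounds.
* Profile-case (level-augmented) BWS, latent-class segmentation and
  non-proportional level weights are out of scope; the weight set is
  indicative, not a population-representative tariff.
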