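---
title: "Summary indices of family planning quality of care: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Summary indices of family planning quality of care: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpqual)
```

## The measurement problem

Quality of care for family planning is observed, in SPA-type facility
surveys, as dozens of binary items spread over three instruments: a facility
inventory, provider interviews, and client visits assessed both by an
interviewer's observation and by the client's exit interview. Condensing
these items into one per-facility score is common practice, but the three
standard mechanisms — a simple additive sum, a domain-weighted additive
index, and a first-principal-component score — embody different assumptions,
and they need not rank facilities alike. `fpqual` implements all three over
a shared indicator matrix, classifies facilities into terciles per score,
and quantifies inter-mechanism agreement, so that the choice of summary
measure can be examined rather than assumed.

## The indicator catalog and construction rules

The packaged catalog (`default_catalog()`) holds 53 binary indicators in 8
domains (sizes 3 / 5 / 6 / 17 / 15 / 1 / 2 / 4), each tagged with its
Donabedian component (structure or process), source instrument, and one of
five construction rules:

* **direct** — a facility-inventory flag used as-is. Structure items are
  defined as present *and* functional/unexpired on the day of the survey;
  that conjunction is encoded upstream in the raw field.
* **method_mix** — available method mix: at least one short-acting method
  (pill or injectable), AND at least one long-acting reversible or permanent
  method (implant, IUD, or sterilization), AND a barrier method (condom).
* **quality_assurance** — the facility routinely conducts *and documents*
  at least one of: a QA meeting report/minutes, a supervisory checklist, a
  mortality review, or an audit of records.
* **mean_dichotomize** — client- or provider-level binaries are averaged to
  a facility mean (plain mean within the facility; record weights are not
  used inside a facility), then dichotomized at the across-facility mean.
* **concordance** — three counseling items (told when to return, explains
  method use, explains side effects) are coded positive per client only
  when both the observation and the exit interview report them, then
  collapsed and dichotomized like any process item.

Two rules are applied everywhere and deserve emphasis:

* **Missing information is coded 0** — the assumption being that an
  unrecorded resource or action did not exist or occur. This applies to
  absent values, to facilities with no contributing records for an item,
  and to whole raw fields missing from the input tables (the affected
  indicator is forced to 0 with a prominent warning).
* **Dichotomization is inclusive** ("at and above the mean"): facilities
  exactly at the threshold are coded 1. A degenerate item where every
  facility is identical therefore codes all facilities 1, never all 0.

Only facilities with at least one observed family planning client on the
day of the survey enter the indices (`eligible_facilities()`).

### Weighting at the dichotomization step

Survey weights exist at all three record levels, but *where* they enter the
construction is a genuine design choice. The package's default uses
facility weights for the across-facility threshold (an estimate of the
population mean of facility means) and plain means within facilities, on
the reading that the analysis is weighted throughout while within-facility
client sets are small (typically 1–15 clients) and already
facility-specific. `run_config(weighted_dichotomize = FALSE)` switches to
unweighted thresholds.

## The three indices

For indicator values $x_{fj}\in\{0,1\}$, facility $f$:

* **Simple additive**: $S_f=\sum_j x_{fj}$, range 0–53. Assumes every item
  carries equal weight and the construct is unidimensional; heaps on a few
  values.
* **Weighted additive**: $W_f=\frac{100}{D}\sum_d \frac{k_{fd}}{n_d}$ with
  $D=8$ domains, $n_d$ items in domain $d$, $k_{fd}$ positives; range
  0–100. Down-weights items inside large domains so each *domain*, not each
  item, carries equal weight. Duplicating every item within its domain
  leaves $W_f$ unchanged (and doubles $S_f$) — a property the test suite
  checks.
* **PCA score**: an unrotated, unweighted PCA of the item correlation
  matrix; the first component's loadings $a_j$ serve as item weights,
  $P_f=\sum_j a_j z_{fj}$ with $z_{fj}$ the standardized indicator. The
  fitting sample's scores then have mean 0 and variance $\lambda_1$.

### PCA numerical choices

* The decomposition runs on the **correlation matrix** by default
  (standardized items), the conventional default for binary readiness
  items of very different prevalence; covariance mode is a flag.
* The PCA is **unweighted** — facility weights do not enter the
  decomposition; they re-enter at classification.
* **Sign convention**: an eigenvector's sign is arbitrary, so the first
  component is oriented with $\sum_j a_{j1}\ge 0$, making a higher score
  mean more items present on average.
* **Zero-variance items** are dropped from the PCA (their standardization
  is undefined) but retained in both additive indices; the fit records
  them and scoring lets them contribute 0.
* No loading threshold filters items: the score uses every analyzed item's
  first-component loading, however small.
* Whether loadings should multiply standardized or raw binary values is
  not standardized across the literature; the package defaults to
  standardized (`pca_score_standardized = TRUE`), which gives the score the
  clean variance-$\lambda_1$ property, and exposes raw mode as a flag.
* Dimensionality diagnostics: the scree table and the Kaiser count
  (components with eigenvalue $\ge 1$, inclusive). When the first component
  explains a small share of variance — the usual regime for this construct,
  where items are many and domains weakly coupled — a first-component score
  is a questionable summary, which is the core of the comparison this
  package enables.

## Tercile classification

Continuous scores are cut at the weighted 1/3 and 2/3 quantiles, defined as
the inverse of the left-continuous weighted empirical CDF (the smallest
observed value whose cumulative weight share reaches $p$). Boundaries are
lower-inclusive, and tied scores always share a category: additive scores
heap on a few integer values, and determinism is preferred over forcing
equal thirds by splitting ties arbitrarily. Consequently the three groups
can be unequal. All-identical scores raise an explicit
degenerate-classification error. Whether the quantiles use survey weights
is a flag (`weighted_terciles`, default on).

## Agreement statistics

Percent agreement is the weighted share of facilities given the same
category by two mechanisms. Cohen's kappa corrects it for chance:
$\kappa=(p_o-p_e)/(1-p_e)$ with $p_e$ from the weighted marginal products.
The null standard error uses the standard formula
$se_0=\sqrt{(p_e+p_e^2-\sum_i r_ic_i(r_i+c_i))/(n(1-p_e)^2)}$; the
effective $n$ is the sum of weights normalized to mean 1 (so with equal
weights it is the facility count — a pragmatic choice, not a design-based
variance estimator). The default test is one-sided ($\kappa>0$), matching
the convention of survey-stats kappa commands. Landis–Koch descriptive
bands label the estimate (0.81–1.0 near perfect, 0.61–0.80 good, 0.41–0.60
moderate, 0.21–0.40 fair, 0.0–0.20 poor, below 0 worse than chance).
Kappa is undefined when both categorizations are constant ($p_e=1$); that
is an error, not an NA.

## The synthetic-data generator

Real SPA microdata are restricted-access, so `simulate_spa()` generates
tables with the same linkage structure and a known truth:

* Each facility draws a latent quality vector $q_f$ over the 8 domains,
  multivariate normal with exchangeable correlation $\rho$
  ($\rho\in[-1/7,1]$ for positive semidefiniteness; default 0.5, a
  moderate coupling under which the mechanisms agree imperfectly —
  the interesting middle ground). Stratifier effects (facility type,
  managing authority, locality) shift the latent additively; hospitals and
  urban facilities sit higher, matching the usual gradient in facility
  surveys.
* Binary items are $\mathrm{Bernoulli}(\mathrm{logit}^{-1}(\alpha_j+\beta_j
  q_{f,d(j)}))$. Default intercepts cycle over $(-1.5,-0.7,0,0.7,1.5)$,
  spreading prevalences over roughly 18–82% as facility surveys show;
  default loadings are $\beta_j=1$.
* Clients per facility are $1+\mathrm{Poisson}(\mu-1)$ capped at a maximum
  (defaults: mean 3.5, max 15 — an average of 3–4 observed clients with
  range 1–15). Client-level process items add a per-client normal
  heterogeneity term (SD 0.5) to the logit. Providers number
  $1+\mathrm{Poisson}(1.5)$ per facility (≈2.5, the provider-to-facility
  ratio typical of these surveys).
* The three concordance items get exit-interview reports through a
  recall/false-positive channel: $P(\text{exit}=1\mid\text{obs}=1)$ = 0.9,
  $P(\text{exit}=1\mid\text{obs}=0)$ = 0.1 by default, emulating imperfect
  client recall.
* Weights are LogNormal(0, 0.25) normalized to mean 1 — mild, positive,
  nonresponse-style variation.
* `$truth` records each facility's latent vector, its equally weighted mean
  (the scalar "true quality"), and its true tercile, enabling rank-recovery
  tests.

Presets pin the two dimensionality regimes: `sim_unidimensional()`
($\rho=0.95$, uniform loadings — one latent dimension, first component
strong) and `sim_multidimensional()` ($\rho=0$, mixed loadings — variance
spread thin, first component under 15%). `sim_loading_dispersion()` holds
the unidimensional structure while varying loading spread, isolating the
mechanism by which uniform loadings make the PCA score mimic the simple
additive sum.

**What the generator does not emulate**: country-specific item
prevalences, cluster/spatial sampling designs, informative nonresponse,
item-level missingness patterns beyond the missing→0 rule, or outcome
measures. Passing tests on synthetic data therefore demonstrate the
*pipeline's* correctness and the *qualitative* regimes of the method, not
any country's empirical results, which require the restricted survey data.

## Problem sizes and determinism

The test suite and acceptance script run at 400–2000 synthetic facilities —
the order of a national SPA facility arm — with fixed seeds; the full suite
completes in well under a minute. Every stochastic step flows from a single
integer seed, and a fixed seed reproduces tables, scores, and agreement
statistics exactly (CSV outputs byte-identically, doubles printed at 15
significant digits).

## Known limitations

* The kappa variance is the null-hypothesis formula on an effective-n
  scale; it is not a design-based (linearized) estimator, and confidence
  intervals around nonzero kappa are out of scope.
* Tercile groups can be far from thirds under heavy score heaping; that is
  by design (ties share categories) but users comparing group sizes across
  mechanisms should inspect the cut points (`attr(x, "cuts")`).
* Mapping real SPA recode files into the catalog's raw-field vocabulary is
  the user's responsibility (a catalog variant with their field names);
  the package does not parse SPA recode formats.
* Oblique or orthogonal rotations, factor analysis, latent-class methods,
  and per-domain sub-scales are outside the package's scope; the PCA
  diagnostics are the tool it offers for judging dimensionality.
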