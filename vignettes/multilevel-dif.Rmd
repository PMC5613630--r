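---
title: "Detecting DIF in multilevel polytomous items: models, simulator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting DIF in multilevel polytomous items}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Health-related quality-of-life questionnaires and similar patient-reported
instruments are scored on ordered Likert scales, and respondents usually
arrive in clusters — children in schools, patients in hospitals. Before group
scores can be compared, each item must function equivalently across groups:
an item shows *differential item functioning* (DIF) when respondents with the
same underlying trait but different group membership (gender, school type)
have different response probabilities. *Uniform* DIF is a constant shift of
the item's difficulty across the whole trait continuum; *nonuniform* DIF
changes direction with the trait level.

The standard regression test for DIF in polytomous items is ordinal logistic
regression (OLR): regress the item response on the observed total score (a
proxy for the trait), then test whether adding the group indicator — and,
for nonuniform DIF, its interaction with the trait — improves the fit.
Clustered sampling violates the independence assumption behind that test, so
this package also implements the hierarchical counterpart (HOLR): the same
cumulative-logit model with a cluster random intercept, allowing grouping
variables at either the person level (within-cluster, e.g. gender) or the
cluster level (between-cluster, e.g. type of school). The package's purpose
is twofold: run these tests on real data, and measure — by Monte-Carlo
simulation — how much the hierarchical structure actually matters for Type I
error and power.

## The analysis models

Let $Y_{ij} \in \{0, \dots, K-1\}$ be the item response of person $i$ in
cluster $j$, and $\theta_{ij}$ the trait proxy (by default the raw total
score over all items, the studied item included). All models are
proportional-odds cumulative-logit models; we write them in the convention
$\mathrm{logit}\, P(Y_{ij} \le k) = \zeta_k - \eta_{ij}$, so a positive
coefficient in $\eta$ pushes responses toward higher categories.

**OLR.** Three nested single-level models are fitted to the studied item:

* $R_1$ (baseline): $\eta = \beta_1 \theta$
* $R_2$: $\eta = \beta_1 \theta + \beta_2 g$
* full: $\eta = \beta_1 \theta + \beta_2 g + \beta_3 (g \times \theta)$

The **uniform** DIF test is the likelihood-ratio comparison of $R_2$ against
$R_1$ (1 df); the **omnibus** test compares the full model against $R_1$
(2 df) and picks up uniform and nonuniform DIF simultaneously.

**HOLR.** The same comparison with a cluster random intercept
$u_j \sim N(0, \sigma_u^2)$ shared by both models. A within-cluster grouping
variable $G_{ij}$ enters the person-level predictor; a between-cluster
variable $G_j$ enters the intercept equation — computationally a
cluster-constant column of the fixed-effects design, tested with 1 df either
way. Because the tested term is a fixed effect and both models share the
random-intercept structure, the usual $\chi^2$ reference distribution
applies (no boundary-mixture issue).

The marginal likelihood integrates the per-cluster response probabilities
over $u_j$. `fit_holr()` evaluates that integral by adaptive Gauss–Hermite
quadrature: for each cluster the integrand's mode and curvature are found by
Newton iteration and the quadrature nodes are centred and scaled there. The
default is 15 nodes; on the package's test fixtures doubling to 31 changes
the log-likelihood by less than $10^{-4}$.

## The simulator

`simulate_dif_data()` generates data from a multilevel graded response
model, one replication of one condition of a factorial design:

* **Abilities**: $\theta_{ij} = u_j + e_{ij}$ with
  $u_j \sim N(0, \rho)$ and $e_{ij} \sim N(0, 1-\rho)$. The total latent
  variance is fixed at 1 so that the intraclass correlation $\rho$ and the
  discrimination scale do not confound each other; the literature this
  design follows states only the ICC values, not the scale, and variance 1
  is the standard identification.
* **Items**: for each of 16 items (15 DIF-free "core" items and 1 studied
  item), a discrimination $a_j$ uniform on $(0.5, 0.99)$ ("low") or
  $(1.5, 2)$ ("high"), and $K-1 = 4$ category thresholds drawn i.i.d.
  uniform on $[-2.5, 2.5]$ and sorted. Drawing and sorting four values keeps
  every threshold inside the stated interval and produces heterogeneous,
  ordered category boundaries; the alternative (one central difficulty with
  fixed offsets) concentrates the thresholds and was not adopted. Item
  banks are re-drawn each replication, so results average over instruments
  rather than conditioning on one.
* **Responses**: cumulative-logit GRM,
  $P(Y \ge k \mid \theta) = \mathrm{logis}\!\big(a_j(\theta - b_{jk})\big)$.
  The logistic link is used throughout so the generating model matches the
  analysis models; a probit (normal-ogive) variant would rescale all effects
  by roughly 1.7 and make the analysis misspecified in a way the study is
  not designed to measure.
* **Uniform DIF**: for focal-group respondents, `dif_magnitude` (0, 0.4 or
  0.8) is added to *all four* thresholds of the studied item only — a pure
  location shift against the focal group. Focal status comes from the person
  label (within) or the cluster label (between).
* **Groups**: balanced by construction. Even cluster sizes split each
  cluster half and half; for odd sizes exact per-cluster balance is
  impossible, so a random half of the clusters carries the extra focal
  person and the overall split stays exactly 50/50. Between-cluster
  grouping labels exactly half the clusters focal.

What the generator deliberately does **not** emulate: nonuniform DIF
(discrimination shifts), group differences in the ability distribution
(impact), unbalanced designs, more than two groups, missing responses,
disordered category use, and three-level nesting. Tests passing on this
generator therefore certify the machinery under clean conditions; real
instruments can fail in ways the simulation never exercises, which is why
`screen_clustering()` (per-item ordinal ICC and design effect) is part of
the recommended workflow before choosing between OLR and HOLR.

## The Monte-Carlo harness

`run_cell()` runs one fully specified condition: per replication it draws a
fresh item bank, abilities, groups and responses, then applies **both**
methods' uniform tests to the *same* dataset, so the OLR/HOLR comparison is
paired. Cells with `dif = 0` estimate Type I error; `dif > 0` estimates
power, both at $\alpha = 0.05$. The harness uses the 1-df uniform test: the
simulated DIF is purely uniform and the corresponding hierarchical models
contain no interaction term. Replications where a method's component fits do
not converge are dropped from that method's denominator and counted
(`n_failed`); in practice failures are rare at the design's sample sizes.
`run_design()` crosses factor levels, gives each cell a disjoint seed range
(`base_seed + cell_index * 1e5 + replication`), checkpoints finished cells,
and emits a long-format table with the Monte-Carlo standard error
$\sqrt{r(1-r)/n}$ per cell and method.

Replication counts in the packaged tests are scaled to what the estimand
needs: 500 replications bound a power estimate's standard error by about
0.022, and 1000 replications give the Type I error a 99% binomial band of
roughly $0.05 \pm 0.018$ — the `[0.03, 0.07]` acceptance band used in the
test suite.

## Numerical choices

* **OLR engine**: `MASS::polr` with `reltol = 1e-12`, wrapped so that
  intercept-only models use their closed form, unobserved categories are
  collapsed to consecutive codes (both models of a comparison share the
  collapse, so LR tests are unaffected), and separation or a failed Hessian
  is flagged as non-convergence rather than silently reported.
* **HOLR optimizer**: `nlminb` on (first cutpoint, log cutpoint increments,
  slopes, $\log \sigma_u$), with an analytic gradient computed inside the
  quadrature (the posterior-weighted score). The gradient matters: adaptive
  quadrature gives the objective a small parameter-dependent ripple that
  breaks finite-difference gradients. A derivative-free simplex restart
  covers residual failures. $\sigma_u^2$ estimates below $10^{-8}$ are
  reported as boundary zeros.
* **Standard errors**: numerically differenced observed information, taken
  on a 31-node rule so the quadrature ripple does not contaminate the
  curvature; $\mathrm{SE}(\sigma_u^2)$ by the delta method from
  $\log \sigma_u$.
* **Starting values**: fixed effects from the single-level fit,
  $\sigma_u^2 = 0.1$; the DIF tests warm-start the group model from the
  baseline fit.
* **Ties/degenerate inputs**: thresholds are re-drawn in the measure-zero
  event of ties; fitting refuses responses with fewer than two observed
  categories; a between-level test refuses a group label that varies within
  any cluster (never silently reinterprets it).

## Diagnostics

`icf()` computes the item characteristic function
$E[X \mid \theta] = \sum_x x\, p_x(\theta)$, which for the GRM equals the
tail sum $\sum_{k \ge 1} P(Y \ge k \mid \theta)$ — an identity the test
suite asserts on random draws. Overlaying the curve with and without the
estimated group shift visualises uniform DIF directly. `icc_ordinal()` fits
the intercept-only random-intercept model and reports the latent-scale ICC
$\sigma_u^2 / (\sigma_u^2 + \pi^2/3)$ (logistic residual variance
$\pi^2/3$); the per-item design effect $1 + (\bar m - 1)\rho$ above the
conventional threshold of 2 is flagged as a recommendation to use HOLR.

## Worked example

```{r, eval = FALSE}
library(hordif)

# one simulated instrument: 50 schools x 10 children, gender-like grouping,
# moderate clustering, uniform DIF of 0.4 on the last item
d <- simulate_dif_data(n_clusters = 50, cluster_size = 10, icc = 0.25,
                       dif = 0.4, level = "within", disc = "high", seed = 7)

olr_dif_test(d, "item_16")                     # single-level uniform test
holr_dif_test(d, "item_16", level = "within")  # hierarchical counterpart
dif_scan(d, method = "HOLR", level = "within") # whole instrument

screen_clustering(d)                           # per-item ICC / design effect

# a small power study (two conditions, OLR only, 100 replications)
run_design(icc = 0.05, n_clusters = 50, cluster_size = 10,
           dif = c(0, 0.4), disc = "low", level = "within",
           n_reps = 100, base_seed = 1, methods = "OLR")
```

## Known limitations

* The total-score trait proxy is the field's convention and is kept even
  though it includes the studied item (a rest-score option exists); with
  strong DIF the contaminated proxy slightly depresses power.
* Random intercepts only: the framework in principle allows random slopes,
  but the analysis models used here (and the claims the package tests) are
  intercept-only. Crossed or three-level structures are out of scope.
* The simulator's power levels depend on the exact threshold scheme and
  link scale of the generating model; published factorial studies of this
  design do not always pin those down, so absolute power values from other
  implementations may differ by more than Monte-Carlo noise even when every
  qualitative conclusion (Type I control, monotonicity in sample size, DIF
  magnitude and discrimination, near-equivalence of OLR and HOLR)
  reproduces.
* No DIF effect-size measure is provided; the tests are purely
  significance-based, with an optional Benjamini–Hochberg adjustment in
  `dif_scan()`.
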