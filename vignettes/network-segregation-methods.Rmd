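---
title: "Methods: functional network segregation and brain-behavior association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional network segregation and brain-behavior association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netseg)
```

## What this package computes

`netseg` implements an end-to-end analysis of functional brain-network
*segregation* and its relation to cognition, of the kind used to study
dedifferentiation in cognitive aging. The inputs are per-subject node
time-series matrices (frames x nodes), a node atlas assigning nodes to
networks and networks to systems (association vs sensory-motor), and a
subject table of cognitive test scores plus covariates. The pipeline:

1. correlates each node's time course with every other node, Fisher
   z-transforms the Pearson matrix, and retains only positive values for all
   metrics except the signed mean within-network connectivity;
2. computes, per subject, association-system segregation, per-network
   segregation (DMN, FPN, CON), mean within-network connectivity,
   participation coefficient, and modularity;
3. derives five cognitive-domain factor scores from an 18-test battery by
   exploratory factor analysis with varimax rotation and regression-method
   scores, and averages them into an overall-cognition composite;
4. relates network metrics to cognition with partial correlations (site and
   cortical thickness as covariates) under one Benjamini-Hochberg FDR
   family, with a sensory-motor negative control and a multiple-regression
   supplement.

Because the kind of cohort this analysis is designed for cannot be
redistributed, the package ships a synthetic-cohort generator with planted
ground truth; every stage is validated against what was planted.

## The segregation model

For a network with mean within-network Fisher-z connectivity $Z_w$ (over
distinct node pairs inside the network; the diagonal is represented as
excluded and can never enter a mean) and mean between-network connectivity
$Z_b$ (from the network's nodes to the comparison scope), segregation is

$$S = \frac{Z_w - Z_b}{Z_w},$$

so $S = 1$ for a fully isolated network and $S = 0$ when within and between
connectivity are equal. $S$ is undefined for $Z_w \le 0$ and the package
raises an error rather than returning a value. *Network* segregation scopes
$Z_b$ to the other networks of the same system; *system* segregation is the
unweighted mean of network segregation over the system's networks. Two
genuinely open conventions are exposed as options rather than silently
fixed:

- **Between-scope.** The system-level between-scope is restricted to
  same-system networks by default (mirroring the network-level definition);
  `scope = "all"` widens it to all labeled networks.
- **Pair pooling.** `system_segregation(..., pooled = TRUE)` pools all
  within pairs and all between pairs across the system before forming $S$,
  instead of averaging per-network segregation values. The default follows
  the per-network-average reading.
- **Denominators under positive masking.** "Only positive correlations
  retained" is implemented as zeroing, not removal: zeroed entries still
  count (as zero) in pairwise-mean denominators. The masking state is an
  explicit flag on the connectivity object; metrics that require the masked
  matrix refuse the signed one and vice versa, so the signed
  within-connectivity metric and the masked segregation/graph metrics can
  never be computed from the wrong variant.

Participation coefficient uses the standard strength-based definition
$P_i = 1 - \sum_s (\kappa_{is}/k_i)^2$ with $P_i = 0$ when $k_i = 0$;
the reported value is the mean over association-system nodes. Modularity is
weighted Newman $Q$ with resolution $\gamma$; the *reported* metric is $Q$
of the atlas partition at $\gamma = 1$, while Louvain community detection
for data-driven relabeling runs at $\gamma = 1.2$. These are two different
uses with two different resolutions, kept separate on purpose. Louvain is
order-dependent, so `louvain_partition()` shuffles the node visit order per
restart from a recorded seed and keeps the best-$Q$ partition over 20
restarts by default; each restart ends with a greedy single-node-move
refinement on the original graph, and a parallel hill-climb from a random
initial partition, because greedy agglomeration from singletons can
provably miss optima that single-node moves from other starting points
reach. On small graphs this attains the exhaustively optimal partition.

## The synthetic cohort generator

`cohort_spec()` / `simulate_cohort()` define the study conditions:

- **Connectivity.** Each subject draws a within-network correlation $w$ and
  a between-network correlation $b$ from truncated normals constrained to
  $0 \le b < w$, separately for the association and sensory-motor systems
  (independent draws are what make the sensory-motor system a genuine
  negative control). Node time series are i.i.d. multivariate-normal frames
  from the block covariance: 1 on the diagonal, $w$ within networks, $b$
  between networks, with cross-system pairs at the average of the two $b$
  values. If a block fill is indefinite it is repaired by clipping negative
  eigenvalues and rescaling the diagonal to one. The subject's true
  segregation on the Fisher-z scale is
  $(\mathrm{atanh}\,w - \mathrm{atanh}\,b)/\mathrm{atanh}\,w$.
- **Defaults.** $w \sim \mathcal{N}(0.20, 0.035)$,
  $b \sim \mathcal{N}(0.105, 0.035)$ (truncated as above), 150 subjects,
  480 frames, a 90-node atlas with five association and four sensory-motor
  networks. These defaults were calibrated once so that the cohort's mean
  association-system segregation falls inside the range observed in
  published oldest-old cohorts (roughly 0.09-0.65, mean near 0.42-0.48);
  raw connectivity level is *not* matched to any particular study, since
  per-pair connectivity tables are generally not published. The across-
  subject spread of $(w, b)$ is deliberately generous: across-subject
  variance in true segregation is what a correlation analysis needs.
- **Cognition.** Latent cognition is
  $g = r\,\tilde S + \sqrt{1-r^2}\,\varepsilon$ with $\tilde S$ the
  standardized true segregation and $r$ the planted brain-behavior
  correlation, so $\mathrm{corr}(S, g) = r$ in population. Each of five
  domain factors loads on $g$ with loading $\sqrt{0.3}$; the factor-specific
  disturbances are *centered across the five factors*, which makes the true
  factor average track $g$ exactly while keeping factor intercorrelations
  near 0.12. This construction was chosen deliberately: if factors load on
  $g$ with independent noise, their intercorrelation equals the squared
  loading, and no single loading value can simultaneously give a
  well-conditioned five-factor eigenstructure (so parallel analysis finds
  five factors) and a factor average that tracks $g$ tightly (so the
  overall-cognition composite is a valid proxy). Centering the disturbances
  decouples the two requirements. Test $j$ is
  $\sum_k \Lambda_{jk} f_k + \sigma \epsilon$, with the default
  $18 \times 5$ loading matrix putting each test at 0.8 on exactly one
  domain and test noise $\sigma = 0.6$ (unit test variance).
- **Covariates.** Site is uniform over four labels. Cortical thickness is
  drawn independently of segregation by default; setting `ct_seg_rho` and
  `ct_cog_rho` plants a thickness confound into both segregation and the
  noise part of $g$, which is how the tests verify that partial correlation
  removes a confound that marginal correlation picks up.

What the generator does *not* emulate: hemodynamics, motion and censoring,
spatial structure within networks, heavy-tailed or skewed test score
distributions, site effects on measurement, and missing data mechanisms.
Passing tests therefore show the pipeline's statistical machinery is
correct under a block-Gaussian world with a linear brain-behavior link,
not that any particular real cohort satisfies those assumptions.

## Cognition stage

Factor retention uses Horn's parallel analysis: the number of leading
eigenvalues of the observed correlation matrix exceeding the 95th
percentile of rank-matched eigenvalues from 1000 random normal datasets of
the same shape, counted consecutively from the first. Extraction is
iterated principal-axis factoring (squared multiple correlations as
starting communalities; Heywood communalities clipped to 1 with a warning),
chosen as the standard companion to varimax in neuropsychological practice.
Rotation is Kaiser-normalized varimax via `stats::varimax`, with column
signs fixed so each factor's largest-magnitude loading is positive and
columns ordered by decreasing sum of squares. Scores are Thurstone
regression scores $Z R^{-1} \Lambda$ (ridge-regularized with a warning if
$R$ is singular), and overall cognition is the plain average of the five
scores — a missing score is an error, never silently averaged over.
Missing data handling is complete-case by default with an optional
column-mean imputation hook; pooled multiple imputation is out of scope.

## Statistics

Correlations are tested with $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees
of freedom, two-sided. Partial correlation is the correlation of OLS
residuals on the covariates (categorical site expanded to $k-1$
indicators), with degrees of freedom reduced by the covariate count. FDR
correction is Benjamini-Hochberg step-up with monotone q-values via
`stats::p.adjust`; the FDR family is the explicit set of predictor-outcome
pairs passed to `associate()`. The a priori power computation solves
$\mathrm{atanh}(\rho)\sqrt{n-3} = z_{1-\alpha/2} + z_{\beta}$; at
$n = 146$, $\alpha = 0.05$, power 0.80 this gives $\rho = 0.2301$, and a
Monte-Carlo check with the effect planted at 0.23 reproduces the 80%
rejection rate.

## Numerical choices and degenerate inputs

- Correlations of magnitude $\ge 1 - 10^{-6}$ are clipped before `atanh`
  (duplicated node time courses in toy data would otherwise produce
  infinities).
- Covariance square roots use Cholesky with an eigendecomposition fallback
  for exactly semi-definite repaired matrices.
- Zero-variance nodes, singleton networks, empty between-scopes,
  zero-weight graphs, and $Z_w \le 0$ are errors, not NA propagation.
- All simulation entry points take explicit seeds and restore the caller's
  RNG state; identical seeds give bit-identical cohorts and pipeline
  outputs, and every written table carries a hash of the generating
  configuration in a header comment.

## Problem sizes used in validation

The shipped validation uses a 90-node, nine-network atlas; single-subject
oracle checks at 200-10,000 frames; study-scale cohorts of 150 subjects at
480 frames (with 100 replicates for the coverage check); 1000 analytic
replicates for power/type-I rates; and several hundred small replicate
cohorts (40 subjects, 60 frames) for the negative-control uniformity check.
These sizes were chosen so that each check's Monte-Carlo error is small
relative to the property being asserted while the whole suite stays
convenient to run routinely.

## Interface note

The package is organized as an analysis workflow: the numbered scripts
under `analysis/` are thin narrative drivers over the exported functions
(`simulate_cohort()`, `metrics_table()`, `fit_cognition()`, `associate()`,
`run_pipeline()`, ...), which are the API the tests and the acceptance
script exercise. No shell-level wrapper is provided; the functions and the
scripts are the interface.

## Known limitations

- The generator's block-Gaussian world has no spatial autocorrelation or
  global signal; absolute levels of participation coefficient and
  modularity are not comparable to empirical cohorts, only their
  across-subject ordering and associations are meaningful here.
- Principal-axis EFA with varimax assumes orthogonal domains; correlated-
  factor (oblique) structures are attenuated into the loadings.
- The negative control demonstrates specificity only against generators in
  which cognition is tied exclusively to association-system segregation; a
  global-connectivity effect would legitimately light up both systems.
- Partial correlation adjusts linearly; nonlinear confounding is out of
  scope.
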