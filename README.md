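# netseg

Functional brain-network segregation and brain-behavior association
analysis, with a fully synthetic validation cohort.

## The problem

In cognitive aging, the *dedifferentiation* hypothesis holds that the
brain's functional networks lose their distinctness with age, and that
this loss tracks cognitive decline. The standard way to quantify
distinctness from resting-state fMRI is network **segregation**: for a
network with mean within-network Fisher-z connectivity `Z_w` and mean
between-network connectivity `Z_b`,

```
S = (Z_w - Z_b) / Z_w
```

`S = 1` means the network is fully isolated; `S = 0` means within and
between connectivity are indistinguishable. System-level segregation
averages `S` over the networks of a system (e.g. the association system:
default mode, fronto-parietal, cingulo-opercular, dorsal/ventral
attention). Segregation is then related to cognition — factor scores
derived from a neuropsychological battery by exploratory factor analysis —
with partial correlations (collection site and cortical thickness as
covariates) under Benjamini-Hochberg FDR correction, with the
sensory-motor system as a negative control.

`netseg` implements that whole pipeline for anyone who has per-subject
node time series and an atlas: connectivity (Pearson -> Fisher z ->
positive masking), graph metrics (segregation, participation coefficient,
modularity, Louvain community detection), the cognition stage (parallel
analysis, principal-axis EFA with varimax rotation, regression-method
factor scores, overall-cognition composite), and the association
statistics (partial correlations, FDR, OLS supplement, a priori power).
Because real cohorts of this kind are not redistributable, the package
also ships a synthetic-cohort generator with planted network structure and
a planted brain-behavior correlation, so every stage can be validated
against known ground truth.

## Worked example

Simulate a study-scale cohort (150 subjects, 90 nodes, 480 frames) with a
planted correlation of 0.25 between association-system segregation and
latent cognition, and run the full pipeline:

```r
library(netseg)

spec <- cohort_spec(n_subjects = 150, n_frames = 480,
                    brain_behavior_r = 0.25, seed = 11)
res  <- run_pipeline(run_config(cohort = simulate_cohort(spec)))

res$associations[, c("predictor", "r", "p", "q", "significant")]
#>                   predictor          r           p          q significant
#> 1        system_segregation  0.2224157 0.006970669 0.01239704        TRUE
#> 2              modularity_Q  0.1756112 0.033990504 0.04758671        TRUE
#> 3  mean_within_connectivity  0.1422556 0.086744209 0.08674421       FALSE
#> 4 participation_coefficient -0.1648453 0.046774417 0.05457015       FALSE
#> 5                   seg_DMN  0.2279151 0.005661847 0.01239704        TRUE
#> 6                   seg_FPN  0.2291939 0.005390895 0.01239704        TRUE
#> 7                   seg_CON  0.2219838 0.007084023 0.01239704        TRUE

res$control[, c("predictor", "r", "p")]
#>        predictor           r         p
#> 1 sm_segregation -0.01027168 0.9020678
```

Reading this: the planted effect of 0.25 is recovered as a partial
correlation of 0.22 between estimated segregation and the
overall-cognition composite (attenuated slightly by measurement noise at
480 frames and by factor-score estimation), significant after FDR; the
sensory-motor control — whose connectivity is generated independently of
cognition — is flat, as it should be. The a priori power computation

```r
min_detectable_r(n = 146, alpha = 0.05, power = 0.80)
#> [1] 0.2300861
```

says a sample of 146 can detect correlations of about 0.23 at 80% power,
which the Monte-Carlo check in `analysis/05_power.R` confirms by
simulation.

The numbered scripts under `analysis/` walk the same pipeline stage by
stage (simulate, metrics, cognition, associations, power) and write their
tables under `results/`.

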