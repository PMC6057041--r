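# icmcda

Multi-criteria decision analysis (MCDA) for evaluating integrated-care
programmes against usual care.

Integrated care for people with multi-morbidity is meant to improve outcomes
across the Triple Aim — health and well-being, experience of care, and costs —
so a single-outcome evaluation (a QALY, a readmission rate) misses most of
what such programmes try to achieve. `icmcda` implements a multi-attribute
value model for this setting: performance of two alternatives on a set of
outcome criteria is standardized, weighted by stakeholder-elicited importance
weights, and aggregated into an overall value score per alternative, with
deterministic and probabilistic sensitivity analysis on top.

## The model

For criterion *j* with raw performance *x*<sub>aj</sub> (integrated care) and
*x*<sub>bj</sub> (comparator), standardized performance is the pairwise vector
normalization

  S<sub>aj</sub> = x<sub>aj</sub> / (x<sub>aj</sub>² + x<sub>bj</sub>²)<sup>1/2</sup>

complemented as 1 − x/‖·‖ for cost-direction criteria so that higher is always
better. The overall value of alternative *i* is the weighted sum
V<sub>i</sub> = Σ<sub>j</sub> w<sub>j</sub> S<sub>ij</sub> with nonnegative
weights summing to 1, so V ∈ [0, 1].

Weights come from two elicitation engines:

* **DCE** — a D-efficient paired discrete choice experiment over the 8 core
  criteria (3 levels each: poor / average / good; 10 sub-designs × 18 choice
  sets; exactly 4 or 5 attributes overlapped per set). Part-worths are
  estimated by conditional-logit maximum likelihood (damped Newton with
  step-halving); with dummy coding against the poor reference, weights are
  the normalized good-level coefficients.
* **SMARTER swing weighting** — respondents rank criteria by which they would
  swing from worst to best first; ranks map to weights by the rank-ordered
  centroid rule w<sub>k</sub> = (1/K) Σ<sub>i=k..K</sub> 1/i.

Uncertainty in performance (truncated-normal around each mean/SE) and in
weights (multivariate-normal part-worths, or bootstrap of swing rankings) is
propagated by Monte-Carlo simulation; the result is summarised as a
**Conditional Multi-attribute Acceptability Curve (CMAC)**: for each budget
threshold B, the probability that the intervention has the highest overall
value *and* its budget impact (population size × mean cost) stays within B.

## Worked example

The package ships the hypothetical two-programme comparison used throughout
its documentation (`inst/extdata/`): eight core criteria, performance means
for both programmes, and weight vectors of two stakeholder groups (P1, P2).

```r
library(icmcda)
set  <- build_core_set()
perf <- read_performance_table(
  system.file("extdata", "example_performance.csv", package = "icmcda"), set)
std  <- standardize_table(perf)
round(cbind(std$intervention, std$comparator), 2)
#>      [,1] [,2]
#> [1,] 0.65 0.76    # physical functioning (60 vs 70, benefit)
#> [2,] 0.81 0.58    # psychological well-being
#> [3,] 0.60 0.80    # social participation & relationships
#> [4,] 0.45 0.89    # resilience
#> [5,] 0.80 0.60    # enjoyment of life
#> [6,] 0.80 0.60    # person-centeredness
#> [7,] 0.86 0.51    # continuity of care
#> [8,] 0.20 0.40    # total costs (8000 vs 6000, cost direction)

overall_value(std, example_weights("P1"))$values
#> intervention   comparator
#>        0.722        0.632
overall_value(std, example_weights("P2"))$values
#> intervention   comparator
#>        0.592        0.643
```

Group P1 (which puts weight 0.30 on enjoyment of life) prefers the integrated
programme, 0.722 vs 0.632; group P2 (which weights physical functioning 0.25
and costs 0.20) prefers the comparator, 0.643 vs 0.592 — the same inputs,
honestly aggregated, support opposite decisions depending on whose
preferences are applied. That disagreement is precisely what the sensitivity
machinery (`exclude_criterion_sa()`, `weight_method_swap_sa()`, `run_psa()`,
`cmac()`) is for.

A full pipeline run (scoring → both weight sets → deterministic SA → PSA →
CMAC) is driven by a YAML config:

```r
cfg <- read_run_config(system.file("extdata", "example_config.yaml",
                                   package = "icmcda"))
run_pipeline(cfg)
```

A thin command-line wrapper with `score`, `weights-swing`, `weights-dce`,
`design-dce`, `sa`, `psa`, `cmac`, `simulate` and `run` subcommands lives at
`system.file("cli", "icmcda.R", package = "icmcda")`.

## Package layout

* `R/criteria.R` — criteria catalog: core set and programme-type supplements
* `R/value.R` — standardization, weighted-sum value scores, IO
* `R/swing.R` — SMARTER/ROC swing weighting and pooling
* `R/dce.R` — design optimization, conditional logit, DCE weights
* `R/uncertainty.R` — deterministic SA, PSA, CMAC
* `R/synthetic.R` — ground-truth simulators for trials, DCE and swing data
* `R/pipeline.R` — run configuration and the end-to-end pipeline
* `vignettes/icmcda-methods.Rmd` — the methods vignette
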