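---
title: "Methods: multi-attribute value MCDA for integrated care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-attribute value MCDA for integrated care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icmcda)
```

## The decision problem

Integrated-care programmes for people with multi-morbidity pursue several
goals at once — better health and well-being, a better experience of care,
and lower cost growth. `icmcda` evaluates such a programme against a
comparator (usually usual care) with a multi-attribute value model: each
alternative's performance on a set of outcome criteria is standardized,
multiplied by importance weights elicited from stakeholders, and summed into
one overall value score per alternative. Five stakeholder groups (the "5Ps":
patients, partners/informal caregivers, professionals, payers, policy makers)
may each hold their own weights, and the model makes explicit how their
priorities change the answer.

## Criteria

The core set holds eight outcomes measured in every evaluation: five health &
well-being criteria (physical functioning, psychological well-being, social
participation & relationships, resilience, enjoyment of life), two
experience criteria (person-centeredness, continuity of care), and total
health and social care costs. Only costs run in the cost direction. Four
programme-type supplements (population health management, frail elderly,
palliative & oncology, problems in multiple life domains) extend the core
set with concepts such as autonomy, preferred place of death or justice
contacts.

Scale ranges are explicit on every criterion because standardization and
truncated sampling need them. The core ranges follow the worked example
(0–100, 0–100, 0–4, 1–5, 0–4, 1–4, 1–5; cost bounds default to 8500–5500
currency units and are configurable per country). The programme-type
supplements are published as concepts without numeric scales, so the shipped
catalog declares a 0–100 default for each; these are deliberate placeholders
that users should override (via `read_criteria()`/`write_criteria()`) when
instruments are chosen. Outcomes whose semantics are unambiguously negative
(mortality, re-admissions, falls, caregiver burden, justice contacts, burden
of medication) are declared cost-direction even though their scales are
placeholders.

## Standardization and aggregation

For criterion $j$, raw scores $x_{aj}$ (intervention) and $x_{bj}$
(comparator) are standardized by pairwise vector normalization
$S_{aj} = x_{aj}/\sqrt{x_{aj}^2 + x_{bj}^2}$. For cost-direction criteria the
complement $1 - x/\sqrt{x_a^2+x_b^2}$ is used: this is what reproduces the
worked example's costs row (8000, 6000 → 0.20, 0.40), and it keeps "higher
standardized score = better" uniform across criteria. Two consequences worth
knowing:

* the identity $S_a^2 + S_b^2 = 1$ (complemented for costs) holds exactly,
  and is asserted to 1e-12 in the tests;
* standardized scores depend on *both* alternatives — the formula is defined
  for exactly two alternatives, and the package rejects anything else rather
  than guess a generalization.

Aggregation is the weighted sum $V_i = \sum_j w_j S_{ij}$ computed from
**unrounded** standardized values; the printed 2-decimal standardized scores
are display-only. This matters: the example's 0.722 is only reproducible
unrounded (rounded inputs give 0.721). Reported rounding follows the example:
2 dp for standardized scores, 3 dp for contributions and overall values.
Preference ties are declared below a 1e-12 tolerance — a convention, since
exact ties essentially never occur with continuous inputs.

The pairwise formula requires nonnegative raw scores that are not both zero;
violations raise errors rather than returning NaN.

## Swing weighting (SMARTER)

A respondent imagines a programme at the worst level on every criterion and
names the criterion they would swing to its best level first, then second,
and so on — a complete, tie-free ranking (the protocol removes one criterion
at a time, which precludes ties, so tied input rankings are rejected). Ranks
become weights by the rank-ordered centroid rule
$w_k = \frac{1}{K}\sum_{i=k}^{K} 1/i$, the centroid of the simplex region
consistent with the ranking; ROC is the default, with rank-sum and
rank-reciprocal behind a flag since the elicitation literature treats the
rule as exchangeable. Respondent vectors are pooled by per-criterion
arithmetic mean renormalized to 1 (the SMARTER convention; median available),
first within and then across stakeholder groups.

Swing weighting covers core plus programme-type criteria in one ranking (up
to 18 criteria); the DCE covers only the 8 core criteria. The two weight
sets are kept separate — provenance (`method`, `group`) travels with every
weight vector and weight file precisely so the two are never silently mixed.

## Discrete choice experiment

Each choice task shows two programme profiles described by their level on
every core criterion (poor / average / good; cost levels are the country
mean ±20%, higher cost being the worse level, and cost is treated as a
categorical 3-level attribute like the others). The respondent picks the
preferred programme; choices follow a conditional logit,
$P(A) = \text{logistic}(V_A - V_B)$ with $V$ the sum of level coefficients.

**Coding.** Dummy coding with the poor level as reference, so each
attribute's "good" coefficient is directly the utility of its worst→best
swing. Relative criterion weights are the normalized good-level coefficients.
Under this coding "best-level coefficient" and "best-minus-worst range"
coincide, which is why it was chosen over effects coding. A fitted good
coefficient below zero contradicts the monotone framing of the elicitation,
so `partworths_to_weights()` refuses it with instructions rather than
clipping silently.

**Design.** 10 sub-designs × 18 paired choice sets, blocked into 3 blocks of
6; each simulated respondent is assigned one sub-design uniformly at random
and answers all 18 sets. Every set has exactly 4 or 5 of the 8 attributes at
identical levels in both alternatives ("level overlap", drawn with equal
probability at initialization — the published counts fix the values but not
the mix), which lowers cognitive burden; overlapped attributes contribute no
information within a set but remain estimable across the design. Designs are
optimized for local D-error, $\det(I(\beta_0))^{-1/p}$ with
$I = \sum_{\text{sets}} p(1-p)\,\Delta x \Delta x^\top$, by greedy coordinate
exchange over single-attribute level assignments that preserves the overlap
pattern as a hard constraint; the search is deterministic given its seed, and
accepts only strict improvements, so the final D-error never exceeds the
initial one. The point-prior (local) D-error is used — no prior
*distribution* is available to justify a Bayesian D-error — and the default
prior is a small positive monotone vector (good 0.5, average 0.25 per
attribute) standing in for literature priors, configurable. Adaptive
updating refits the part-worths once a stakeholder group reaches ~50
respondents and re-optimizes the design under the refit prior.

**Estimation.** Hand-written damped Newton–Raphson with step-halving on the
exact log-likelihood; convergence at gradient max-norm < 1e-8; covariance =
inverse observed information at the optimum. Step-halving guarantees the
log-likelihood is non-decreasing across accepted steps. Non-identifiable
coefficients (a level that never varies in the data) and separation
(coefficients diverging past |β| = 30) are reported as errors naming the
attribute. An independent `glm` fit on the utility differences is used in
the test suite as a cross-check oracle, and a brute-force grid-search MLE
verifies a tiny two-coefficient instance to 1e-3. Respondent-level taste
heterogeneity is deliberately not modelled (plain conditional logit, not
mixed logit): group-level weights are the target.

A note on design size: a paired design identifies at most as many coefficient
directions as it has distinct choice sets, so at least 16 distinct sets are
needed for the 16 coefficients; the unit tests use 2×9 designs for speed and
the full 10×18 design for the recovery studies.

## Uncertainty analysis

Deterministic analyses: excluding a criterion (weights renormalized
proportionally) and swapping the weight source (e.g. DCE vs swing vectors,
or one stakeholder group vs another) with an agreement flag on the preferred
alternative.

The PSA samples, per draw, every performance mean from
$\mathcal{N}(\hat\mu, \text{SE})$ truncated to the criterion's scale range
(rejection sampling with an inverse-CDF fallback for heavy truncation), and
the weights from their uncertainty model: multivariate normal on the
part-worths using the estimated covariance, weights recomputed per draw
(sampled negative good-coefficients are truncated at zero before
renormalizing — the estimation contract forbids them, but MVN tails do not);
or a bootstrap over swing respondents; or fixed weights. Each draw is
standardized and aggregated exactly like the base case, so a PSA with all
SEs zero and zero coefficient covariance reproduces the deterministic values
bit-for-bit — a property the tests assert. Draws are deterministic given the
seed.

The CMAC reports, per budget threshold $B$, the fraction of draws in which
the intervention has the strictly higher overall value **and**
$\text{population\_size} \times \text{cost}_{\text{int}} \le B$. Budget
impact defaults to the intervention's drawn mean total cost times the
population size — the simplest faithful reading — with incremental cost
(intervention minus comparator) behind a flag. The cost criterion stays
inside the value score while also driving the threshold condition, mirroring
the worked example which keeps costs among the weighted criteria; a
`include_costs_in_value = FALSE` flag exists for users worried about double
counting. The curve is non-decreasing, bounded by the unconditional
preference probability, and equals a brute-force recount of the draws (an
invariant tested exhaustively). Monte-Carlo standard error of any curve
point is at most $\sqrt{0.25/n_{\text{draws}}}$.

## Synthetic data

No raw study data ship with the package, so a generator module produces all
three inputs with known ground truth: trial performance tables (true means
plus truncated-normal noise at the stated SEs), DCE respondents (uniform
sub-design assignment, Bernoulli choices under true part-worths), and swing
rankings (true weights plus additive normal noise, ranked descending — a
Thurstonian model; a Plackett–Luce sampler would be the main alternative).
All generators are pure functions of (truth, seed) and restore the caller's
RNG state.

`table_truth()` ships the worked example as the deterministic fixture
(SE = 0 reproduces its inputs exactly); `weights_to_partworths()` builds
part-worth truths whose derived weights equal a given weight vector, tying
recovery tests directly to the example.

What the simulations do **not** emulate: real respondents' inconsistency and
learning effects, interviewer effects, attrition and confounding in the
performance estimates (the performance table is an *input* here — its
estimation from patient-level data is a separate, out-of-scope step), and
preference heterogeneity within stakeholder groups. Passing recovery tests
therefore shows the machinery is consistent, not that real elicitations are
unbiased.

## Problem sizes and numerical choices

The shipped studies use sizes a desk evaluation would: recovery at 600 and
2400 simulated respondents on the full 10×18 design (coefficient MAE < 0.05
at 600, shrinking at 2400; derived weights within 0.02 of truth), PSA curves
at 2,000–10,000 draws. Tolerances: 1e-12 for algebraic identities, 1e-8
gradient norm for the MLE, 1e-9 for weight-sum validation. Ties in simulated
rankings have probability zero under continuous noise; `order()`'s stable
tie-break is documented behaviour for the degenerate noiseless case with
tied true weights, where the elicited order is genuinely ambiguous.

## Known limitations

* The pairwise standardization does not generalize to three or more
  alternatives, and the package refuses rather than guesses.
* Catalog scales for programme-type-specific outcomes are placeholders.
* Local (point-prior) D-efficiency only; no Bayesian D-error.
* Conditional logit assumes i.i.d. Gumbel errors and no taste heterogeneity;
  weights are group-level constructs.
* The budget-impact definition (population × intervention mean cost, no time
  horizon discounting) is deliberately minimal; population size is a
  required input, not an estimate.
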