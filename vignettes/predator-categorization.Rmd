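---
title: "Predator categorization in virtual prey communities: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predator categorization in virtual prey communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preycat)
```

## The experiment being simulated

A predator forages on a community of 36 prey, half profitable ("good") and
half unprofitable ("bad"). Every prey displays two discrete traits, one on
the shape dimension and one on the color dimension. One dimension is the
*reliable trait* R: each of its values is perfectly associated with
profitability (P(good | Rᵢ⁺) = 1). The other is the binary *unreliable key
trait* U, congruent with profitability for 28 of 36 prey, so
P(good | U⁺) = 28/36 ≈ 0.78. Five communities vary the reliable trait's
richness (2, 4, 8, 4, 8 values) and evenness (experiments 4 and 5 make one
good and one bad value dominant). A predator can therefore either learn
many reliable values, or categorize broadly by the key trait and accept a
0.22 error rate.

Foraging proceeds in trials. A single pretraining trial (all prey bad, low
life bar, sampling compelled) teaches the cost structure. Each experiment
then pairs a training trial — sequential encounters with a random
permutation of the community, attack-or-skip decisions, immediate feedback,
a life bar that loses 2 units per bad prey and gains 1 per good prey,
death at 0, and an 18-attack cap — with a feedback-free test trial on a
community that is identical for all experiments (four reliable values, two
good and two bad, crossed with both key-trait values). The test trial
measures the categories formed in training without changing them.

### The grid-to-sequence abstraction

The original task showed subjects a full grid they could scan freely. Here
prey are presented one at a time in a random permutation and skipped prey
are not revisited. This is the one substantial abstraction in the game
module: it removes spatial/strategic scanning but preserves the quantities
the analysis consumes (which phenotypes were attacked, how many, in what
order). Trial termination (attack cap, death, early stop) is unchanged.

## Agent archetypes

The original predators were humans; no learning model is implied by the
source experiment. Each archetype below is an explicit *model of one
hypothesis* about categorization, not a claim about human mechanism.

* **rw_learner** — Rescorla–Wagner compound-cue learning. Both displayed
  values share a prediction ΣV; after feedback each displayed cue moves by
  ΔVᵢ = α(λ_outcome − ΣV). Cue competition through the shared error makes
  the more valid cue capture the association (relative validity), so this
  archetype models "predators always use the reliable trait". Defaults:
  λ = +1/−2 mirroring the payoff ratio; α = 0.4, chosen once to represent
  fast, human-like learning within an 18-attack trial (at small α the
  learner is still naive when training ends; at α near 1 single outcomes
  dominate).
* **key_trait** — keeps mean-payoff tallies per key-trait value and, once
  the tallies favor one side, deterministically attacks U⁺-like prey and
  rejects the rest. Models pure broad categorization.
* **memorizer** — a rote table of per-phenotype tallies with capacity
  `capacity` and least-recently-reinforced eviction; unknown phenotypes
  fall back on an optimistic (+0.5), pessimistic (−0.5), or key-trait
  valuation.
* **human_like** — the memorizer with key-trait fallback; the default
  study subject. Capacity defaults to 6, a working-memory-scale value
  sitting between the 4 phenotypes of experiment 1 (memory suffices:
  reliable-trait behavior) and the 16 of experiments 3/5 (memory is
  swamped: fallback behavior). In uneven communities the abundant
  phenotypes monopolize both encounters and memory slots, which restores
  reliable-trait use — the same mechanism produces the focus on the most
  abundant good value that the split-value likelihood-ratio test detects.
* **random** — attacks with probability 0.5; the no-categorization null.

### The choice rule and its temperature

Valuation-based agents attack with probability `plogis(value /
temperature)`, with values in payoff units (+1 known-good, −2 known-bad).
The default temperature is 1. A much colder rule (e.g. 0.25) makes agents
near-deterministic; simulated studies then exhibit complete separation in
the logistic model (trait coefficients diverging, SEs in the hundreds),
which destroys the delta-method contrasts the entire analysis rests on —
and no real subject pool behaves that way. At temperature 1 the spread
between known-good and known-bad valuations is 3 log-odds units,
consistent with the effect magnitudes reported for the original control
experiment (reliable-trait effect ≈ 3.4). `fit_model()` still detects and
flags separation (`separation = TRUE`) for agents, like the deterministic
key_trait archetype, that produce it.

## The statistical model

Only test trials are analysed. For each experiment the *focal* prey are
the four most abundant phenotypes of its training community; the analysis
keeps every test row whose reliable value belongs to a focal phenotype.
(Keeping only the four phenotypes themselves would confound the two
traits: among focal phenotypes the key-trait value is perfectly aligned
with profitability. The reliable-value reading restores independent
variation of R and U in the retained rows.) Test values never seen in an
experiment's training (two of the four, for experiment 1) are eliminated.
Reliable values are recoded by their training association into binary G/B;
R, U (coded 0/1) and the experiment presentation rank are centered.

The model, fit by maximum likelihood with a logit link on Bernoulli rows:

```
attacked ~ 0 + experiment + subject
           + experiment:U_c + experiment:R_c
           + experiment:U_c:order_c + experiment:R_c:order_c
```

There is deliberately no intercept and no trait main effect — a violation
of marginality that makes each `experiment:R_c` coefficient directly the
reliable-trait effect in that experiment, estimated at the mean of the
centered covariates. Subject is a fixed effect (the random-effect variant
did not converge on the original data and is out of scope). Aggregated
(attacked, not-attacked) binomial fitting would give identical
coefficients, covariance, and likelihood *differences*; only the constant
in the likelihood differs, so the LRT is unaffected.

Per experiment the pipeline reports, with delta-method standard errors
(exact for linear functions: se = √(cᵀΣc)) and Wald intervals:

* the **difference** β_R − β_U — relative use of the reliable trait;
  exp(difference) is the relative odds of attack due to R versus U;
* the **sum** β_R + β_U — total discrimination.

Pairwise comparisons between experiments (differences of differences, 10
pairs) use Bonferroni-adjusted intervals (α/10); experiments share a
letter in the compact letter display (insert-and-absorb construction,
columns ordered by estimate) exactly when their adjusted interval covers
zero.

The **split-vs-lumped LRT** refits the model with the original focal
reliable values (up to two good and two bad per experiment) in place of
the binary G/B coding and compares likelihoods. Degrees of freedom are
counted structurally (difference in estimable parameters) rather than
hard-coded: with randomized experiment orders some value-by-order cells
can be aliased, so the count is data-dependent and is verified in the test
suite against the column-rank difference of the two design matrices.

## Numerical choices and degenerate inputs

* Centering: 0/1 coding minus the grand column mean over retained rows.
* Intervals: Wald (normal) throughout, consistent with delta-method SEs.
* Separation: flagged when any trait coefficient exceeds 15 log-odds; no
  penalization is applied by default.
* Single-experiment tables degrade gracefully: the experiment factor
  leaves the design (subject dummies absorb it) and order interactions
  alias out when order is constant; aliased (NA) coefficients are dropped
  from the coefficient vector and parameter counts.
* Communities at sizes other than 36 must keep the 0.78 congruence
  realizable within one prey and the abundance vectors integral, else
  construction fails with an explanation.
* Congruent prey are apportioned to reliable values proportionally to
  abundance, remainders to the most abundant first, skipping a value when
  that would empty its incongruent cell — this keeps experiments 3 and 5
  on identical phenotype *sets* (they differ only in abundances).
* Focal-phenotype ties in even communities prefer the congruent pairing,
  then the lowest value index.

## What the generator does and does not establish

The synthetic subjects are the stated world of this package: 45 subjects,
each running all five experiments in random order under balanced random
treatments, with per-subject counter-based seed streams (adding subjects
never perturbs earlier ones). A green test establishes that the pipeline
recovers the qualitative signatures its agent archetypes were built to
express — decline of reliable-trait use with richness for the
capacity-limited composite, its recovery with unevenness, uniformly
positive relative use for the Rescorla–Wagner learner, null effects for
the random agent — and that the estimator is calibrated (CI coverage,
grid-oracle agreement, reparameterization checks). It does **not**
establish anything about human predators: the original behavioral effect
sizes are properties of human subjects and are not reproducible from
scratch. Real data can be ingested through `read_records()` with a column
mapping and pushed through the identical analysis.

Other known limitations: no spatial grid effects, no timing or sound
penalties, no evolving prey, no fitting of learning-model parameters to
behavioral data, and no mixed-effects or Bayesian refits.
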