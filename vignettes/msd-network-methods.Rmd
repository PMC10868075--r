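---
title: "Methods: a discrete Bayesian network for psychosocial risk and musculoskeletal symptoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a discrete Bayesian network for psychosocial risk and musculoskeletal symptoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msdbayes)
```

## The model

`msdbayes` analyses occupational survey cohorts with a seven-node discrete
Bayesian network over binary (`low`/`high`) constructs: post-traumatic
stress (PTSD), job stress, the three burnout dimensions (emotional
exhaustion, depersonalization, personal accomplishment), depression, and
musculoskeletal symptom status (MSD). The structure is expert-drawn, not
learned: PTSD is the sole root and points at job stress and all four
mediators; job stress points at the four mediators; the mediators are the
parents of MSD (13 arcs). `firefighter_dag()` returns it.

The joint distribution factorizes into one conditional probability table
(CPT) per node given its parents. With seven binary nodes the joint has
only $2^7 = 128$ states, so *all* inference in the package is exact. The
key modelling assumptions are therefore: (i) binary states suffice (every
construct is dichotomized); (ii) the fixed DAG is an adequate description
of the dependence structure; (iii) respondents are independent draws from
one cohort distribution. None of the arcs is given a causal reading — the
network encodes conditional dependence, and "influence" below is a
probabilistic, not causal, quantity.

## Instruments and scoring

`standard_instruments()` defines the five-questionnaire battery:

| instrument | items | item range | subscales | total range |
|---|---|---|---|---|
| HSE-MS IT (`hse`) | 35 | 1–5 | 8/6/5/4/4/5/3 | 35–175 |
| PTSD Checklist (`pcl`) | 17 | 0–1 | 5/2/5/5 | 0–17 |
| MBI (`mbi`) | 22 | 0–6 | 9/5/8 | per dimension |
| CES-D (`cesd`) | 20 | 0–3 | — | 0–60 |
| NMQ (`nmq`) | 9 | 0–1 | — | 0–9 regions |

Reverse-scored items are mapped $r \mapsto r_{\min} + r_{\max} - r$ before
summation. Which HSE items are reversed varies between language adaptations
and is not fixed by the package; it is a configuration argument
(`hse_reverse_items`, default none). A total is missing whenever any of its
items is missing — no pro-rating, because imputation is handled at the
analysis level (EM over binary profiles), not the item level.

## Dichotomization

Each construct except MSD is split at the *cohort median* of its raw total
(`median_split()`; even cohort sizes use the mean of the middle pair). Two
constructs are **inverted**: high job stress corresponds to a raw HSE total
*below* the median (high HSE scores mean low stress), and reduced personal
accomplishment likewise (low accomplishment scores indicate burnout). The
three burnout dimensions are split independently, each at its own median.
Ties at the median go to `low` in both orientations — a single conservative
rule applied uniformly, chosen so that borderline respondents never enter
the exposed class. MSD uses the any-region rule: zero affected body regions
is `low`, one or more is `high`.

A genuine median split allocates roughly half the cohort to each level by
construction. Published level frequencies for such designs can nevertheless
be far from 50/50 (e.g. 70/30) when the split point was carried over from a
different sample or instrument convention; since such medians are usually
unpublished, `dichotomize_constructs()` also accepts explicit fixed
`thresholds`, and the synthetic generator records the thresholds it used
(`generating_thresholds()`) so that analyses can be run on either
convention.

## Parameter learning

`fit_mle()` estimates each CPT entry as
$(\mathrm{count} + a)/(\mathrm{total} + 2a)$ with pseudo-count $a \ge 0$.
The default is $a = 0$ (pure maximum likelihood): survey-scale fits can
legitimately contain the extreme entries 0 and 1, which any positive prior
would smooth away. Parent configurations never observed get a uniform row
with a warning.

`fit_em()` handles missing cells by expectation–maximization at the profile
level. The E-step distributes every partially observed row over its
completions in proportion to the current joint probability; rows are
grouped by their observation pattern (at most $3^7 = 2187$ patterns), and
expected counts are accumulated over the 128-state joint table, which makes
each iteration cheap at any cohort size. The M-step renormalizes expected
counts into CPTs. Iteration stops when the observed-data log-likelihood
improves by less than `tol` (default `1e-6`) or at `max_iter` (default
500, with a warning and `converged = FALSE`). Initialization is uniform
CPTs by default — on complete data the first M-step then lands exactly on
the MLE — with seeded random restarts available (`init = "random"`). The
log-likelihood trace is returned and is non-decreasing up to numerical
tolerance `1e-8`, the standard EM ascent guarantee; the test suite asserts
it across randomized cohorts.

## Exact inference

`posterior()` computes $P(X = \mathrm{high} \mid \mathrm{evidence})$ by
either full enumeration of the joint table (default) or variable
elimination. Both are exact; they are implemented independently and the
suite requires agreement to $10^{-10}$ over randomized parameterizations —
a two-route design that protects against indexing bugs, the classic failure
mode of CPT code. Evidence with probability zero raises an error rather
than returning `NaN`. State order is fixed as (`low`, `high`) everywhere,
and parent configurations are indexed with the first parent varying
fastest; `bn_to_json()` serializes networks (17 significant digits, which
round-trips doubles bit-exactly) with the state order recorded explicitly.

## Sensitivity and influence

`evidence_delta_profile()` implements evidence propagation: fix one or more
nodes at an observed state ("with probability 100%") and report, per
remaining node, `conditioned - baseline` in probability points. Reports
print these as percentages (a `+0.34` shift reads "+34%").

`arc_influence()` implements a delta-p measure of arc strength. For arc
$U \to V$ with co-parents $C$:
$\delta(c) = |P(V{=}\mathrm{high} \mid U{=}\mathrm{high}, C{=}c) -
P(V{=}\mathrm{high} \mid U{=}\mathrm{low}, C{=}c)|$, read from $V$'s CPT.
`maximum` is $\max_c \delta(c)$; `average` is $\sum_c w(c)\,\delta(c)$ with
$w(c)$ the *joint marginal* probability of $C = c$ under the network
(renormalized). Two deliberate choices here were genuinely open. First, the
distance is the absolute difference in $P(V = \mathrm{high})$; for binary
nodes most candidate distances (total variation, per-state differences)
coincide up to this choice. Second, the averaging weights are the network's
own co-parent marginals rather than uniform: configurations that barely
occur should barely contribute, and uniform weighting cannot reproduce the
characteristic pattern of a modest average alongside a large maximum driven
by a rare near-deterministic row. For single-parent arcs there is one
configuration and average = maximum — a structural identity the suite
asserts. `rank_arcs()` sorts descending by average, ties broken by
(parent, child) lexicographic order so rankings are reproducible.

Because MSD's parents are the four mediators, a table of
$P(\mathrm{MSD} \mid \mathrm{PTSD}, \mathrm{JobStress})$ is *not* a CPT of
this network: it is a posterior with the mediators marginalized.
`msd_given_stress_table()` computes exactly that, keeping the two objects
distinct.

## Cross-validated prediction

`cross_validate_msd()` evaluates how well the six non-MSD constructs
predict symptom status: rows are shuffled once with a seeded permutation
and cut into $k$ contiguous folds whose sizes differ by at most one (for
$n = 2339$, $k = 10$: nine folds of 234 and one of 233); each fold is
scored by a model EM-fitted on the other $k-1$ folds, each scorable row as
$P(\mathrm{MSD}{=}\mathrm{high} \mid \text{its observed covariates})$, with
missing covariates marginalized by exact inference. Rows with missing MSD
train but are never scored. Two fallbacks keep pure-MLE fits usable: a
training split that never observes some node state is refitted with
pseudo-count 0.5, and a held-out covariate pattern with probability zero
under a degenerate fit is rescored against a pseudo-count-0.5 refit (both
with warnings).

The positive class is `high` MSD; classification uses
score $\ge$ threshold (closed on the high side, stated for bit-exact
reproducibility) with default threshold 0.5. `roc_and_auc()` sweeps the
distinct scores (ties grouped, one step per distinct score) and integrates
by the trapezoid rule, which equals the Mann–Whitney concordance
probability with ties counted one-half; the suite verifies this equivalence
against exhaustive pair counting and against an independent ROC
implementation.

## The synthetic cohort generator

The raw survey behind the model is not publicly available, so
`simulate_cohort()` generates item-level cohorts with known ground truth.
It emulates, in order:

1. **Binary profiles** sampled from a generating network with the
   firefighter structure. Its CPTs are *fabricated but calibrated*: the
   published record gives marginal level frequencies and per-level raw-score
   means/SDs, but not the CPTs themselves. Each child's CPT is additive and
   monotone — base rate plus one non-negative effect per `high` parent —
   with per-arc effects set to the published average-influence values where
   the additive form permits (the four symptom arcs are scaled down so rows
   stay inside $[0,1]$), and base rates solved analytically so every node's
   marginal $P(\mathrm{high})$ equals its target *exactly* (for additive
   CPTs the marginal depends only on the parents' marginals). Defaults:
   PTSD 0.291, job stress 0.209, emotional exhaustion 0.291,
   depersonalization 0.250, personal accomplishment 0.358, depression
   0.248, MSD 0.493.
2. **Raw totals** drawn per construct from the level-conditional score
   model: a discrete normal on the correct side of a fixed generating
   threshold (the rounded midpoint of the two level means), with the
   location parameter solved so the *truncated* mean equals the published
   group mean (plain truncation would bias it). Truncation mildly shrinks
   the SDs; means are reproduced to well under one scale point. The PTSD
   group means are published on the 17–85 checklist metric while the
   instrument here scores 17 binary items, so they are mapped linearly onto
   0–17 ($x' = (x-17) \cdot 17/68$) — a synthetic adaptation, flagged as
   such.
3. **Item allocation**: each total is spread across its instrument's items
   by sequential constrained sampling within per-item bounds (vectorized
   across respondents). Symptom flags are all zero for `low` profiles and
   sum to the drawn region count otherwise. Demographics are sampled from
   the study cohort's category frequencies, independently of everything
   else.
4. **Missingness**: `inject_missingness()` blanks item cells independently
   with a fixed probability — missing completely at random (MCAR), the
   weakest assumption available given that the survey's missingness
   mechanism is uncharacterized. The truth table is never blanked.

At zero missingness, re-scoring the generated items and cutting at the
generating thresholds reproduces the truth table *exactly* — the round-trip
identity that anchors the whole pipeline's tests.

What the generator deliberately does **not** emulate: item-level
correlation structure within an instrument (totals, not items, matter
downstream), demographic confounding, informative (MNAR) missingness, and
any clustering by fire station. Passing tests therefore certify the
*machinery* — scoring, splitting, learning, inference, validation — on
data whose marginal and conditional structure matches the published
record; they do not certify conclusions about real cohorts.

## Numerical and testing choices

* Tolerances: EM `tol = 1e-6` on the log-likelihood (pipeline stages use
  `1e-4`, ample for 3-decimal reporting); CPT rows validated to sum to 1
  within `1e-9`; inference-route agreement `1e-10`.
* Sample-size arithmetic rounds *up* (ceiling) — the only rule consistent
  with both published design numbers (1642.47 → 1643, 2053.75 → 2054).
* All randomized functions take explicit seeds and restore the caller's
  RNG state, so pipelines are reproducible end to end.
* Parameter-recovery checks pin their tolerances to what the binomial error
  of the *rarest parent configuration* allows: a four-parent node splits
  the sample over 16 configurations, so recovery to 0.01 absolute at
  $n = 10^5$ is only statistically meaningful on networks whose
  configurations all carry ample mass. The acceptance suite therefore runs
  its strict recovery checks on balanced networks of in-degree ≤ 2
  (complete data, $n = 10^5$, < 0.01) and a chain (10% MCAR + EM,
  $n = 2 \times 10^4$, < 0.02), and checks the firefighter network at the
  tolerance its rare configurations support (< 0.06 at $n = 3 \times 10^4$).
* Test problem sizes were chosen to exercise the asymptotics while keeping
  the default suite around half a minute: cohorts of 120–2500 rows for
  behavioural tests, $10^5$ draws for recovery, 100–200 replicates for
  property checks.

## Limitations

Binary nodes only (dichotomization is the design, but it discards
within-level variation); the DAG is fixed, no structure learning; exact
enumeration is the right tool at 7 nodes but would not scale past ~20;
influence values are conditional-dependence summaries, not causal effects;
and the synthetic generator's CPTs are calibrated fabrications — analyses
of real cohorts should treat them only as a test harness, never as
substantive estimates.
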