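---
title: "Disease trajectory networks: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease trajectory networks: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

trajnet turns a longitudinal cohort with self-reported, year-resolution
chronic-disease onset ages — the structure of ageing surveys such as CHARLS
— into a directed *disease trajectory network*: which diseases tend to come
before which, how strong each directed association is, and which
three-disease chains the most participants actually follow.  This vignette
documents the statistical model behind each stage, the conventions the
package commits to where the methodology literature leaves choices open,
and what the synthetic-data generator does and does not establish.

## The pipeline at a glance

1. **Cleaning** (`read_cohort()`, `apply_exclusions()`,
   `resolve_recall()`): participants without any follow-up wave or with
   missing demographics are removed (in that order; a participant failing
   both rules is counted under the first).  Multi-wave disease reports are
   reduced to one event per person and disease, the most recent statement
   winning: a later wave may confirm, correct, or retract an earlier
   report.
2. **Descriptives** (`multimorbidity_distribution()`,
   `onset_age_summary()`, `km_cumulative_incidence()`): survey-weighted
   prevalences and age-scale Kaplan–Meier cumulative incidence.
3. **Direction** (`direction_test_all()`): for each unordered pair
   (D1, D2), participants with both diseases in distinct years split into
   N1 (D1 first) and N2 (D2 first).  Under no directional tendency
   N1 ~ Binomial(N1+N2, ½); a two-sided exact binomial test decides
   whether the majority ordering is a direction.
4. **Association** (`build_case_control()`, `clogit_fit()`,
   `bootstrap_ci()`): each directed pair D1 → D2 gets a nested
   case-control analysis with incidence-density sampling and conditional
   logistic regression; pairs with OR > 1 and a bootstrap CI excluding 1
   become network edges.
5. **Network** (`build_network()`, `chain_trajectories()`,
   `linear_trajectories()`, `rank_trajectories()`): edges sharing nodes
   chain into trajectories; three-disease chains are ranked by the number
   of participants who follow them in strict onset order.

`run_pipeline()` orchestrates all stages deterministically under one
master seed and writes every intermediate table with a header recording
the package version, seed and a configuration fingerprint.

## Temporal ordering and the exact binomial test

Onset ages are whole years (surveys record the calendar year or age of
first diagnosis), so "before" means *strictly* earlier by at least one
year.  Same-year onsets are genuinely unordered at this resolution; they
are counted separately (`n_sim`) and excluded from the test denominator,
rather than broken by an arbitrary tie rule.

The two-sided p-value is the sum of both extreme tails of the symmetric
binomial, equivalently `min(1, 2 * P(X >= max(N1, N2)))`.  The default
multiplicity correction divides the base level by the number of pairs
tested (family-wise Bonferroni, 91 pairs for the canonical 14 diseases).
Some trajectory studies instead divide by the pair's own participant
count N; that reading is available as `policy = "per_pair_n"`, and an
uncorrected `"fixed"` policy exists for calibration experiments.  The
direction is chosen post hoc as the majority side, which is why the test
is two-sided by default.

## The matched odds ratio

For a directed pair D1 → D2, cases are participants with *incident* D2
(onset strictly after their baseline age).  Each case is matched at its
D2 onset age (the *index age*) to up to `ratio` controls (default 1:3)
who:

* are of the same sex and within `age_caliper` years of the case's
  baseline age (default ±2; 0 gives exact-age matching),
* are still under observation at the index age and have no D2 onset at or
  before it (the incidence-density risk set; later cases may serve as
  earlier controls, and controls may be reused across sets),
* were free of both D1 and D2 at baseline.

Exposure, for every set member, is a D1 onset strictly before the index
age.  With one case per set and a binary exposure, the conditional
likelihood of a set with `m` members, `k` exposed and case exposure `x_c`
is `exp(beta * x_c) / (k * exp(beta) + m - k)`.  Sets are collapsed to
these `(m, k, x_c)` sufficient patterns and the likelihood is maximised
by Newton–Raphson with step halving; convergence requires the absolute
score below 1e-8.  Two degeneracies are detected rather than papered
over: designs with no exposure-discordant set are unidentifiable (an
error), and designs whose discordant sets all point one way — including
any design made of a single repeated pattern, whose score has constant
sign — are complete separations and are flagged instead of returning a
spurious finite OR.

Confidence intervals resample whole matched sets with replacement
(default 1000 replicates), refit each replicate, and take percentile
bounds; the replicate mean OR is reported alongside the original-fit OR,
which is the primary point estimate.  Replicates that fail to converge
are dropped and counted; more than 50% failures flags the interval
unreliable.

### Two conventions that matter

**"Free at baseline" is strict.**  At year resolution, an onset recorded
in the entry year postdates the baseline interview, so "never had D1/D2
at baseline" excludes onsets *strictly before* the baseline age.  The
inclusive alternative silently shortens every control's exposure window
by one year relative to the cases' and removes the most-exposed control
candidates; in simulation this inflates the estimated OR by roughly
40–50% relative to the true hazard ratio.  The strict convention keeps
exposure ascertainment symmetric between cases and controls.

**The age caliper trades bias for matchability.**  Baseline age matching
is not cosmetic: exposure probability grows with time under observation,
so age-at-entry is a strong confounder of "D1 before the index age".
With entry ages spread over decades, a ±2-year caliper leaves a residual
+10–20% inflation of the OR in simulation, while exact-age matching
(`age_caliper = 0`) recovers planted hazard ratios to within a few
percent at the cost of smaller eligible pools.  The default stays at ±2
(the conventional compromise for sparse strata); the package's own
parameter-recovery tests use exact-age matching so that they measure the
estimator, not the caliper.

## The trajectory network

Selected edges (OR > 1, CI excluding 1) form a directed graph whose nodes
carry patient counts and whose edges carry ORs.  Nodes with only
out-edges are *start* diseases, nodes with only in-edges are *end*
diseases, and total-degree rank identifies the network's *center*.
Trajectories are all simple directed paths up to a maximum length,
enumerated cycle-safely: although the binomial step makes 2-cycles
impossible, longer cycles are not formally excluded, so enumeration never
revisits a node and flags any truncated cycle instead of assuming a DAG.

For each 3-node path D1 → D2 → D3 the package reports `n_12`, the number
of cohort members with D1 strictly before D2 (counted in the whole
cohort, which is why trajectories sharing a stem share the count);
`median_t12`, the median D2−D1 gap among them; the median D1 onset age
among those same stem members (the alternative basis — among full-chain
members — is `age_basis = "full"`); `n_123`, the members with
D1 < D2 < D3 strictly; and `median_t23`.  Ranking is by `n_123`
descending, ties broken by `n_12` and then lexicographic path, which
makes the top-k table a deterministic total order.

## The synthetic cohort: what a green test establishes

`simulate_cohort()` is a yearly discrete-time multistate simulation on an
age time-scale: each year, each not-yet-onset disease fires with
probability `baseline(age) * prod(HR of predecessors already onset)`,
with a planted dependency taking effect the year *after* the
predecessor's onset so the planted direction is strict.  Discrete years
were chosen over continuous-time exponentials deliberately: they match
the year-resolution of recalled onsets and make same-year onsets — which
the direction test must handle — a real phenomenon rather than a
measure-zero event.

Defaults describe a CHARLS-like world: 15,000 participants entering at
ages 45–75, four survey waves (2011, 2013, 2015, 2018) with 7% per-wave
dropout converting to right censoring at the last attended wave,
covariate frequencies matching published weighted descriptives (52.07%
female, 47.06% urban, 14.33% high education, 30.43% smokers, 33.18%
drinkers), log-normal survey weights, and per-year baseline hazards
chosen once so that lifetime prevalence over a few decades reproduces the
published prevalence ordering (arthritis ≈ 0.014/yr at the top, cancer
≈ 0.0005/yr at the bottom).  The onset process starts at age 30 by
default, emulating recalled pre-baseline onsets; `start_age = "entry"`
starts it at study entry, which is the clean regime for estimator
validation because nobody is prevalent at baseline.

Features of real data the generator does **not** emulate: recall error
and differential misreporting (events are always "confirmed"), mortality
distinct from dropout, covariate-dependent hazards, secular calendar
trends, and household clustering of survey weights.  A green
parameter-recovery test therefore establishes that the pipeline measures
what the simulator plants — not that a real cohort is free of the recall
and selection problems the original surveys carry.

## Numerical and reporting conventions

* Quantiles use linear interpolation between order statistics (R type 7).
* Kaplan–Meier curves offer two risk-set conventions: `"prevalent"`
  (default; recalled pre-baseline onsets count as events at their
  reported age, everyone at risk from age 0) and `"left"` (entry at
  baseline age, prevalent cases excluded) — the literature this package
  follows is silent on the choice, so both are exposed.
* Multimorbidity is ≥2 diseases: the published category arithmetic
  (2, 3, ≥4 summing to the "multimorbidity prevalence") only works under
  that reading, despite occasional "more than two" phrasing in prose.
* Second-stage durations averaging to 5.05 report as 5.1 under
  round-half-up, the convention of mainstream statistical reporting
  software; base R's round-half-even would print 5.0.
* Per-pair seeds are derived from the master seed and the pair's *name*,
  so estimates do not depend on the order in which pairs are processed.
* Bootstrap replicates in the packaged tests are reduced (30–200) to keep
  runtimes in minutes; the default for analyses remains 1000.

## Known limitations

* The matched analysis adjusts by design only (sex and age); no
  multivariable adjustment, robust variances, or tie-handling machinery
  (one case per set makes Breslow/Efron corrections moot).
* The exact binomial direction test is conservative at small N; its
  attained size, not the nominal level, is the right calibration
  reference (the acceptance suite computes it from the binomial pmf).
* Survey weights are consumed as given; their construction is out of
  scope, as is ingestion of any proprietary survey release format.
* GraphML export targets generic viewers; no layout or styling is
  attempted.
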