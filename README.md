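# trajnet — disease trajectory networks from longitudinal multimorbidity cohorts

Middle-aged and older adults rarely develop chronic diseases in
isolation: arthritis tends to precede hypertension, hypertension precedes
dyslipidemia, and so on.  **trajnet** is an R package for epidemiologists
who want to extract that temporal structure from a longitudinal cohort
with self-reported, year-resolution disease onset ages (the data shape of
ageing surveys such as CHARLS) and summarise it as a *directed disease
trajectory network*.

## What it computes

Given participants (with covariates, survey weights and an observation
window) and one onset event per person and disease, the pipeline runs:

1. **Cleaning** — exclusion rules (no follow-up, missing demographics)
   with an auditable count log, and recall resolution of multi-wave
   disease reports (latest confirmed statement wins; retractions delete).
2. **Descriptives** — survey-weighted prevalences and multimorbidity
   distribution, onset-age medians/IQRs, and age-scale Kaplan–Meier
   cumulative incidence `1 − ∏_{t ≤ a} (1 − d_t / n_t)`.
3. **Direction** — for each pair (D1, D2), the participants with both
   diseases in distinct years split into N1 (D1 first) and N2 (D2
   first); under no directional tendency N1 ~ Binomial(N1+N2, ½), tested
   with a two-sided exact binomial test under a Bonferroni-style
   threshold (same-year onsets are excluded as simultaneous).
4. **Association** — each directed pair D1 → D2 gets a nested
   case-control analysis: incident-D2 cases are matched 1:3 on sex and
   baseline age to incidence-density controls at risk at the case's onset
   age; a from-scratch conditional-logistic fitter maximises
   `Σ_sets [β·x_case − log Σ_j exp(β·x_j)]`, and a set-resampling
   bootstrap yields percentile CIs.  Edges keep pairs with OR > 1 and CI
   excluding 1.
5. **Network & trajectories** — selected edges chain through shared nodes
   into a directed network (start / center / end roles) and ranked linear
   D1 → D2 → D3 trajectories with patient counts and median inter-onset
   gaps.

A discrete-time multistate **simulator** with planted directional hazard
ratios (`simulate_cohort()`) provides ground truth, so every stage has
parameter-recovery and type-I-error tests that run offline.

## Worked example

Simulate a cohort whose only true dependencies are
arthritis → hypertension → dyslipidemia (hazard ratio 4 each), then run
the whole pipeline:

```r
library(trajnet)

sim <- sim_config(
  n_participants = 12000, seed = 0,
  diseases = c("arthritis", "hypertension", "dyslipidemia"),
  baseline_hazards = c(arthritis = 0.02, hypertension = 0.015,
                       dyslipidemia = 0.01),
  dependency_hr = data.frame(
    d1 = c("arthritis", "hypertension"),
    d2 = c("hypertension", "dyslipidemia"), hr = c(4, 4)),
  start_age = "entry", entry_age_range = c(45, 65),
  dropout_per_wave = 0.05)

cfg <- pipeline_config(
  simulation = sim,
  match = match_config(bootstrap_reps = 200, age_caliper = 0),
  out_dir = "trajnet_demo", seed = 42)

report <- run_pipeline(cfg)
report$selected_edges[, c("source", "target", "n_sets", "or",
                          "ci_low", "ci_high")]
#>         source       target n_sets   or ci_low ci_high
#> 1    arthritis hypertension   1268 4.44   3.71    5.39
#> 2 hypertension dyslipidemia    820 4.31   3.37    5.77
report$trajectories
#>   rank        d1           d2           d3 median_onset_age_d1 n_12 median_t12
#> 1    1 arthritis hypertension dyslipidemia                  57  302          2
#>   n_123 median_t23
#> 1    25          2
```

Reading the output: of 3 testable pairs, exactly the two planted edges
survive the direction test and the CI rule, with matched odds ratios
(4.44 and 4.31) bracketing the planted hazard ratio 4; 302 participants
developed arthritis strictly before hypertension (median gap 2 years in
this short follow-up window), 25 of whom completed the full chain.  Every
stage's table lands in `trajnet_demo/` with a header recording the
package version, master seed and configuration fingerprint; two runs with
the same seed are byte-identical.

A shell front end with `run-all` / `simulate` / `validate` subcommands is
installed at `inst/cli/trajnet`:

```sh
Rscript inst/cli/trajnet run-all --config config.json --seed 42 --out demo/
```

## Package layout

- `R/cohort.R` — data model, IO, exclusions, recall resolution
- `R/simulate.R` — discrete-time multistate cohort simulator
- `R/descriptives.R` — weighted descriptives, Kaplan–Meier curves
- `R/direction.R` — pair enumeration and exact binomial direction test
- `R/matched_or.R` — incidence-density matching, conditional logistic
  likelihood, bootstrap CIs
- `R/network.R` — network assembly, path chaining, linear trajectories,
  exports (edge list, GraphML)
- `R/pipeline.R` — configuration, validation, orchestration, CLI
- `vignettes/disease-trajectory-networks.Rmd` — models, conventions,
  simulator scope and limitations
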