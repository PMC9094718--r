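---
title: "Projecting joint dementia and frailty burden by microsimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting joint dementia and frailty burden by microsimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demfrailsim)
library(data.table)
```

## The model

`demfrailsim` projects the joint burden of dementia and physical frailty in
a population aged 60 years and older by dynamic microsimulation. Each
simulated person carries a state vector — age, sex, educational attainment
(less than high school / high school / college or higher), eleven chronic
condition flags (diabetes, coronary heart disease, stroke, hypertension,
hyperlipidaemia, cancer, respiratory disease, joint conditions, eye
problems, chronic kidney disease, other diagnoses), ADL and IADL limitation
counts, depression, self-reported health, and vital status — evolved in
half-year cycles as a first-order Markov process:

1. **Mortality** — a half-year death probability from the person's age band
   × sex × education cell, raised multiplicatively on the hazard scale by
   current conditions (configurable log hazard ratios).
2. **Incidence** — each absent condition may onset with its stratum-specific
   half-year probability. Chronic conditions are non-reversible: a flag,
   once set, never clears while the person is alive.
3. **Functional decline** — IADL/ADL limitation counts may increment,
   depression may onset, self-reported health takes a small worsening or
   improving step.

Ages advance 0.5 years per cycle (capped at 105; the 100+ band reuses its
parameter cell); dead individuals are frozen. Each calendar year a new
cohort aged 60–62 enters, with counts thinned by pre-entry mortality
attrition and education shares that drift towards higher attainment across
cohorts — the mechanism that drives compositional improvements over the
projection. Results are reported on a 3-year grid; survey-calibrated
parameter tables are stated as half-year probabilities, with
`halfyear_prob_from_3yr()` / `threeyr_prob_from_halfyear()` converting
under a constant-hazard assumption (`p½ = 1 − (1 − p₃)^{1/6}`).

The within-cycle event order (mortality → incidence → functional) is a
design choice: it affects results only at the margin, but it must be fixed
and documented because the alternatives are not identical. Common random
numbers — one uniform per person, cycle and event channel — make
comparative runs sharp: raising any mortality cell can never increase the
number alive at a later time.

## Classifying dementia, MCI and frailty

Cognitive impairment is operationalised the way survey-based dementia
algorithms do it: a **multivariate probit** of ten correlated binary
outcomes — failure on three cognitive tests (immediate word recall, delayed
recall, serial sevens) and difficulty with seven IADLs — on age, sex,
education and comorbidity. Fitting is per-outcome maximum-likelihood probit
plus a pairwise moment-matching estimate of the latent correlation matrix
(a composite-likelihood strategy; full joint ML over ten outcomes buys
little here and costs much). The bivariate normal rectangle probabilities
needed for the pairwise step are computed by Gauss–Legendre quadrature
along the correlation path with an `r = sin θ` substitution, which removes
the endpoint singularity and is accurate to ~1e−8.

For each simulated person the model implies two probabilities:

* `p_fail` — probability of failing the battery (default: at least 2 of 3
  tests below cutoff; the `battery_k` rule is configurable because the
  exact battery rule is not identifiable from the available material);
* `p_joint` — probability of battery failure together with at least one
  IADL difficulty.

Joint orthant probabilities under the latent-normal model are computed by a
one-factor Gauss–Hermite reduction when the correlation is (close to)
exchangeable — the default is exchangeable ρ = 0.3 — and by fixed-seed
Monte Carlo for general matrices. The quadrature path is exact for
exchangeable matrices and is the pipeline default; the two routes agree to
< 0.02 in tests.

**Thresholds are calibrated, not assumed.** Given target prevalence curves
(age band × sex), bisection on the empirical prevalence step function finds
cutoffs `θ_dementia` (on `p_joint`) and `θ_MCI` (on `p_fail`, among persons
not labelled dementia) so the modelled overall prevalence matches the
target within 1e−4 — or to the nearest attainable share when tied
predictions quantise the step function (accepted up to half the boundary
tie-group share, capped at one percentage point; beyond that the
calibration errors rather than silently mislabel). Dementia is the more
severe label substantively — it requires the IADL component — but the two
cutoffs act on different probability scales, so no order relation between
the numbers `θ_dementia` and `θ_MCI` is enforced. The default is one global
threshold pair matched to the population-wide target, with achieved
prevalence per age band and sex reported for validation
(`achieved_by_cell`); per-sex calibration is available via
`threshold_granularity = "sex"`.

Frailty is a **logistic regression** of the binary frailty phenotype
(emulating a community survey of 1952 people aged 65+ that used a modified
Cardiovascular Health Study instrument) on age, sex, education, seven
comorbid conditions, depression and impaired mobility. "Impaired mobility
in daily living" has no unique mapping from the simulated state; the
default is any ADL limitation or ≥ 2 IADL difficulties, configurable via
`impaired_mobility()`. Frailty is re-evaluated at every reporting period
from current covariates — unlike the chronic flags it may fluctuate — and
persons under 65 (outside the survey's support) are never labelled frail.

## Life expectancy

Period life tables are built from the simulation's own occurrence/exposure
rates: each half-year lived contributes 0.5 person-years at the person's
integer age, a death contributes 0.25 (mid-interval convention), and
`q = n·m / (1 + (n − n/2)·m)` per interval with an open terminal interval
closed by `L = l/m`. With a constant hazard this construction is *exact*
for the geometric survival model — a closed form the tests verify to 1e−6.
The Sullivan method then splits life expectancy at 65 into years with and
without each condition, `years_with = Σ prevalence·Lx / l65`, using
prevalence from the same snapshot year (the period perspective). The
partition identity holds to 1e−9 by construction and is asserted on every
run.

Pipeline life tables default to 5-year (abridged) intervals with the open
interval at 90+, because single-year cells become unstable at the
population sizes used for bootstrap work (2,000–20,000 persons); the
single-year path with terminal 100+ is used in the cross-validation test
against direct cohort survival at n = 100,000, where the two estimates
agree within Monte-Carlo error. Empty prevalence cells at extreme ages
inherit the nearest younger cell's value.

## Costs

Health-care use is linear in age, sex, the eleven condition flags and a
multimorbidity indicator (comorbidity count ≥ 3), fitted per service type
(inpatient vs outpatient + prescription) by least squares and annualised
(×12, floored at zero). A *raw* comorbidity count alongside all eleven
flags is an exact linear combination of them; requesting it
(`count_column = "ncond"`) raises the rank-deficiency error naming the
collinear column.

Formal long-term care collapses the seven-level public eligibility scale to
the two tiers the costing actually uses: **high** dependency with any ADL
limitation, **mild** with IADL limitation or frailty only. Monthly cost
means by age band × sex × tier × setting (home/community vs care home) are
table-driven; residence is assigned stochastically from an age- and
tier-dependent care-home probability, since no assignment rule is
identifiable. Informal care, for home-based persons only, is
25 h/week (high) or 10 h/week (mild) × 52 weeks × $11/hour — 14,300 and
5,720 dollars per year exactly, in constant 2016 dollars, no discounting.
Headline condition totals attribute the dementia-and-frailty overlap group
to *both* conditions (with the overlap also reported separately), matching
how such headline figures are customarily quoted. The household-substitution
sensitivity scales informal volume down 20% and community-based formal care
up 13%.

## Uncertainty

`bootstrap_run()` repeats the whole pipeline (default 50 iterations),
redrawing the stochastic baseline population, the entry cohorts and all
transition randomness with seeds derived deterministically from one master
seed; estimated model coefficients are held fixed (re-drawing coefficients
from their sampling distributions would mix estimation and projection
uncertainty and is deliberately out of scope). Summaries are the mean, the
5th/95th **nearest-rank** percentiles (on 50 iterations: the 3rd and 48th
order statistics — conventions differ, so this one is fixed and tested) and
the Monte-Carlo standard error `sd/√n`. Iterations are sequential;
reproducibility is exact under the master seed. In cells where a count is
zero in ≥ 95% of iterations the mean can exceed the nearest-rank 95th
percentile; that is estimator granularity, not disorder, and the tests
distinguish the two.

## The synthetic-data generator

The restricted microdata behind the real study (national living-conditions
surveys, cognitive-test and frailty field studies, insurance claims, a
census–death linkage) cannot be redistributed, so every input is generated
with known ground truth:

* **Baseline population** — age/sex/education composition and logistic
  condition-prevalence models emulating the 60+ population of Japan as of
  2016; mean comorbidity count ≈ 1.5–1.7 at the observed mix.
* **Mortality** — Gompertz hazards with education offsets (±0.25 log
  hazard) and condition log-hazard offsets, calibrated analytically so
  period life expectancy at 65 is ≈ 23.7 years (women) / 18.7 (men) at
  baseline; the education drift of entry cohorts then produces the
  projected LE increase of roughly one year by 2043.
* **Incidence** — half-year logistic models whose levels are derived from
  the baseline cross-sections (hazard ≈ age-slope × prevalence), so
  age-specific prevalence is approximately stationary and the projection's
  drift comes from composition, not an artefact of inconsistent inputs.
* **Surveys and claims** — cognitive outcomes from a thresholded latent
  Gaussian with exchangeable ρ = 0.3 (the real outcome covariance is not
  recoverable; the exchangeable default is a documented stand-in), a
  logistic frailty phenotype, and claims with additive Gaussian noise whose
  intercepts keep the zero floor inactive (< 0.1% of draws), so
  least-squares refits recover the truth within nominal coverage.
* **Calibration targets** — logistic-in-age prevalence curves anchored so
  the overall 60+ prevalence matches 2016 observations (dementia 14.6%
  women / 8.1% men; MCI ≈ 10.4/10.8%; frailty 11.4/7.2%).

One global seed drives everything; module sub-streams are derived
deterministically so any module can be regenerated independently, and a
fixed seed reproduces byte-identical tables.

What the generator does **not** emulate: survey weighting and nonresponse,
measurement error in the cognitive tests, the actual fee schedule of the
insurance systems, behavioural risk factors, or any feedback from
classification onto transitions. Passing tests therefore demonstrate that
the *methods* are implemented correctly and recover known truth — not that
the synthetic defaults reproduce any particular published national figure.

## Problem sizes and numerical choices

Test and acceptance runs use sizes chosen to make Monte-Carlo error small
relative to the assertions while keeping a full suite run in minutes:
n = 100,000 for the Markov-oracle, binomial-survival and
life-table-vs-cohort checks; n = 10,000–20,000 for parameter recovery;
n = 20,000 with a 27-year horizon for the headline projection; 50 bootstrap
iterations at n = 2,000 over 12 years for interval work. Other fixed
choices: Gauss–Hermite with 40 nodes (orthant probabilities), Gauss–
Legendre with 24 nodes (bivariate normal), bisection to 2⁻⁸⁰ with
step-function snapping, calibration tolerance 1e−4, Monte-Carlo orthant
draws 8,000 under a fixed internal seed.

## Known limitations

* Transition parameters are held constant at their baseline ("as of 2015")
  values; no secular improvement in incidence or case fatality.
* Dementia/frailty labels do not feed back into mortality or incidence;
  comorbidity does, which carries part of that association.
* The multivariate probit correlation is estimated pairwise, and
  classification uses its exchangeable approximation; with strongly
  non-exchangeable truth the Monte-Carlo path should be selected instead.
* Education is fixed at entry; within-cohort educational change is ignored.
* Costs exclude indirect productivity losses and price dynamics; informal
  care is valued at a single constant wage.

## A small worked run

```{r example, eval = FALSE}
models <- fit_pipeline_models(truth_parameters(), seed = 1)
cfg <- generator_config(population_size = 20000, seed = 1)
run <- run_projection(cfg, models, horizon_years = 27, seed = 1)

run$prevalence[age_group == "60+" & condition == "dementia" & year == 2016]
run$life_expectancy[year == 2043]
run$cost_totals[group == "all" & year == 2016, sum(total)] / 1e9

ens <- bootstrap_run(generator_config(population_size = 2000, seed = 1),
                     models, n_iterations = 50, master_seed = 1,
                     horizon_years = 12, present_years = c(2016, 2025))
build_prevalence_table(ens, years = c(2016, 2025))
```
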