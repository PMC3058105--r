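---
title: "Microsimulation and deviance calibration of a lung cancer screening trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microsimulation and deviance calibration of a lung cancer screening trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(lungscreensim)
```

## The problem

Historical randomized trials of chest-radiograph lung cancer screening in
heavy smokers produced a puzzling pattern: longer survival from diagnosis in
the screened arm, more diagnosed cancers in the screened arm, but no
reduction in lung cancer mortality. Several competing mechanisms can produce
such a pattern without any true mortality benefit or harm: imperfect test
sensitivity, a systematic tendency to repeatedly miss the same lesion,
over-diagnosis of indolent lesions that would never have surfaced
clinically, and a chance imbalance in baseline cancer risk between arms.

`lungscreensim` turns each of these mechanisms into one free parameter of a
person-level microsimulation, scores simulated diagnosis counts against an
observed count table with a Poisson deviance, and compares the resulting
nested models with chi-squared likelihood-ratio tests. The package's job is
the machinery of that contest — simulation, scoring, fitting, comparison —
plus a synthetic-data generator so that every step can be validated against
ground truth that is known by construction.

## Natural history model

Each person is simulated independently:

* **Onset.** With probability `risk_factor * lifetime_onset_prob` (per cell
  type) the person develops preclinical cancer at an age drawn from a
  Weibull distribution parameterized by shape and mean. Three cell-type
  pathways (squamous, adeno/large, small cell) are simulated with separate
  parameters, mixed in fixed proportions.
* **Progression.** Disease passes through an undetectable preclinical stage
  (`PRE_I`), a screen-detectable preclinical stage (`PRE_II`), and two
  clinical stages (`CLIN_III`, `CLIN_IV`). Dwell times are exponential with
  per-stage, per-type means. A tumor entering stage III surfaces clinically
  at the end of that dwell with probability `p_clinical_dx_at_III`,
  otherwise it progresses and surfaces at the end of its stage IV dwell.
  Clinical surfacing can happen only in stages III/IV; `PRE_II` is
  screen-detectable only.
* **Indolence.** With probability `indolent_fraction` a tumor entering
  `PRE_II` never leaves it: screen-detectable for the rest of life, never
  symptomatic. This absorbing-state reading is the most literal model of an
  over-diagnosable lesion, and makes other-cause mortality the quantity that
  decides whether an indolent lesion is ever found.
* **Competing mortality.** Other-cause death is drawn from an annual life
  table (`make_life_table()` offers constant and Gompertz hazards; the
  default Gompertz, `a = 1e-4`, `b = 0.085` per year of age, puts the median
  other-cause death of a 55-year-old heavy smoker in the late seventies).
  The exported sampler walks the table with one Bernoulli trial per year;
  the vectorized trial engine uses the distributionally identical
  inverse-CDF walk over the same table.

A person whose tumor would have surfaced clinically before trial entry is
treated as contributing no diagnosis — such a person would not have enrolled
cancer-free. Tumors still preclinical at entry are retained; they are the
prevalence pool the first screen harvests.

## Screening model

The intervention arm receives exams every 4 months for 6 years (19 exams,
including the prevalence screen at time zero); each exam is attended
independently with probability 0.75. The control arm's policy is an annual
schedule with attendance 0 — a pure no-screening control — so that every
between-arm contrast is attributable to a modeled mechanism rather than an
assumed usual-care contact rate.

At an attended exam the tumor is detectable if it is in `PRE_II` (stage
group II−, sensitivity `sens_II`) or in stage III/IV but not yet surfaced
(stage group III+, sensitivity `sens_III`). The first attended detectable
exam misses with probability `1 - sens`; after a miss, every later exam in
the *same* stage group misses with probability `min(1, (1 - sens) + syserr)`
— the systematic negative error, a persistent lesion-level effect. Whether
the increment deepens with each successive miss is not identifiable from
count data; the default applies a single fixed increment, and a `compound`
flag applies it once per previous miss instead.

Two consequences of these definitions are worth stating plainly:

* With `sens = 1` fixed, a first miss can never occur, so the systematic
  error parameters have no effect: the SystematicError model's objective is
  flat and its deviance equals the Simple model's. The model is retained in
  the suite because its contract is defined this way; its flatness is itself
  a finding about the parameterization, not a bug.
* Screen detection, when it happens, is always strictly earlier than the
  same path's clinical surfacing time, so lead time is nonnegative by
  construction.

## Trial assembly and count tables

`simulate_trial()` composes the pieces for both arms and aggregates
diagnoses into a count table over arm × detection mode (× stage group
× cell type). The default calibration layout is arm × mode × stage group
(8 cells): fine enough to separate the screen-detected stage shift from
clinical incidence, coarse enough that typical trial-scale cells keep
double-digit counts. The deviance machinery is layout-agnostic; tables can
be aggregated to marginals or refined to cell type.

Expected tables are estimated by simulating `oversample` times the trial's
persons per arm (default 20×) and rescaling, which keeps the Monte-Carlo
standard error of each expected cell well below the Poisson noise of the
observed cell it is scored against.

## Calibration

Cells are treated as independent Poisson counts — the standard
count-calibration choice, under which the saturated model is simply the
observed table itself (`count_deviance()` also offers a per-arm multinomial
family that conditions on arm totals and scores only the allocation of
diagnoses across cells). The Poisson deviance is

```
D = 2 * sum( O * log(O/E) - (O - E) ),    O = 0 terms reduce to E.
```

Free parameters are fitted by minimizing `D` under **common random
numbers**: all the randomness of a fit — entry ages, cell types, onset and
dwell deviates, death ages, attendance, per-exam miss uniforms — is drawn
once from the fit's seed, and every candidate parameter vector is evaluated
against those fixed draws, which it moves only as thresholds. The objective
is therefore deterministic given the seed, nearly piecewise-smooth, and
nested models can be compared without simulator noise masquerading as fit
improvement.

Search is derivative-free and bounded. Single-parameter models
(Overdiagnosis, RiskDifference) use Brent search on the bounded interval,
with the interval ends and the parameter's null value always evaluated as
candidates; one-dimensional Nelder–Mead is documented as unreliable in
`stats::optim`, which is why Brent is used here. Multi-parameter models use
Nelder–Mead on a logit-rescaled unbounded parameterization with three
jittered restarts, stopping when a restart improves the deviance by less
than `1e-3` or 300 evaluations are spent. The null point (all free
parameters at their fixed values) is always evaluated too, so every
extension model is nested in the Simple model by construction, even when
Nelder–Mead stalls short of a boundary optimum.

Degrees of freedom for the likelihood-ratio test equal the number of newly
freed parameters. Because a widely used alternative convention refers every
reduction to one degree of freedom, `run_suite()` reports both `p_value`
(at `df_freed`) and `p_value_df1`.

As a reference for the chi-squared arithmetic itself: upper-tail
probabilities at 1 df are 0.26 at a reduction of 1.27, 0.14 at 2.14, 0.79
at 0.07, and 0.02 at 5.04 (2 d.p.).

## The six models

| Model            | Free parameters                              | Mechanism tested            |
|------------------|----------------------------------------------|-----------------------------|
| Simple           | none                                         | baseline (perfect test)     |
| Sensitivity      | `sens_II`, `sens_III`                        | imperfect test sensitivity  |
| SystematicError  | `syserr_II`, `syserr_III`                    | repeated misses of a lesion |
| SensitivityError | all four above                               | joint test imperfection     |
| Overdiagnosis    | `indolent_fraction`                          | indolent lesions            |
| RiskDifference   | `risk_factor`                                | baseline risk imbalance     |

All six fits in a suite share one observed table and one seed (hence one
common-random-number schedule).

## What the synthetic-data generator emulates — and what it does not

`generate_trial_counts()` runs the simulator at 1× sampling and returns the
realized integer counts: one stochastic trial replicate under explicit
ground truth. That makes parameter-recovery and type-I-error experiments
possible with truth known by construction. It emulates diagnosis count
tables only: no smoking histories, no images, no person-level covariates,
no survival times. Passing recovery tests therefore shows that the
calibration machinery is unbiased and well-behaved *under the model's own
data-generating process*; it cannot show that the natural-history model is
a faithful description of real tumor biology, and it cannot detect
misspecification shared by generator and fitter.

`mlp_fixture_table()` ships the package's canonical pseudo-observed table.
Only the intervention-arm marginals (90 screen-detected, 116 otherwise
diagnosed) are anchored to published totals; the stage-group split and the
entire control arm are synthetic, flagged `fixture` in a `source` column so
no downstream report can silently present them as trial data.

## Default parameters

The natural-history defaults are fixtures, not estimates: no public
person-level data exist to calibrate them, so they were chosen once to give
a trial of roughly 4600 persons per arm on the order of 200 lung cancer
diagnoses per arm over a 10-year follow-up, with a total screen-detectable
sojourn on the order of a year — the scale at which a chest-radiograph
trial in older male heavy smokers operates.

* Lifetime onset probability 0.23/0.24/0.14 (squamous/adeno-large/small),
  mixed 0.35/0.45/0.20 — a weighted lifetime risk of about 22%, at the high
  end of what persistent heavy smoking carries.
* Weibull onset age: mean 62/61/60 years, shape 5/4.5/5.
* Mean dwells (years): `PRE_I` 1.2/1.2/0.7, `PRE_II` 0.6/0.5/0.3, stage III
  and IV 0.4/0.4/0.25 each; small cell fastest throughout.
* `p_clinical_dx_at_III` 0.40/0.40/0.25: most cancers surface in stage IV.
* Entry ages uniform over 45–69; arm sizes 4618/4593; follow-up 10 years.

Changing any of these is a constructor argument away; the defaults exist so
that examples and tests have one documented, trial-scale operating point.

## Numerical choices and degenerate inputs

* Deviance cells with `O = 0, E = 0` contribute zero; `O > 0, E = 0` yields
  an infinite deviance with a warning (the optimizer treats the point as
  rejected rather than erroring out).
* A candidate `risk_factor` that would push any cell type's onset
  probability above 1 is rejected with an infinite objective value.
* The exam schedule is `0, interval, ..., <= duration` with a small
  tolerance in the count so that `duration/interval` landing on an integer
  boundary in floating point still yields the full schedule.
* Ages are continuous years; the life table's cap age (`max(age) + 1`) acts
  as administrative censoring of the lifespan.
* Observed tables must be integer; expected tables are nonnegative reals.

## Problem sizes used by the validation suite

The package's own tests exercise the pipeline at sizes chosen to make
Monte-Carlo tolerances meaningful: distributional oracles at 10^5 draws
(3-standard-error bands), detection-probability oracles at 10^5 screening
replicates per setting against brute-force hit/miss enumeration, and
parameter recovery over 20 replicate synthetic trials at trial scale with
fitting simulations of 2 × 10^4 persons per arm. Suite-level type-I and
power behavior is measured over 20 replicate six-model suites at the
default 20× oversampling, where the deviance-reduction null distribution is
close to its chi-squared reference; at much smaller oversampling the
simulator's own noise inflates the reductions and the nominal quantiles
become conservative in the other direction.

## Known limitations

* One tumor per person (first onset only): diagnosis counts are
  person-level, so multiplicity is not identifiable here.
* Attendance is independent per exam; habitual attenders/refusers are not
  modeled.
* The control arm's usual-care screening contact is off by default; if a
  nonzero contact rate is configured, screen-detected cells appear in the
  control arm and the between-arm contrast changes meaning.
* Survival and mortality endpoints are out of scope: the calibration
  currency is incidence counts by detection mode.
* The biological sub-phases of early carcinogenesis are collapsed into
  dwell-time distributions; the model cannot distinguish mechanisms that
  only differ inside those phases.

## A minimal session

```{r, eval = FALSE}
# a synthetic trial with a true 30% risk excess in the intervention arm
truth <- truth_spec(config = trial_config(risk_factor_intervention = 1.3))
obs <- generate_trial_counts(truth, seed = 42)

# fit the six models and compare
comparison <- run_suite(obs, trial_config(), seed = 43)
comparison

# the winning model's fitted risk factor
attr(comparison, "fits")$RiskDifference$fitted_values
```
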