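---
title: "Emulating monthly nested trials of menopausal hormone therapy: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating monthly nested trials of menopausal hormone therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mhtemulate)
```

## The problem

Whether contemporary menopausal hormone therapy (MHT) raises the risk of
cardiovascular disease cannot be settled by naive cohort comparisons:
comparing prevalent users with non-users selects tolerant survivors into
the user group, and letting follow-up start at different times for exposed
and unexposed women manufactures immortal time.  The remedy implemented
here is target-trial emulation: at a sequence of calendar time zeros, a
hypothetical randomized trial is "run" on registry data — eligibility is
evaluated at time zero, treatment strategy is assigned from dispensations
in that month, follow-up starts at that same time zero, and randomization
is emulated by inverse-probability weighting.

`mhtemulate` implements that full pipeline against linked longitudinal
registry tables (persons, dispensations, diagnoses, procedures), plus a
synthetic registry generator with known ground truth so the pipeline can
be validated end to end without access-restricted register data.

## Trial structure

One emulated trial starts on the first day of every calendar month of the
study window; the default window, July 2007 through December 2018, gives
138 trials (`make_trial_sequence()`).  A woman is eligible for a trial if,
at its start date, she

* is aged 50–58 in completed years (birthday arithmetic, the registry
  convention — not division by 365.25);
* has redeemed no systemic MHT prescription in the washout window of 730
  days (2190 for the six-year sensitivity screen).  The window is the
  half-open interval `[start − washout, start)`: a fill on the boundary
  day counts as inside the washout, a deterministic and
  exclusion-conservative reading of "the previous two years";
* has no exclusion diagnosis ever (prior ischaemic heart disease, stroke,
  peripheral vascular or arterial disease, any cancer — matched on ICD-10
  prefixes, with the full available history);
* has no exclusion procedure: hysterectomy, bilateral oophorectomy,
  sterilisation, or unilateral oophorectomy on **two distinct dates**;
* is alive and present (death or emigration on the trial start day
  excludes, so every follow-up time is strictly positive);
* first appears in the registers by the registration cut-off (end of
  2005), which screens out women with missing pre-immigration history.

`failed_criteria` records *every* violated criterion, not just the first,
so screening is auditable.  Because an initiator's fill sits inside the
washout window of subsequent trials, she is ineligible for at least the
next 24 monthly trials; with day-level arithmetic a 25th exclusion occurs
only for some fill dates, and we deliberately do not reverse-engineer a
month-level washout to force it.

## Treatment strategies

Each eligible woman's trial-month dispensations map to one of eight
strategies (`assign_strategy()`), with a fixed priority order: tibolone
dominates combinations; transdermal oestrogen plus any progestogen (oral,
transdermal, or local including the levonorgestrel intrauterine system,
LNG-IUS) is transdermal combined; transdermal oestrogen alone is
transdermal unopposed; oral oestrogen plus an LNG-IUS insertion forms its
own arm; fixed oral combined products carry their labelled
continuous/sequential class; an oral oestrogen redeemed together with a
separate progestogen is "self-combined" and split by the
oestrogen:progestogen per-DDD dose ratio — below 7 continuous, above 7
sequential.  A ratio of exactly 7 is not covered by the published rule;
the tie policy assigns it to the continuous class and logs it.  The
priority order is itself a design choice (the source protocol states the
transdermal-combined rule explicitly but not the full order); it is
configurable through `strategy_rule()`.  Progestogen-only dispensations
without oestrogen or tibolone are not systemic MHT: the woman is
classified non-initiator and the record flagged as an anomaly.

The ratio uses the per-DDD dose in mg-equivalents as recorded in the
dispensation table; cross-compound potency conversion is out of scope.

## Outcomes and competing risks

Five outcomes are ascertained per person-trial: ischaemic heart disease
(I20, I21, I22, I24, I25), myocardial infarction (I21, I22), cerebral
infarction (I63), venous thromboembolism (I26, I80, I81, I82), and the
composite cardiovascular outcome (the arterial union; VTE is always
analysed separately).  Follow-up runs to the first of: outcome event,
competing event, death, emigration, or administrative end at 730 days.

The competing set for each outcome is the other analysed outcomes, with
one deliberate exception: because MI is a subset of IHD, MI events never
compete against the IHD or MI analyses (an I21 at day 30 is an IHD
*event*, not a censoring).  Whether VTE competes against the arterial
outcomes (and vice versa) is a configuration switch (`vte_competes`),
on by default.  A fatal event recorded in the cause-of-death register on
the death day counts as an event (event outranks death at a tie);
non-cardiovascular death is a competing terminal state; emigration is
treated as loss to follow-up.

Medication covariates (hypertension, heart disease, diabetes drugs) are
computed from ATC-matched dispensations in the 365 days before each trial
start.  The lookback length is a declared default — one year is a
standard drug-based comorbidity window — since the source's exact window
is not public.

## Adherence: episodes and protocol deviations

Treatment episodes chain fills into continuous-use intervals
(`compute_episodes()`).  A fill of `n_packages × ddd_per_package` tablets
at one DDD per day covers that many days; after each fill the exposure
window extends by a grace period of **twice the most recent single
package's coverage** — a 42-tablet package extends exposure by 84 days
beyond the last covered day.  A fill arriving within the extension chains
into the episode; a later fill starts a new one.

Per-protocol deviations (`pp_censor_time()`): an initiator deviates when
her baseline episode's extension lapses without a refill (discontinued)
or when she redeems a fill incompatible with her baseline strategy
(switched preparation); a non-initiator deviates at her first systemic
MHT fill.  Switching is judged at the *strategy* level — a brand change
within the same class is not a deviation; whether the source study used
product- or strategy-level change is unstated, and strategy-level is the
default here.  The LNG-IUS is assumed in place for the entire follow-up:
insertion records neither extend nor shorten episodes, and only the oral
component of that arm can trigger discontinuation.

## Weighting

**Treatment weights.**  For each contrast (one initiator strategy versus
non-initiators) a binomial logistic propensity model of initiation on the
baseline covariates — age, trial month (continuous 1–138), calendar year,
education, geographical region, region of birth, and the three medication
flags, continuous terms entering linearly — yields stabilized weights
`sw = P(A=a) / P(A=a | L)` with the marginal arm probability in the
numerator.  One binary model per contrast mirrors the pairwise contrast
structure (a multinomial over all eight arms is the documented
alternative).  Within a contrast the mean stabilized weight should sit
near 1; `weight_diagnostics()` reports mean, tails, effective sample size
and weighted/unweighted standardized differences.  Truncation is off by
default and available as percentile caps.  A treated woman with fitted
propensity 0 (or an untreated woman with propensity 1) is a hard
positivity error; strata that contain one arm only produce bounded
weights and are downgraded to a warning.

**Censoring weights.**  For the per-protocol contrast, follow-up is split
into 30-day intervals and pooled binomial models of deviating per
interval are fitted — numerator on interval terms (linear plus quadratic)
only, denominator additionally on the covariates.  The models are fitted
*separately per arm*, because the deviation mechanisms differ in kind:
initiators discontinue or switch, non-initiators start treatment; a
pooled additive model would dilute exactly the covariate effects the
weights must capture.  The stabilized weight of an interval is the
cumulative product of the numerator-to-denominator probabilities of
remaining undeviated, multiplied onto the treatment weight.  If an arm
has no deviations its censoring weights are exactly 1.  The interval
models are solved by Fisher scoring on a pre-built design matrix
(numerically the same iteration as `glm`, with a relative deviance
tolerance of 1e-6), which keeps interval-expanded fits with hundreds of
thousands of rows fast on one core.

Finite-sample behaviour worth knowing: the cumulative product amplifies
coefficient noise of the denominator model, so individual censoring
weights in small arms can drift far from 1 even under non-informative
stopping; the distribution stays centred on 1.  Percentile truncation
(e.g. at the 1st/99th weight quantiles) is the standard mitigation when
tails matter: it trades a controlled bias back toward the unweighted
estimate for a substantial variance reduction, which is usually the
right trade at moderate sample sizes.

## Estimation

The hazard model is a marginal structural Cox model: a single time-fixed
binary treatment term, covariates entering **only** through the weights.
Ties use the Efron approximation; the variance is the robust sandwich
estimator clustered on person identity, because the same woman
contributes to many stacked trials.  Confidence intervals use 1.96 normal
quantiles at the 0.05 level; estimates are average contrasts over the
two-year follow-up (no time-varying coefficient).  Fitting goes through
`survival::coxph`; the test suite independently verifies the fitted
log-hazard-ratio against a brute-force maximiser of the same weighted
Efron partial likelihood to 1e-6 on small datasets.

The Fine–Gray sensitivity model (`fit_fine_gray()`) keeps individuals
with competing events (including death) in the risk set with
time-decreasing census weights via `survival::finegray`, estimating a
subdistribution hazard ratio — a total effect on cumulative incidence,
versus the cause-specific ratio's direct-effect reading.  With zero
competing events the two coincide; the suite also cross-checks the path
against `cmprsk::crr`.  Adjusted cumulative incidence
(`adjusted_incidence()`) is an IPTW-weighted Aalen–Johansen estimator per
arm, from which the one-year absolute risk difference is read; adjusted
incidence rates are weighted events over weighted person-years per 1000.

Hazard ratios from this design inherit the usual built-in selection of
hazard-based estimands; the package therefore reports incidence curves
and rates alongside, rather than hazard ratios alone.  Pooled logistic /
discrete-time estimation is a non-goal.

## The synthetic registry generator

`simulation_scenario()` + `simulate_registry()` generate linked
registries with the statistical structure the analysis assumes:

* **Population.**  Ages at study start span beyond 48–60 so the 50–58
  window is populated in every trial month; education, region of birth,
  geographical region and medication-flag marginals default to the
  published non-initiator distribution (e.g. diabetes medication 7.8%,
  urban residence 32.3%).
* **Initiation.**  A per-month logistic hazard while aged 50–58: baseline
  `monthly_init_prob` (default 0.0008, reproducing an ever-initiator
  share near 8% over 138 months) plus the confounding linear predictor.
  Each woman initiates at most once; re-initiation after discontinuation
  is not generated, since no downstream rule depends on it.  Strategies
  are drawn from `strategy_mix`, defaulting to the published mix (oral
  combined continuous above a third of initiations).
* **Dispensations.**  First fill in the initiation month, refills at
  package-coverage intervals ({28, 42, 84} DDD packages, one DDD/day)
  until a geometric stop calibrated to `monthly_stop_prob` per 30 days
  (default 0.051, matching 46% discontinuation within a year).
  Self-combined arms emit paired oestrogen/progestogen rows with ratios
  on the intended side of 7; the LNG-IUS arm emits one insertion record.
  Flagged women receive quarterly medication fills so covariate lookbacks
  find them.
* **Outcomes.**  Cause-specific *exponential* hazards — chosen precisely
  because closed forms give oracle answers for rates, risk differences
  and calibrated effects — with baseline rates (per 1000 person-years)
  ihd 2.55, cerebral infarction 1.01, vte 2.26, partitioning the
  published pooled composite non-initiator rate of 3.56 by observed event
  shares; 42% of ihd events are coded I21/I22.  The strategy's `true_hr`
  multiplies the hazard while generatively exposed: for the whole
  follow-up from initiation (`effect_mode = "itt"`) or only while fills
  cover the day (`"pp"`).  Death (default 2/1000 py) and emigration
  (1.5/1000 py) compete; a small fraction of arterial events is fatal and
  sourced from the cause-of-death register.
* **Confounding and censoring.**  `confounding_strength` applies the same
  named effects to initiation log-odds and outcome log-hazard;
  `hazard_only_strength` affects the hazard only (a risk factor that does
  not influence prescribing — needed to study censoring selection in
  isolation); `informative_censoring` makes the stop probability depend
  on a chosen covariate.
* **Determinism.**  Per-table random streams derive from one master seed,
  so regenerating one table does not perturb the others; identical
  scenarios reproduce identical registries.

What the generator does **not** emulate: the joint covariate distribution
of the real Swedish cohort (only the marginals), calendar trends in
prescribing or incidence, dose titration and stockpiling, cancer
incidence beyond exclusion flags, and any real dependence of
discontinuation on covariates (the informative-censoring scenario is a
stylised stand-in).  Passing tests therefore demonstrate that the
*pipeline recovers known truths under the design's assumptions*, not that
the assumptions hold in any particular registry.

## Validation scale and numerical conventions

The test suite validates the pipeline at desk scale, with baseline event
rates raised in proportion so effects stay identifiable: confidence
coverage of a confounded null uses 200 replicates of 5,000 women across
12 trials; effect recovery uses a hazard ratio of 1.5 on roughly 100,000
stacked person-trials; the risk-difference check calibrates the hazard
ratio by closed form (`hr_for_risk_difference()`) so the generative
one-year risk difference is exactly 1 per 1000, and recovers it on about
200,000 person-trials; the censoring-weight repair check uses 100
replicates of an informative-censoring scenario.  All generative truths
are fixed analytically before simulation.

Numerical conventions collected in one place: dates are day-resolution;
the washout is half-open with the boundary day inside; age is completed
years; death or emigration on a trial start day excludes; event outranks
competing event outranks death outranks emigration at a tied day; the
self-combined tie at ratio 7 goes to continuous and is logged; Efron tie
handling; 1.96 normal quantiles; propensity fits use `glm` defaults,
interval-expanded censoring fits Fisher scoring with relative deviance
tolerance 1e-6; no weight truncation unless requested.

## Limitations

Unmeasured confounding (smoking, body-mass index) is inherited from the
design and only mitigated by proxies; exposure is redemption, not
ingestion; the strategy classifier trusts the register's dose fields; the
per-protocol censoring model's exact specification in the source study is
not public, so the construction here (30-day intervals, per-arm pooled
logistic) is a declared reconstruction; dynamic treatment strategies are
out of scope.
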