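---
title: "Methods: visit-level risk triaging for interruption in HIV treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: visit-level risk triaging for interruption in HIV treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iitriage)
```

## The outcome and the analysis unit

The primary outcome is an **interruption in treatment (IIT)**: a scheduled
clinic visit not attended before or within 28 days of its scheduled date.
The boundary is inclusive — attendance exactly 28 days late still counts as
retained; 29 days is an interruption — and attendance *before* the
scheduled date counts as on time. The analysis unit is the *visit*, not the
client: every scheduled visit is scored for the risk that the client's
**next** scheduled visit ends in an interruption, so one client contributes
as many observations as they have visits with an observed follow-up.

Two censoring conventions protect the outcome definition:

* a visit is **eligible** only if scheduled at least three calendar months
  before the database censor date (one month for the outcome window, two
  for data-capture lag);
* a visit's `iit_next_visit` is absent when there is no eligible next
  scheduled visit — the last observed visit of each client carries no
  label and is excluded from model training, triage tables and archetype
  tables.

For a never-attended visit, the next *observed* scheduled visit (the
re-engagement visit) serves as the next visit when one exists. Pairing
conserves events: the eligible IIT count equals the count of
`iit_next_visit = TRUE` plus IIT visits that open their client's sequence —
a property the test suite asserts on random synthetic cohorts.

Time on ART is measured in calendar months by date arithmetic, never
30-day blocks. Strata are `[0, 6]` and `(6, 12]` months, boundaries
inclusive on the right endpoint named: a visit exactly six calendar months
after initiation is in the 0–6 stratum, a visit at 6.5 months is in 7–12.
The first follow-up visit after initiation is flagged as its own stratum
(it also lies within the first six months).

## Predictor features and leakage control

`build_features()` computes, per eligible visit, the visit-history and
client covariate features of the risk model. All history windows run over
strictly prior visits *plus the current visit's own lateness*; nothing
dated after the current visit enters a feature. Specific operationalized
definitions:

* `pct_visits_gt3d_late` and `n_times_gt28d_late` use strict inequalities
  (>3, >28 days); a never-attended visit counts as late under both.
* `n_missed_months` — undefined in most reporting conventions — is the
  count of distinct calendar months between the first and current visit
  containing no attended visit: the simplest auditable reading.
* `visits_on_regimen` counts consecutive visits on the current regimen
  code.
* Viral-load features (`last_vl_value`, `months_since_last_vl`,
  `n_vl_tests`) only use results whose result date is on or before the
  current *scheduled* date.
* `day_of_week_next_appt` is ISO-encoded (Monday = 1); the next
  appointment's date is known at the current visit, so these are not
  leakage.
* Fractional durations use months of 30.4375 days.

`restrict_to_emr_features()` drops the five survey-derived predictors
(screening CD4, travel time, TB symptom count, year first tested positive,
household size), leaving the sixteen variables available from routine EMR
data alone; comparing the full and restricted model quantifies the added
value of a baseline survey.

`encode_for_model()` produces the numeric design matrix: categoricals are
one-hot encoded with an `other` bucket for levels unseen at training time,
and *every* feature column is paired with a missingness indicator, absent
values imputed with a sentinel (0). Sentinel-plus-indicator was chosen over
row dropping because the triage use case requires a score for every visit,
including visits with incomplete labs. Column order is deterministic and
reproduced exactly at scoring time from stored metadata.

## The classifier

The scorer is AdaBoost (discrete SAMME / AdaBoost.M1) over depth-1
`rpart` decision stumps, written out in full in `train_classifier()`:
round *m* fits a weighted stump, its weighted error $\varepsilon_m$ sets
the vote weight $\alpha_m = \tfrac{\mathrm{lr}}{2}\log\frac{1-\varepsilon_m}{\varepsilon_m}$,
and misclassified observations are reweighted by $e^{\alpha_m}$. The visit
score is $\sigma(2F(x))$ where $F$ is the alpha-normalized weighted vote
margin in $[-1, 1]$ — probability-like, monotone in predicted risk, and
invariant in rank under rescaling of the vote weights (the AUC therefore
is too). Defaults: 200 rounds, learning rate 1, matching common library
defaults for the algorithm; both are configurable. If no stump beats
chance (e.g. constant features) the scorer degrades to the training
prevalence as a constant score rather than failing. A gradient-boosting
alternative (`algorithm = "gradient_boost"`, via xgboost, depth 3,
logistic objective) is provided for comparison; AdaBoost is the primary
algorithm.

Class imbalance (IIT rates near 11–14%) is addressed before training by
random **down-sampling** of the majority class to the minority size, or
**up-sampling** of the minority with replacement to the majority size
(`rebalance()`); the test set is never resampled. Train/test splitting
defaults to the *visit* level with outcome stratification — clients may
straddle the split, mirroring the reference analysis design — with a
client-level split (`split_unit = "client"`) available as the
methodologically safer, leakage-free alternative, and a time-based split
(`split_unit = "time"`, most recent four months held out) for
deployment-style evaluation. Confusion-matrix metrics are reported at a
score threshold of 0.5 (the natural midpoint of the vote margin; no
published threshold exists to adopt), alongside the threshold-free AUC.

`bootstrap_stability()` refits the whole split/rebalance/train pipeline on
bootstrap resamples and reports per-feature top-*k* selection frequencies
and metric quantiles (q05/q50/q95), the standard check that a parsimonious
top-*k* model (default k = 11) is not an artifact of one split.

## Threshold triage

`assign_bins()` classifies scored visits by empirical percentile:
the lowest 50% of scores are green (low risk), the middle 40% yellow
(moderate), the top 10% red (high). Cutpoints are order statistics of the
scores themselves; **ties at a cutpoint all go to the lower-risk bin** — a
conservative rule that can never inflate the red bin (boosting scores are
discrete, so ties are common). If every score is tied the result is
all-green with a warning. Percentiles are computed on the scored analysis
set itself; a frozen-cutpoint deployment mode is available by reusing the
returned `score_cutpoints`.

The 50/90 defaults are motivated by a doubling criterion: cutoffs at which
each bin's IIT rate is roughly twice the bin below.
`calibrate_doubling_cutoffs()` re-derives cutoffs from data by grid search
(p1 over 0.20–0.80, p2 from p1+0.05 to 0.98, step 0.01). Two objectives
are implemented:

* `method = "lsq"`: the direct ratio-matching criterion
  $\left(\log\frac{r_y}{r_g} - \log 2\right)^2 + \left(\log\frac{r_r}{r_y} - \log 2\right)^2$;
* `method = "ml"` (default): for each candidate pair, the constrained
  binomial model with bin rates $(r, 2r, 4r)$ is fit by one-dimensional
  maximum likelihood and the pair with the best likelihood wins.

The likelihood objective is the default because the least-squares form is
weakly identifying in practice: with rare events the log-ratio of a small
tail bin is noisy, and candidate pairs far from the true change points can
beat the truth by chance. The constrained likelihood weighs every visit
and rewards within-bin homogeneity, and in repeated simulations from a
generator with rates doubling exactly at the 50th/90th percentiles it
recovers (0.50, 0.90) to within one grid step, which the least-squares
objective does not. Candidates with an event-free bin are skipped; if all
are skipped, the function errors rather than guessing.

## Archetype triage

`builtin_rules()` encodes sixteen rule-based profiles in three categories:
four mutually exclusive demographic strata (adult female/male at ≥25
years; AGYW/ABYM at 15–<25 — age 25 exactly is adult, closing the gap a
"between 15 and 25 / over 25" reading would leave), four behavioral rules
readable from any EMR, and eight socio-behavioral rules requiring survey
fields. Operationalizations the rules share:

* "attended on time" / "regularly prompt": within 3 days of schedule;
  *regularly* requires at least two prior visits, all prompt. "Regularly
  late": at least two prior visits attended more than 3 days late. Both
  reuse the model's own 3-day lateness feature rather than inventing a new
  boundary.
* "returning after disengagement": any prior visit missed under the
  28-day rule (attended >28 days late *or* never attended) — once a
  client has disengaged and returned, the state persists for all later
  visits.
* "lives alone" means zero other household members; "alone or with one
  other person" means ≤1. "More than 20 minutes away" and "less than 20
  minutes" are both strict: exactly 20 minutes matches neither rule, and
  this is deliberate rather than an off-by-one.
* "next visit scheduled <7 days from payday" uses circular day-of-month
  distance (a payday on the 28th is 3 days from an appointment on the 1st).
* Multi-facility attendance ("shopper", "loyal") reads a per-client flag;
  the generator synthesizes it as a Bernoulli covariate rather than
  simulating inter-facility movement.

A visit with client age under 15 receives no demographic archetype. Rules
whose survey fields are absent for a client skip that visit (not matched)
and report the skip count; a survey field absent for *every* client raises
a configuration warning. `archetype_table()` compares each archetype to a
reference (conventionally: adult females for demographic rows and the
demographic-by-behavior combined table; prompt-and-loyal for behavioral;
super-green for socio-behavioral) by crude RR, optionally restricted to
the first six months on ART, and optionally crossed demographic ×
behavioral.

`discover_archetypes()` is the enumerative companion: all value
configurations of every key-variable pair (order configurable) are
evaluated for IIT rate against the whole-population baseline. Segments
smaller than `min_size` (default 50 visits — the source procedure says
only that "very small" subgroups were removed) are dropped; logically
contradictory condition sets necessarily have zero support and are removed
by the same filter.

## Crude relative risk

`crude_rr()` computes RR = (a/n1)/(c/n0) with the Katz log-method interval
$\exp(\ln RR \pm z\sqrt{1/a - 1/n_1 + 1/c - 1/n_0})$, z = 1.96 at 95%.
This estimator was fixed because it reproduces the checkable published
worked examples at two-decimal rounding; bootstrap or model-based
intervals are deliberately out of contract. Zero reference events make the
RR undefined (an error — no silent continuity correction); zero exposed
events return RR = 0 with the interval flagged undefined. Rounding is
half-up to two decimals and happens only at rendering
(`format_rr()`, `render_triage_table()`). No adjustment is made for
repeated visits per client: the estimates are crude by design, and the
intervals are accordingly anti-conservative for clustered visits — a
documented limitation, not a defect.

## The synthetic cohort generator

`generate_cohort()` emulates the data structure the pipeline assumes:

* **Schedules.** First follow-up 28 days after ART initiation, monthly for
  the first three visits, then every two months to the follow-up horizon
  (default 24 months) — a typical early-ART schedule producing realistic
  per-client visit counts.
* **Disengagement propensity.** Per client,
  $\mathrm{logit}(p_i) = \mathrm{logit}(p_0) + x_i'\beta + \epsilon_i$,
  with $\epsilon_i \sim N(0, \sigma)$ persistent client-level noise
  (default σ = 0.7). The vector $p$ is then mean-normalized on the
  probability scale so the marginal per-visit miss probability equals
  `base_iit_rate` (default 0.12, matching reported IIT rates of 11–14%)
  exactly in expectation — without normalization, Jensen's inequality
  would bias the marginal away from the target whenever σ > 0.
* **Lateness.** Each scheduled visit draws its delay category from the
  mixture {on-time (≤0 d, up to 5 d early), 1–3 d, 4–28 d, >28 d}; the
  >28 d mass is the client's (tilted) miss probability, the attended
  categories share the rest proportionally. A missed visit is attended
  29–120 days late with probability 0.6, otherwise never; a never-attended
  visit is followed by a re-engagement visit 60–150 days later with
  probability 0.7, otherwise the client's stream ends.
* **Covariates.** Demographics approximate the reference populations (64%
  female, ages centred in the mid-30s); survey fields (employment, payday
  among days 25–31 for the employed, household size, travel time,
  disclosure, testing history, readiness) and labs (viral load and
  screening CD4 present with probability 0.7) exist to exercise the
  survey-dependent archetypes and absent-value handling. Default covariate
  effects are moderate log-odds tilts (0.2–0.5) on youth, male sex,
  multi-facility attendance, distance, living alone and unpreparedness —
  the direction and rough magnitude of the risk gradients the archetype
  literature reports.
* **Determinism.** A single seed fans out into independent per-client
  substreams, so enlarging the cohort leaves earlier clients' records
  bit-identical; identical configurations reproduce byte-identical CSVs.

Default `archetype_multipliers` are neutral (1.0): the elevated risk
observed among clients returning after disengagement arises from the
persistent latent heterogeneity (clients with high $\epsilon_i$ both miss
more visits and accumulate the returning state), which is the realistic
mechanism. The multiplier hook exists to inject explicit state dependence
and for monotonicity testing.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: inter-facility transfers (misclassified as
missed visits in real EMR data too), secular trends and seasonality in
attendance, measurement error in scheduled dates, survey non-response
correlated with risk, and mortality. One structural subtlety is worth
knowing: under client-level heterogeneity the realized per-visit IIT rate
runs slightly below the nominal target, because higher-risk clients exit
their visit streams earlier and so contribute fewer visits (informative
dropout). The calibration tests therefore assert the marginal under
homogeneous clients (σ = 0), where the target is exact.

## Numerical and testing conventions

Problem sizes in the test suite were chosen to make the stochastic
assertions sharp at interactive runtimes: calibration and monotonicity
checks use 1500–2000 clients (roughly 20–26k visits) with ±2 binomial SE
bands; discrimination and bin-monotonicity checks use a 600-client cohort
(~6700 scored visits) with strong injected effects (log-odds 0.6–1.2);
doubling-cutoff recovery uses 5000 scored visits; CI coverage uses 2000
simulated tables of two groups of 1000 at 30% event rates, where the exact
coverage of the Katz interval is 0.9505, within half a Monte-Carlo
standard error of nominal. The end-to-end reproducibility check runs a
500-client pipeline twice and compares artifacts byte for byte. All
stochastic tests run under fixed seeds.
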