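# iitriage

Risk triaging for interruption in HIV treatment (IIT) from longitudinal
clinic visit records.

Lifelong antiretroviral therapy (ART) only works when clients keep coming
back. Programme data from high-burden settings show that a client who misses
a scheduled clinic visit by more than 28 days — the PEPFAR-aligned
definition of an interruption in treatment — is at sharply elevated risk of
disengaging from care altogether. `iitriage` packages the full analysis
pipeline for building and evaluating *visit-level* risk triage from routine
electronic medical record (EMR) data and baseline survey data, for
epidemiologists and implementation scientists working on retention in care:

1. **Outcome labeling** — apply the 28-day rule to scheduled/attended visit
   pairs (`label_visits()`), pair each visit with the IIT status of the
   *next* scheduled visit (`pair_next_visit()`), and exclude visits
   scheduled within three months of the database censor date.
2. **Feature engineering** — visit-history predictors computed only from
   information available at the visit: % of visits attended >3 days late,
   number of times >28 days late, months since last visit, last viral load,
   next-appointment calendar features, and so on (`build_features()`).
3. **Risk scoring** — an AdaBoost classifier of depth-1 decision stumps,
   trained after random down- or up-sampling of the majority (on-time)
   class, emitting a probability-like score per visit
   (`train_classifier()`, `score_visits()`, `evaluate()`).
4. **Threshold triage** — visits below the 50th percentile of scores are
   *green*, the middle 40% *yellow*, the top 10% *red*; cutoffs can also be
   re-derived from the rate-doubling criterion
   (`assign_bins()`, `calibrate_doubling_cutoffs()`, `triage_table()`).
5. **Archetype triage** — sixteen rule-based client profiles (demographic,
   behavioral, socio-behavioral: "late twice", "returning after
   disengagement", "super green", "lone ranger", ...) with crude relative
   risks against a reference group, plus an enumerative discovery procedure
   over key-variable configurations (`builtin_rules()`,
   `assign_archetypes()`, `archetype_table()`, `discover_archetypes()`).
6. **Crude relative risks** — for a 2×2 table with `a/n1` events in the
   exposed group and `c/n0` in the reference group,

   RR = (a/n1) / (c/n0),  95% CI = exp( ln RR ± 1.96 · √(1/a − 1/n1 + 1/c − 1/n0) )

   the Katz log-method interval (`crude_rr()`).

Because the source EMR and trial datasets of such analyses are restricted,
the package ships a synthetic cohort generator (`generate_cohort()`) that
emulates their statistical structure — monthly-then-bimonthly visit
schedules, a lateness mixture tilted by a covariate-linked latent
disengagement propensity, re-engagement after missed visits, and a
calibrated marginal IIT rate of ~12% — so every stage of the pipeline is
testable end to end without any data download.

## Worked example

```r
library(iitriage)

cohort  <- generate_cohort(generator_config(n_clients = 800, seed = 7))
labeled <- label_visits(cohort$visits, censor_date = max(cohort$visits$scheduled_date))
labeled <- time_on_art_stratum(labeled, cohort$clients)
labeled <- pair_next_visit(labeled)

fv     <- build_features(labeled, cohort$clients)
scored <- fv[!is.na(fv$iit_next_visit), ]
mc     <- model_config(n_estimators = 150, seed = 7)
parts  <- split_train_test(scored, mc)
scorer <- train_classifier(rebalance(parts$train, "downsample", seed = 7), mc)
evaluate(scorer, parts$test)

scores <- score_visits(scorer, scored)
tab    <- triage_table(assign_bins(scores), scored)
render_triage_table(tab[tab$stratum == "all", ])
```

```
  stratum bin    visits iit          rr_95ci
1 all     all      9105 12% (n=1101) ""
2 all     green    4553 9% (n=417)   "Ref"
3 all     yellow   3644 14% (n=497)  "1.49 (1.32-1.68)"
4 all     red       908 21% (n=187)  "2.25 (1.92-2.63)"
```

Of 9105 scored visits, 12% are followed by an interruption. The score-based
bins separate risk as intended: yellow visits are 1.49 times and red visits
2.25 times as likely as green visits to be followed by an IIT (held-out
AUC 0.568 under the generator's default moderate covariate effects).
The behavioral archetypes tell the same story from simple rules:

```r
aa <- assign_archetypes(labeled, cohort$clients)
t6 <- archetype_table(aa, reference = "prompt_and_loyal",
                      archetypes = c("late_twice", "returning_after_disengagement"))
render_archetype_table(t6)
```

```
  archetype                     visits iit       rr_95ci
1 prompt_and_loyal                5590 606 (11%) Ref
2 late_twice                       1249 160 (13%) 1.18 (1.00-1.39)
3 returning_after_disengagement   3429 505 (15%) 1.36 (1.22-1.52)
```

`run_pipeline(pipeline_config(...))` chains all of the above from a single
seeded configuration and writes `labeled.csv`, `features.csv`,
`metrics.json`, triage and archetype tables, and a `run_log.yaml` recording
every decision parameter; re-running the same configuration reproduces the
artifacts byte for byte.

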