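# Fixture builders and memoised synthetic cohorts shared across tests.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# one client record with overridable fields
make_client <- function(client_id = "C00001", ...) {
  defaults <- tibble::tibble(
    client_id = client_id, sex = "F",
    birth_date = as.Date("1985-06-15"), employment = "employed",
    payday_day_of_month = 28L, household_size_others = 2L,
    travel_time_min = 25, disclosed_status = TRUE, has_hiv_info = TRUE,
    planned_to_test_today = TRUE, prepared_to_start_today = TRUE,
    prior_hiv_test_history = TRUE, year_first_tested_positive = 2018L,
    cd4_screening = 350, phone_number_on_file = TRUE,
    attends_other_facilities = FALSE, art_start_date = as.Date("2019-01-01")
  )
  overrides <- list(...)
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  defaults
}

# visit stream for one client from a days_late vector (NA = never attended)
make_visits <- function(client_id = "C00001", days_late = c(0, 0, 0),
                        start = as.Date("2019-02-01"), gap = 28) {
  scheduled <- start + gap * (seq_along(days_late) - 1)
  tibble::tibble(
    client_id = client_id, facility_id = "F001",
    scheduled_date = scheduled,
    attended_date = scheduled + days_late,
    regimen_code = "TLD", vl_value = NA_real_, vl_date = as.Date(NA),
    tb_symptom_count = 0L
  )
}

label_and_pair <- function(visits, clients, censor = NULL) {
  censor <- censor %||% max(visits$scheduled_date) + 365
  lab <- label_visits(visits, censor)
  lab <- time_on_art_stratum(lab, clients)
  pair_next_visit(lab)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# default-condition cohort, medium size
default_cohort <- function() {
  cache_get("default_cohort", function() {
    co <- generate_cohort(generator_config(n_clients = 400, seed = 2024))
    lab <- label_and_pair(co$visits, co$clients,
                          censor = max(co$visits$scheduled_date))
    fv <- build_features(lab, co$clients)
    list(cohort = co, labeled = lab, features = fv)
  })
}

# strong-covariate-signal cohort used for discrimination/recovery checks
signal_cohort <- function() {
  cache_get("signal_cohort", function() {
    cfg <- generator_config(
      n_clients = 600,
      covariate_effects = c(age_lt_25 = 1.2, male = 0.6,
                            attends_other_facilities = 1.0,
                            lives_alone = 0.8, travel_gt_20 = 0.6),
      client_noise_sd = 0.9, seed = 31
    )
    co <- generate_cohort(cfg)
    lab <- label_and_pair(co$visits, co$clients,
                          censor = max(co$visits$scheduled_date))
    fv <- build_features(lab, co$clients)
    fv <- fv[!is.na(fv$iit_next_visit), ]
    mc <- model_config(n_estimators = 100, seed = 7)
    parts <- split_train_test(fv, mc)
    scorer <- train_classifier(rebalance(parts$train, "downsample", 7), mc)
    list(cohort = co, labeled = lab, features = fv, parts = parts,
         scorer = scorer, metrics = evaluate(scorer, parts$test),
         scores = score_visits(scorer, fv))
  })
}

# scorer that reproduces a fixed 0/1 prediction from a single feature
prediction_scorer <- function() {
  cache_get("prediction_scorer", function() {
    train <- tibble::tibble(
      client_id = sprintf("T%03d", 1:40),
      f = rep(c(0, 1), each = 20),
      iit_next_visit = rep(c(FALSE, TRUE), each = 20)
    )
    train_classifier(train, model_config(n_estimators = 5, seed = 1))
  })
}
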