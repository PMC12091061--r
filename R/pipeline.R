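# End-to-end orchestration: simulate/ingest -> label -> featurize -> train
# -> score -> triage -> archetypes, with reproducible artifacts.

#' Pipeline configuration
#'
#' Bundles every stage's parameters. A single pipeline seed fans out into
#' named per-stage substreams, so changing the model seed does not change
#' the simulated cohort.
#'
#' @param generator A [generator_config()], or `NULL` when reading an
#'   existing cohort from `input_dir`.
#' @param input_dir Directory with `clients.csv`/`visits.csv` (ignored when
#'   `generator` is given).
#' @param censor_date Database censor date; default: the latest scheduled
#'   date in the data.
#' @param model A [model_config()].
#' @param cut_percentiles Triage cut percentiles, default `c(0.5, 0.9)`.
#' @param calibrate_doubling Re-derive the cutoffs from the doubling
#'   criterion instead of using `cut_percentiles` directly.
#' @param emr_only Additionally train and evaluate a model restricted to
#'   EMR-available variables (restricted-variable comparison).
#' @param archetype_references Named references per category.
#' @param discover_min_size Minimum segment size for archetype discovery.
#' @param restrict_months Month restriction for the combined
#'   demographic-by-behavior table (default 6).
#' @param out_dir Output directory.
#' @param seed Integer master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = NULL, input_dir = NULL,
                            censor_date = NULL,
                            model = model_config(),
                            cut_percentiles = c(0.5, 0.9),
                            calibrate_doubling = FALSE,
                            emr_only = FALSE,
                            archetype_references = c(
                              demographic = "adult_female",
                              behavioral = "prompt_and_loyal",
                              socio_behavioral = "super_green"
                            ),
                            discover_min_size = 50,
                            restrict_months = 6,
                            out_dir = tempfile("iitriage_run_"),
                            seed = 1L) {
  if (is.null(generator) && is.null(input_dir)) {
    stop("either a generator config or an input_dir is required",
         call. = FALSE)
  }
  if (!is.null(input_dir) && is.null(generator) && !dir.exists(input_dir)) {
    stop("input_dir does not exist: ", input_dir, call. = FALSE)
  }
  seed <- as.integer(seed)
  # named per-stage substreams derived from the master seed
  substreams <- list(
    generator = seed,
    model = as.integer((seed + 104729) %% 2147483647),
    rebalance = as.integer((seed + 224737) %% 2147483647)
  )
  if (!is.null(generator)) generator$seed <- substreams$generator
  model$seed <- substreams$model
  structure(
    list(generator = generator, input_dir = input_dir,
         censor_date = censor_date, model = model,
         cut_percentiles = cut_percentiles,
         calibrate_doubling = calibrate_doubling, emr_only = emr_only,
         archetype_references = archetype_references,
         discover_min_size = discover_min_size,
         restrict_months = restrict_months,
         out_dir = out_dir, seed = seed, substreams = substreams),
    class = "pipeline_config"
  )
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(serializable_config(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

serializable_config <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  cfg$generator <- if (!is.null(cfg$generator)) unclass(cfg$generator)
  cfg$model <- unclass(cfg$model)
  cfg
}

#' Run the full triaging pipeline
#'
#' Executes, in order: simulate or ingest the cohort; label outcomes; assign
#' time-on-ART strata; pair next-visit outcomes; build features; split,
#' rebalance and train the classifier; score all eligible visits with an
#' observed next visit; triage by score percentile; build the archetype
#' tables. Writes `clients.csv`, `visits.csv`, `labeled.csv`,
#' `features.csv`, `scores.csv`, `metrics.json`, `table4.csv`,
#' `table6.csv`, `table7.csv`, `config.json` and `run_log.yaml` into the
#' output directory. Re-running with an identical configuration reproduces
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `labeled`, `features`, `scorer`, `metrics`, `scores`, `bins`,
#'   `triage`, `assignments`, `table6`, `table7`, `cut_percentiles`,
#'   `out_dir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate/ingest"
  res <- tryCatch({
    cohort <- if (!is.null(config$generator)) {
      generate_cohort(config$generator)
    } else {
      read_cohort(config$input_dir)
    }
    write_cohort(cohort$clients, cohort$visits, out_dir)

    stage <- "label"
    censor <- config$censor_date %||% max(cohort$visits$scheduled_date)
    labeled <- label_visits(cohort$visits, censor)
    labeled <- time_on_art_stratum(labeled, cohort$clients)
    labeled <- pair_next_visit(labeled)
    write_table_csv(labeled, file.path(out_dir, "labeled.csv"))

    stage <- "featurize"
    fv <- build_features(labeled, cohort$clients)
    write_table_csv(fv, file.path(out_dir, "features.csv"))

    stage <- "train"
    scorable <- fv[!is.na(fv$iit_next_visit), ]
    parts <- split_train_test(scorable, config$model)
    train <- rebalance(parts$train, config$model$rebalance,
                       seed = config$substreams$rebalance)
    scorer <- train_classifier(train, config$model)
    metrics <- evaluate(scorer, parts$test)
    metrics_out <- list(full_model = unclass(metrics))
    if (isTRUE(config$emr_only)) {
      emr_parts <- lapply(parts, restrict_to_emr_features)
      emr_train <- rebalance(emr_parts$train, config$model$rebalance,
                             seed = config$substreams$rebalance)
      emr_scorer <- train_classifier(emr_train, config$model)
      metrics_out$emr_restricted_model <-
        unclass(evaluate(emr_scorer, emr_parts$test))
    }
    jsonlite::write_json(metrics_out, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    stage <- "score"
    scores <- score_visits(scorer, scorable)
    score_df <- tibble::tibble(
      client_id = scorable$client_id,
      scheduled_date = scorable$scheduled_date,
      score = scores
    )
    write_table_csv(score_df, file.path(out_dir, "scores.csv"))

    stage <- "triage"
    cuts <- if (isTRUE(config$calibrate_doubling)) {
      calibrate_doubling_cutoffs(scores, scorable$iit_next_visit)
    } else {
      config$cut_percentiles
    }
    bins <- assign_bins(scores, cuts)
    triage <- triage_table(bins, scorable)
    write_table_csv(render_triage_table(triage),
                    file.path(out_dir, "table4.csv"))

    stage <- "archetypes"
    assignments <- assign_archetypes(labeled, cohort$clients)
    refs <- config$archetype_references
    rules <- attr(assignments, "rules")
    by_cat <- split(names(rules),
                    vapply(rules, `[[`, character(1), "category"))
    t6 <- dplyr::bind_rows(lapply(names(refs), function(cat) {
      dplyr::mutate(
        archetype_table(assignments, reference = refs[[cat]],
                        archetypes = setdiff(by_cat[[cat]], refs[[cat]])),
        category = cat, .before = 1
      )
    }))
    write_table_csv(render_archetype_table(t6),
                    file.path(out_dir, "table6.csv"))
    t7 <- archetype_table(assignments,
                          reference = refs[["demographic"]],
                          restrict_months = config$restrict_months,
                          cross_demographic = TRUE)
    write_table_csv(render_archetype_table(t7),
                    file.path(out_dir, "table7.csv"))

    list(cohort = cohort, labeled = labeled, features = fv, scorer = scorer,
         metrics = metrics_out, scores = scores, bins = bins,
         triage = triage, assignments = assignments, table6 = t6,
         table7 = t7, cut_percentiles = cuts, out_dir = out_dir)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  hash <- config_hash(config)
  writeLines(jsonlite::toJSON(serializable_config(config), auto_unbox = TRUE,
                              digits = NA, pretty = TRUE, null = "null"),
             file.path(out_dir, "config.json"))
  run_log <- list(
    config_hash = as.character(hash),
    seed = config$seed,
    substreams = config$substreams,
    decision_parameters = list(
      iit_boundary_days = 28L, iit_boundary = "inclusive (28 d late retained)",
      early_attendance = "counts as on time",
      censor_window_months = 3L,
      lateness_feature_days = 3L,
      month_convention = "calendar months; strata [0,6] and (6,12]",
      triage_cut_percentiles = res$cut_percentiles,
      triage_tie_rule = "ties at a cutpoint go to the lower-risk bin",
      classification_threshold = 0.5,
      adult_age_boundary = 25,
      distance_boundary_min = 20,
      lives_alone_max_household = 1,
      payday_window_days = 7,
      discover_min_size = config$discover_min_size,
      restrict_months = config$restrict_months
    )
  )
  yaml::write_yaml(run_log, file.path(out_dir, "run_log.yaml"))
  invisible(res)
}

write_table_csv <- function(df, path) {
  df <- as.data.frame(df)
  for (nm in names(df)) {
    if (inherits(df[[nm]], "Date")) df[[nm]] <- format(df[[nm]], "%Y-%m-%d")
    if (is.factor(df[[nm]])) df[[nm]] <- as.character(df[[nm]])
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
}

#' Render the triage table for presentation
#'
#' Fixed column order; rates as whole percentages; RR cells as
#' `"2.17 (2.14-2.19)"`, with `"Ref"` for the green reference row and
#' `"N/A"` for undefined cells. Rounding is half-up at two decimals and
#' happens only here.
#'
#' @param triage Output of [triage_table()].
#' @return A tibble with `stratum`, `bin`, `visits`, `iit`, `rr_95ci`.
#' @export
render_triage_table <- function(triage) {
  tibble::tibble(
    stratum = triage$stratum,
    bin = as.character(triage$bin),
    visits = triage$n_visits,
    iit = ifelse(
      is.na(triage$iit_rate), "N/A",
      sprintf("%d%% (n=%d)", round_half_up(100 * triage$iit_rate, 0),
              triage$n_iit_next)
    ),
    rr_95ci = mapply(function(bin, rr, lo, hi, n) {
      if (bin == "all") return("")
      if (bin == "green") return("Ref")
      if (is.na(rr) || n == 0) return("N/A")
      format_rr(list(rr = rr, ci_low = lo, ci_high = hi))
    }, triage$bin, triage$rr, triage$ci_low, triage$ci_high,
    triage$n_visits, USE.NAMES = FALSE)
  )
}

#' Render an archetype table for presentation
#'
#' @param tab Output of [archetype_table()] (optionally with a `category`
#'   column).
#' @return A tibble with formatted visit counts, IIT cells and RR cells
#'   (reference row rendered `"Ref"`).
#' @export
render_archetype_table <- function(tab) {
  out <- tibble::tibble(
    archetype = tab$archetype,
    visits = tab$n_visits,
    iit = ifelse(
      is.na(tab$iit_rate), "N/A",
      sprintf("%d (%d%%)", tab$n_iit, round_half_up(100 * tab$iit_rate, 0))
    ),
    rr_95ci = mapply(function(rr, lo, hi, n) {
      if (is.na(rr) && n > 0) return("Ref")
      if (n == 0) return("N/A")
      format_rr(list(rr = rr, ci_low = lo, ci_high = hi))
    }, tab$rr, tab$ci_low, tab$ci_high, tab$n_visits, USE.NAMES = FALSE)
  )
  if ("category" %in% names(tab)) {
    out <- dplyr::mutate(out, category = tab$category, .before = 1)
  }
  out
}

round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}
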