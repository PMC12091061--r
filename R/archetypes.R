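# Archetype approach: rule-based client segmentation into demographic,
# behavioral and socio-behavioral profiles, plus enumerative archetype
# discovery over key-variable configurations.

new_archetype_rule <- function(name, category, data_requirement,
                               evaluation_time, requires, predicate) {
  structure(
    list(name = name, category = category,
         data_requirement = data_requirement,
         evaluation_time = evaluation_time,
         requires = requires, predicate = predicate),
    class = "archetype_rule"
  )
}

#' Built-in archetype rules
#'
#' The sixteen rule-based client profiles: four demographic (mutually
#' exclusive age/sex strata), four behavioral (visit-attendance patterns),
#' and eight socio-behavioral (survey-derived characteristics combined with
#' attendance). Operationalizations:
#' "attended on time"/"regularly prompt" means attended no more than 3 days
#' after schedule (prompt requires at least two prior visits, all prompt);
#' "regularly late" means at least two prior visits attended more than 3
#' days late; "lives alone" means no other household members; distances at
#' exactly 20 minutes match neither the near nor the far condition; age 25
#' exactly is adult; payday proximity is circular day-of-month distance
#' strictly under 7 days.
#'
#' @return A named list of `archetype_rule` objects: 4 demographic,
#'   4 behavioral, 8 socio-behavioral.
#' @export
builtin_rules <- function() {
  rules <- list(
    new_archetype_rule(
      "adult_female", "demographic", "emr_only", "each_visit",
      c("sex", "age_at_visit"),
      function(ctx) ctx$sex == "F" & ctx$age_at_visit >= 25
    ),
    new_archetype_rule(
      "adult_male", "demographic", "emr_only", "each_visit",
      c("sex", "age_at_visit"),
      function(ctx) ctx$sex == "M" & ctx$age_at_visit >= 25
    ),
    new_archetype_rule(
      "agyw", "demographic", "emr_only", "each_visit",
      c("sex", "age_at_visit"),
      function(ctx) ctx$sex == "F" & ctx$age_at_visit >= 15 & ctx$age_at_visit < 25
    ),
    new_archetype_rule(
      "abym", "demographic", "emr_only", "each_visit",
      c("sex", "age_at_visit"),
      function(ctx) ctx$sex == "M" & ctx$age_at_visit >= 15 & ctx$age_at_visit < 25
    ),
    new_archetype_rule(
      "prompt_and_loyal", "behavioral", "emr_only", "each_visit",
      c("days_late", "attends_other_facilities"),
      function(ctx) !is.na(ctx$days_late) & ctx$days_late <= 3 &
        !ctx$attends_other_facilities
    ),
    new_archetype_rule(
      "late_twice", "behavioral", "emr_only", "each_visit",
      c("prev1_days_late", "prev2_days_late"),
      function(ctx) !is.na(ctx$prev1_days_late) & ctx$prev1_days_late >= 1 &
        !is.na(ctx$prev2_days_late) & ctx$prev2_days_late >= 1
    ),
    new_archetype_rule(
      "shopper_no_number", "behavioral", "emr_only", "each_visit",
      c("attends_other_facilities", "phone_number_on_file"),
      function(ctx) ctx$attends_other_facilities & !ctx$phone_number_on_file
    ),
    new_archetype_rule(
      "returning_after_disengagement", "behavioral", "emr_only", "each_visit",
      c("any_prior_iit"),
      function(ctx) ctx$any_prior_iit
    ),
    new_archetype_rule(
      "super_green", "socio_behavioral", "survey_required", "each_visit",
      c("regularly_prompt", "household_size_others"),
      function(ctx) ctx$regularly_prompt & ctx$household_size_others > 0
    ),
    new_archetype_rule(
      "employed_youth_at_payday", "socio_behavioral", "survey_required",
      "each_visit",
      c("age_at_visit", "employment", "payday_distance"),
      function(ctx) ctx$age_at_visit >= 18 & ctx$age_at_visit <= 29 &
        ctx$employment == "employed" & ctx$payday_distance < 7
    ),
    new_archetype_rule(
      "prior_test_and_prompt", "socio_behavioral", "emr_only", "each_visit",
      c("prior_hiv_test_history", "regularly_prompt"),
      function(ctx) ctx$prior_hiv_test_history & ctx$regularly_prompt
    ),
    new_archetype_rule(
      "lone_ranger", "socio_behavioral", "survey_required", "at_initiation",
      c("household_size_others", "travel_time_min"),
      function(ctx) ctx$household_size_others <= 1 & ctx$travel_time_min > 20
    ),
    new_archetype_rule(
      "unexpected_and_unsupported", "socio_behavioral", "survey_required",
      "at_initiation",
      c("planned_to_test_today", "household_size_others"),
      function(ctx) !ctx$planned_to_test_today & ctx$household_size_others <= 1
    ),
    new_archetype_rule(
      "disillusioned_disclosers", "socio_behavioral", "survey_required",
      "at_initiation",
      c("has_hiv_info", "disclosed_status", "household_size_others"),
      function(ctx) ctx$has_hiv_info & ctx$disclosed_status &
        ctx$household_size_others <= 1
    ),
    new_archetype_rule(
      "live_close_always_late", "socio_behavioral", "survey_required",
      "each_visit",
      c("travel_time_min", "regularly_late"),
      function(ctx) ctx$travel_time_min < 20 & ctx$regularly_late
    ),
    new_archetype_rule(
      "prepared_and_late", "socio_behavioral", "survey_required", "each_visit",
      c("prepared_to_start_today", "prior_hiv_test_history", "regularly_late"),
      function(ctx) ctx$prepared_to_start_today & ctx$prior_hiv_test_history &
        ctx$regularly_late
    )
  )
  stats::setNames(rules, vapply(rules, `[[`, character(1), "name"))
}

# circular day-of-month distance between the next appointment and payday
payday_distance <- function(next_date, payday_dom) {
  dom <- as.integer(format(next_date, "%d"))
  d <- abs(dom - payday_dom)
  pmin(d, 31 - d)
}

# per-visit evaluation context for the archetype predicates
archetype_context <- function(labeled, clients) {
  labeled <- dplyr::arrange(labeled, .data$client_id, .data$scheduled_date)
  cl <- clients[match(labeled$client_id, clients$client_id), ]
  if (anyNA(cl$client_id)) {
    stop("linkage error: visit client_id missing from clients", call. = FALSE)
  }
  ctx <- labeled |>
    dplyr::group_by(.data$client_id) |>
    dplyr::mutate(
      prev1_days_late = dplyr::lag(.data$days_late, 1),
      prev2_days_late = dplyr::lag(.data$days_late, 2),
      n_prior = dplyr::row_number() - 1L,
      any_prior_iit = dplyr::lag(cumsum(.data$iit_this_visit), default = 0L) > 0L,
      .prior_prompt = dplyr::lag(
        cumsum(!is.na(.data$days_late) & .data$days_late <= 3), default = 0L),
      .prior_late3 = dplyr::lag(
        cumsum(!is.na(.data$days_late) & .data$days_late > 3), default = 0L),
      regularly_prompt = .data$n_prior >= 2 & .data$.prior_prompt == .data$n_prior,
      regularly_late = .data$.prior_late3 >= 2
    ) |>
    dplyr::ungroup()
  ctx$sex <- cl$sex
  ctx$age_at_visit <- as.numeric(ctx$scheduled_date - cl$birth_date) / 365.25
  for (nm in c("employment", "household_size_others", "travel_time_min",
               "planned_to_test_today", "has_hiv_info", "disclosed_status",
               "prepared_to_start_today", "prior_hiv_test_history",
               "phone_number_on_file", "attends_other_facilities")) {
    ctx[[nm]] <- cl[[nm]]
  }
  ctx$payday_distance <- ifelse(
    is.na(ctx$next_scheduled_date) | is.na(cl$payday_day_of_month),
    NA_real_,
    payday_distance(ctx$next_scheduled_date, cl$payday_day_of_month)
  )
  ctx
}

#' Assign archetypes to visits
#'
#' Evaluates each rule against every visit. Every visit with age at least 15
#' receives exactly one demographic archetype; behavioral and
#' socio-behavioral archetypes may overlap freely. A rule whose required
#' fields are absent for a visit skips that visit (not matched); the number
#' of skips per rule is reported via a message, and a rule whose required
#' field is missing for every client raises a configuration warning.
#'
#' @param labeled Labeled, paired visits ([label_visits()] +
#'   [pair_next_visit()]; `time_on_art_months` is carried through when
#'   present).
#' @param clients Clients tibble.
#' @param rules List of rules, default [builtin_rules()].
#' @return A tibble with identifier columns, `iit_next_visit`, a
#'   `demographic` column naming the matched demographic archetype, and one
#'   logical column per archetype.
#' @export
assign_archetypes <- function(labeled, clients, rules = builtin_rules()) {
  ctx <- archetype_context(labeled, clients)
  out <- ctx[intersect(c("client_id", "scheduled_date", "iit_next_visit",
                         "time_on_art_months", "eligible"), names(ctx))]
  demo_names <- character(0)
  skip_msgs <- character(0)
  for (rule in rules) {
    missing_req <- setdiff(rule$requires, names(ctx))
    if (length(missing_req) > 0) {
      warning("rule '", rule$name, "' references field(s) absent from the ",
              "data: ", paste(missing_req, collapse = ", "), call. = FALSE)
      out[[rule$name]] <- rep(FALSE, nrow(ctx))
      next
    }
    # a client-level survey field absent wholesale is a configuration
    # problem; derived history fields (previous lateness, payday distance)
    # are legitimately absent for boundary visits
    client_fields <- intersect(rule$requires, c(
      "sex", "employment", "household_size_others", "travel_time_min",
      "planned_to_test_today", "has_hiv_info", "disclosed_status",
      "prepared_to_start_today", "prior_hiv_test_history",
      "phone_number_on_file", "attends_other_facilities"
    ))
    all_na <- vapply(client_fields, function(f) all(is.na(ctx[[f]])),
                     logical(1))
    if (any(all_na)) {
      warning("rule '", rule$name, "' requires field(s) missing for all ",
              "clients: ", paste(client_fields[all_na], collapse = ", "),
              call. = FALSE)
    }
    m <- rule$predicate(ctx)
    n_skip <- sum(is.na(m))
    if (n_skip > 0) {
      skip_msgs <- c(skip_msgs, sprintf("%s: %d visit(s) skipped (missing fields)",
                                        rule$name, n_skip))
    }
    out[[rule$name]] <- !is.na(m) & m
    if (rule$category == "demographic") demo_names <- c(demo_names, rule$name)
  }
  if (length(skip_msgs) > 0) {
    message("archetype rules skipped visits with missing survey fields:\n  ",
            paste(skip_msgs, collapse = "\n  "))
  }
  if (length(demo_names) > 0) {
    demo_mat <- as.matrix(out[demo_names])
    n_demo <- rowSums(demo_mat)
    if (any(n_demo > 1)) {
      stop("demographic archetypes must be mutually exclusive", call. = FALSE)
    }
    out$demographic <- ifelse(
      n_demo == 0, NA_character_,
      demo_names[max.col(demo_mat, ties.method = "first")]
    )
  }
  attr(out, "rules") <- rules
  out
}

#' Archetype IIT table with relative risks
#'
#' One row per archetype: visits matched, IIT-at-next-visit events, rate,
#' and crude RR with 95% CI versus the reference archetype (conventionally
#' adult females for demographic rows, prompt-and-loyal for behavioral,
#' super-green for socio-behavioral). With `cross_demographic = TRUE`, rows
#' are demographic x (behavioral + socio-behavioral) combinations against a
#' single demographic reference. `restrict_months` keeps only visits within
#' that many months on ART (the combined tables restrict to the first 6
#' months).
#'
#' @param assignments Output of [assign_archetypes()].
#' @param reference Name of the reference archetype (non-empty in the data).
#' @param archetypes Archetype columns to tabulate; default all non-reference
#'   archetype columns.
#' @param restrict_months Optional upper bound on `time_on_art_months`.
#' @param cross_demographic Tabulate demographic x behavioral combinations.
#' @return A tibble with `archetype`, `n_visits`, `n_iit`, `iit_rate`, `rr`,
#'   `ci_low`, `ci_high` (reference row first, `NA` RR).
#' @export
archetype_table <- function(assignments, reference,
                            archetypes = NULL, restrict_months = NULL,
                            cross_demographic = FALSE) {
  df <- assignments[!is.na(assignments$iit_next_visit), ]
  if (!is.null(restrict_months)) {
    if (!"time_on_art_months" %in% names(df)) {
      stop("restrict_months requires time_on_art_months (run ",
           "time_on_art_stratum first)", call. = FALSE)
    }
    df <- df[df$time_on_art_months <= restrict_months, ]
  }
  rules <- attr(assignments, "rules")
  arch_cols <- intersect(names(rules %||% list()), names(df))
  if (length(arch_cols) == 0) {
    arch_cols <- setdiff(names(df)[vapply(df, is.logical, logical(1))],
                         "iit_next_visit")
  }
  if (cross_demographic) {
    demo_cols <- arch_cols[vapply(rules[arch_cols], function(r)
      r$category == "demographic", logical(1))]
    other_cols <- setdiff(arch_cols, demo_cols)
    combos <- expand.grid(demo = demo_cols, arch = other_cols,
                          stringsAsFactors = FALSE)
    mask_of <- function(i) df[[combos$demo[i]]] & df[[combos$arch[i]]]
    names_of <- function(i) paste(combos$demo[i], combos$arch[i], sep = ":")
    idx <- seq_len(nrow(combos))
  } else {
    arch_use <- archetypes %||% setdiff(arch_cols, reference)
    mask_of <- function(i) df[[arch_use[i]]]
    names_of <- function(i) arch_use[i]
    idx <- seq_along(arch_use)
  }
  ref_mask <- if (reference %in% names(df)) df[[reference]] else {
    stop("reference archetype '", reference, "' not found", call. = FALSE)
  }
  n_ref <- sum(ref_mask)
  if (n_ref == 0) stop("reference archetype is empty", call. = FALSE)
  e_ref <- sum(df$iit_next_visit[ref_mask])
  rows <- list(tibble::tibble(
    archetype = reference, n_visits = n_ref, n_iit = e_ref,
    iit_rate = e_ref / n_ref, rr = NA_real_, ci_low = NA_real_,
    ci_high = NA_real_
  ))
  for (i in idx) {
    m <- mask_of(i)
    n <- sum(m)
    e <- sum(df$iit_next_visit[m])
    rr <- lo <- hi <- NA_real_
    if (n > 0 && e_ref > 0) {
      est <- crude_rr(two_by_two(e, n, e_ref, n_ref))
      rr <- est$rr; lo <- est$ci_low; hi <- est$ci_high
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      archetype = names_of(i), n_visits = n, n_iit = e,
      iit_rate = if (n > 0) e / n else NA_real_,
      rr = rr, ci_low = lo, ci_high = hi
    )
  }
  dplyr::bind_rows(rows)
}

#' Enumerative archetype discovery
#'
#' Systematically explores all value configurations of key-variable pairs
#' (or higher-order tuples), computing each segment's IIT rate and its
#' difference from the whole-population baseline rate. Segments smaller
#' than `min_size` are dropped; configurations with zero support (including
#' logically contradictory condition sets) are removed. Results are sorted
#' by absolute rate difference, descending.
#'
#' @param features Tibble of discretized key variables (logical, factor,
#'   character, or integers with at most 10 distinct values) plus any
#'   identifier columns (ignored).
#' @param iit_next_labels Logical outcomes aligned with `features` rows.
#' @param key_variables Character vector of variable names to combine.
#' @param min_size Minimum segment size (default 50 visits).
#' @param order Tuple order (default 2: variable pairs).
#' @return A tibble `variables`, `values`, `n_visits`, `n_iit`, `iit_rate`,
#'   `delta_vs_baseline`, with attribute `n_configs_evaluated` (the count
#'   of configurations enumerated before pruning).
#' @export
discover_archetypes <- function(features, iit_next_labels, key_variables,
                                min_size = 50, order = 2) {
  if (length(key_variables) == 0) stop("no key variables supplied", call. = FALSE)
  missing_v <- setdiff(key_variables, names(features))
  if (length(missing_v) > 0) {
    stop("variable(s) not in features: ", paste(missing_v, collapse = ", "),
         call. = FALSE)
  }
  if (length(key_variables) < order) {
    stop("need at least `order` key variables", call. = FALSE)
  }
  keep <- !is.na(iit_next_labels)
  df <- features[keep, key_variables, drop = FALSE]
  y <- iit_next_labels[keep]
  for (v in key_variables) {
    lv <- unique(stats::na.omit(df[[v]]))
    if (length(lv) > 10) {
      stop("variable '", v, "' has more than 10 levels; discretize first",
           call. = FALSE)
    }
    df[[v]] <- as.character(df[[v]])
  }
  baseline <- mean(y)
  combos <- utils::combn(key_variables, order, simplify = FALSE)
  rows <- list()
  n_eval <- 0L
  for (vars in combos) {
    level_sets <- lapply(vars, function(v) sort(unique(stats::na.omit(df[[v]]))))
    grid <- expand.grid(level_sets, stringsAsFactors = FALSE)
    names(grid) <- vars
    for (g in seq_len(nrow(grid))) {
      n_eval <- n_eval + 1L
      m <- rep(TRUE, nrow(df))
      for (v in vars) m <- m & !is.na(df[[v]]) & df[[v]] == grid[[v]][g]
      n <- sum(m)
      if (n == 0 || n < min_size) next
      e <- sum(y[m])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variables = paste(vars, collapse = " & "),
        values = paste(paste0(vars, "=", unlist(grid[g, ])), collapse = " & "),
        n_visits = n, n_iit = e, iit_rate = e / n,
        delta_vs_baseline = e / n - baseline
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) {
    out <- out[base::order(-abs(out$delta_vs_baseline)), ]
  }
  attr(out, "n_configs_evaluated") <- n_eval
  attr(out, "baseline_rate") <- baseline
  out
}
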