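# Per-visit predictor features: visit-history summaries, calendar features,
# labs and survey covariates, using only information available at or before
# the visit being scored.

# columns of a feature frame that are identifiers/labels, not predictors
feature_id_cols <- function() {
  c("client_id", "scheduled_date", "next_scheduled_date", "iit_next_visit",
    "art_stratum", "is_first_visit_after_initiation", "eligible")
}

# the variable set available from routine EMR data alone (no baseline survey)
emr_feature_names <- function() {
  c("pct_visits_gt3d_late", "n_times_gt28d_late", "n_visits_this_facility",
    "n_vl_tests", "months_since_first_visit", "months_since_last_visit",
    "current_age", "day_of_month_next_appt", "day_of_week_next_appt",
    "last_vl_value", "sex", "n_missed_months", "visits_on_regimen",
    "time_on_art", "appointment_month", "months_since_last_vl")
}

survey_feature_names <- function() {
  c("cd4_screening", "travel_time_min", "tb_symptom_count",
    "year_first_tested_positive", "household_size_others")
}

#' Build per-visit predictor features
#'
#' Computes, for each eligible visit, the predictor variables of the risk
#' model. History features use strictly prior visits plus the current visit's
#' own lateness; nothing dated after the current visit enters (no leakage).
#' A never-attended visit counts as both `>3 days late` and `>28 days late`
#' in the history summaries. Lab features use the most recent viral load
#' whose result date is on or before the current scheduled date. Fractional
#' months are days/30.4375.
#'
#' @param labeled Labeled, paired visits: output of [label_visits()] then
#'   [pair_next_visit()] (and optionally [time_on_art_stratum()], whose
#'   columns are carried through).
#' @param clients Clients tibble; every visit's `client_id` must be present.
#' @return A tibble with one row per eligible visit: identifier columns
#'   (`client_id`, `scheduled_date`, `next_scheduled_date`,
#'   `iit_next_visit`, and stratum columns when present) plus the feature
#'   columns. `day_of_week_next_appt` is ISO (Monday = 1).
#' @export
build_features <- function(labeled, clients) {
  missing_cl <- setdiff(unique(labeled$client_id), clients$client_id)
  if (length(missing_cl) > 0) {
    stop("linkage error: client(s) in visits but not in clients: ",
         paste(utils::head(missing_cl, 3), collapse = ", "), call. = FALSE)
  }
  needed <- c("days_late", "iit_this_visit", "next_scheduled_date")
  if (!all(needed %in% names(labeled))) {
    stop("labeled visits must come from label_visits() + pair_next_visit()",
         call. = FALSE)
  }
  labeled <- dplyr::arrange(labeled, .data$client_id, .data$scheduled_date)
  cl <- clients[match(labeled$client_id, clients$client_id), ]
  feats <- labeled |>
    dplyr::group_by(.data$client_id) |>
    dplyr::mutate(
      .late3 = is.na(.data$days_late) | .data$days_late > 3L,
      .late28 = .data$iit_this_visit,
      pct_visits_gt3d_late = cumsum(.data$.late3) / dplyr::row_number(),
      n_times_gt28d_late = cumsum(.data$.late28),
      n_visits_this_facility = dplyr::row_number(),
      months_since_first_visit =
        as.numeric(.data$scheduled_date - dplyr::first(.data$scheduled_date)) /
          30.4375,
      .prev_attended = dplyr::lag(cummax_date(.data$attended_date)),
      months_since_last_visit =
        as.numeric(.data$scheduled_date - .data$.prev_attended) / 30.4375,
      .run_id = cumsum(.data$regimen_code !=
                         dplyr::lag(.data$regimen_code,
                                    default = dplyr::first(.data$regimen_code))),
      n_missed_months = missed_months_to_date(.data$scheduled_date,
                                              .data$attended_date)
    ) |>
    dplyr::group_by(.data$client_id, .data$.run_id) |>
    dplyr::mutate(visits_on_regimen = dplyr::row_number()) |>
    dplyr::ungroup()

  # most recent viral load available at the current scheduled date
  vl <- vl_history_features(feats)
  feats$last_vl_value <- vl$last_vl_value
  feats$months_since_last_vl <- vl$months_since_last_vl
  feats$n_vl_tests <- vl$n_vl_tests

  out <- feats |>
    dplyr::mutate(
      current_age = as.numeric(.data$scheduled_date - cl$birth_date) / 365.25,
      time_on_art = as.numeric(.data$scheduled_date - cl$art_start_date) /
        30.4375,
      appointment_month = as.integer(format(.data$scheduled_date, "%m")),
      day_of_month_next_appt = ifelse(
        is.na(.data$next_scheduled_date), NA_integer_,
        as.integer(format(.data$next_scheduled_date, "%d"))
      ),
      day_of_week_next_appt = as.integer(ifelse(
        is.na(.data$next_scheduled_date), NA_integer_,
        lubridate::wday(.data$next_scheduled_date, week_start = 1)
      )),
      sex = cl$sex,
      cd4_screening = cl$cd4_screening,
      travel_time_min = cl$travel_time_min,
      household_size_others = cl$household_size_others,
      year_first_tested_positive = cl$year_first_tested_positive,
      tb_symptom_count = .data$tb_symptom_count
    )
  keep <- intersect(
    c(feature_id_cols(), emr_feature_names(), survey_feature_names()),
    names(out)
  )
  res <- out[keep]
  if ("eligible" %in% names(labeled)) {
    res <- res[labeled_order_eligible(out), ]
  }
  res
}

# rows of the (grouped-then-ungrouped) frame that are eligible
labeled_order_eligible <- function(out) {
  if ("eligible" %in% names(out)) which(out$eligible) else seq_len(nrow(out))
}

# running maximum of a Date vector, propagating over NAs (never-attended)
cummax_date <- function(d) {
  x <- as.numeric(d)
  x[is.na(x)] <- -Inf
  m <- cummax(x)
  m[is.infinite(m)] <- NA
  as.Date(m, origin = "1970-01-01")
}

# per-visit count of calendar months between the first and current visit
# containing no attended visit (information up to the current visit only)
missed_months_to_date <- function(scheduled, attended) {
  mi <- function(d) as.integer(format(d, "%Y")) * 12L + as.integer(format(d, "%m"))
  m_sched <- mi(scheduled)
  m_att <- ifelse(is.na(attended), NA_integer_, mi(attended))
  vapply(seq_along(scheduled), function(t) {
    span <- seq(m_sched[1], m_sched[t])
    seen <- m_att[seq_len(t)]
    sum(!span %in% seen[!is.na(seen)])
  }, integer(1))
}

vl_history_features <- function(feats) {
  n <- nrow(feats)
  last_vl <- rep(NA_real_, n)
  months_since <- rep(NA_real_, n)
  n_tests <- integer(n)
  idx_by_client <- split(seq_len(n), feats$client_id)
  for (idx in idx_by_client) {
    vl_dates <- feats$vl_date[idx]
    vl_vals <- feats$vl_value[idx]
    sched <- feats$scheduled_date[idx]
    for (j in seq_along(idx)) {
      avail <- which(!is.na(vl_dates) & vl_dates <= sched[j] &
                       seq_along(idx) <= j)
      n_tests[idx[j]] <- length(avail)
      if (length(avail) > 0) {
        k <- avail[which.max(as.numeric(vl_dates[avail]))]
        last_vl[idx[j]] <- vl_vals[k]
        months_since[idx[j]] <- as.numeric(sched[j] - vl_dates[k]) / 30.4375
      }
    }
  }
  list(last_vl_value = last_vl, months_since_last_vl = months_since,
       n_vl_tests = n_tests)
}

#' Restrict a feature frame to EMR-available variables
#'
#' Drops the survey-derived features (screening CD4, travel time, TB symptom
#' count, year first tested positive, household size) so that the model uses
#' only variables available from routinely collected medical records,
#' mirroring the restricted-variable model comparison. Idempotent.
#'
#' @param fv Feature tibble from [build_features()].
#' @return The tibble without survey-only columns.
#' @export
restrict_to_emr_features <- function(fv) {
  fv[setdiff(names(fv), survey_feature_names())]
}

#' Encode features as a numeric design matrix
#'
#' Deterministic encoding for the classifier: categorical variables are
#' one-hot encoded (with an `other` bucket for levels unseen at training
#' time, which are counted and reported via a message), every feature column
#' gets a paired missingness indicator, and absent values are imputed with a
#' sentinel (0) alongside the indicator. Column order is stable across
#' calls; pass the `metadata` of a previous encoding to reproduce its
#' columns exactly on new data.
#'
#' @param fv Feature tibble from [build_features()].
#' @param metadata Optional metadata from a previous call (training
#'   encoding) to apply to new data.
#' @return A list with `x` (numeric matrix), `y` (the `iit_next_visit`
#'   labels when present, else `NULL`), and `metadata`.
#' @export
encode_for_model <- function(fv, metadata = NULL) {
  feat_cols <- setdiff(names(fv), feature_id_cols())
  if (is.null(metadata)) {
    levels_map <- list()
    for (nm in feat_cols) {
      if (is.character(fv[[nm]]) || is.factor(fv[[nm]])) {
        levels_map[[nm]] <- sort(unique(stats::na.omit(as.character(fv[[nm]]))))
      }
    }
    metadata <- list(feature_cols = feat_cols, levels = levels_map,
                     sentinel = 0)
  } else {
    missing_feat <- setdiff(metadata$feature_cols, names(fv))
    if (length(missing_feat) > 0) {
      stop("column mismatch: feature(s) absent at scoring time: ",
           paste(missing_feat, collapse = ", "), call. = FALSE)
    }
  }
  cols <- list()
  n_unseen <- 0L
  for (nm in metadata$feature_cols) {
    v <- fv[[nm]]
    if (nm %in% names(metadata$levels)) {
      v <- as.character(v)
      lv <- metadata$levels[[nm]]
      unseen <- !is.na(v) & !v %in% lv
      n_unseen <- n_unseen + sum(unseen)
      for (l in lv) {
        cols[[paste0(nm, "_", l)]] <- as.numeric(!is.na(v) & v == l)
      }
      cols[[paste0(nm, "_other")]] <- as.numeric(unseen)
      cols[[paste0(nm, "_missing")]] <- as.numeric(is.na(v))
    } else {
      num <- as.numeric(v)
      miss <- is.na(num)
      num[miss] <- metadata$sentinel
      cols[[nm]] <- num
      cols[[paste0(nm, "_missing")]] <- as.numeric(miss)
    }
  }
  if (n_unseen > 0) {
    message(n_unseen, " value(s) in unseen categorical level(s) bucketed as 'other'")
  }
  x <- do.call(cbind, cols)
  rownames(x) <- NULL
  y <- if ("iit_next_visit" %in% names(fv)) fv$iit_next_visit else NULL
  list(x = x, y = y, metadata = metadata)
}
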