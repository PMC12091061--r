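# Outcome labeling: per-visit lateness, the 28-day interruption-in-treatment
# (IIT) rule, next-visit outcome pairing, and the censor-window rule.

#' Label visits with lateness and IIT outcomes
#'
#' Applies the 28-day retention rule to each scheduled visit: a client is
#' retained at a visit if attendance is observed before or within 28 days of
#' the scheduled date (the boundary is inclusive: 28 days late is retained,
#' 29 is an interruption; early attendance counts as on time). A visit is
#' `eligible` for analysis only when scheduled at least three calendar months
#' before the database censor date, leaving one month to meet the outcome
#' definition and two for data-capture lag.
#'
#' @param visits A visits tibble (see [generate_cohort()]), sorted per client
#'   by `scheduled_date`.
#' @param censor_date Database censor date (`Date` or ISO string), at or
#'   after every scheduled date considered.
#' @return The input with added columns `days_late` (attended minus
#'   scheduled, `NA` if never attended), `attended_within_28`,
#'   `iit_this_visit`, and `eligible`.
#' @examples
#' v <- tibble::tibble(
#'   client_id = "C1", facility_id = "F1",
#'   scheduled_date = as.Date("2020-03-01"),
#'   attended_date = as.Date("2020-03-29"),
#'   regimen_code = "TLD", vl_value = NA_real_,
#'   vl_date = as.Date(NA), tb_symptom_count = 0L
#' )
#' label_visits(v, censor_date = "2020-12-31")$iit_this_visit # FALSE (28 d)
#' @export
label_visits <- function(visits, censor_date) {
  censor_date <- as.Date(censor_date)
  if (nrow(visits) > 0) {
    ord <- order(visits$client_id, visits$scheduled_date)
    if (!identical(ord, seq_len(nrow(visits)))) {
      stop("ordering error: visits must be sorted by client_id and ",
           "scheduled_date", call. = FALSE)
    }
    dup <- duplicated(visits[c("client_id", "scheduled_date")])
    if (any(dup)) {
      stop("schema error: duplicated scheduled date for client ",
           visits$client_id[which(dup)[1]], call. = FALSE)
    }
    if (max(visits$scheduled_date) > censor_date) {
      stop("censor_date must be at or after every scheduled date",
           call. = FALSE)
    }
  }
  eligibility_cutoff <- censor_date %m-% months(3)
  visits |>
    dplyr::mutate(
      days_late = as.integer(.data$attended_date - .data$scheduled_date),
      attended_within_28 = !is.na(.data$attended_date) & .data$days_late <= 28L,
      iit_this_visit = !.data$attended_within_28,
      eligible = .data$scheduled_date <= eligibility_cutoff
    )
}

#' Attach each visit's next-visit outcome
#'
#' The prediction target of the risk model is the IIT status of the visit
#' observed immediately after a scored visit ("next visit"). For each client,
#' in schedule order, attaches `next_scheduled_date` and `iit_next_visit`;
#' both are absent for the last visit of a client and `iit_next_visit` is
#' absent when the next scheduled visit is not itself eligible under the
#' censor rule. A never-attended visit's next visit is the next observed
#' scheduled visit (the re-engagement visit) when one exists.
#'
#' @param labeled Output of [label_visits()].
#' @return `labeled` with `next_scheduled_date` and `iit_next_visit` columns.
#' @export
pair_next_visit <- function(labeled) {
  labeled |>
    dplyr::group_by(.data$client_id) |>
    dplyr::arrange(.data$scheduled_date, .by_group = TRUE) |>
    dplyr::mutate(
      next_scheduled_date = dplyr::lead(.data$scheduled_date),
      iit_next_visit = ifelse(dplyr::lead(.data$eligible) %in% TRUE,
                              dplyr::lead(.data$iit_this_visit), NA)
    ) |>
    dplyr::ungroup()
}

#' Assign time-on-ART strata
#'
#' Computes calendar months on ART at each scheduled visit (date arithmetic,
#' not 30-day blocks: a visit exactly 6 calendar months after initiation is
#' at 6.0 months) and assigns the stratum used in the triage tables: the
#' first follow-up visit after initiation is flagged separately (and also
#' falls within the 0-6 month period); otherwise strata are 0-6 months
#' (boundary inclusive), 7-12 months (6 exclusive to 12 inclusive), and
#' over 12 months.
#'
#' @param labeled A labeled visits tibble.
#' @param clients Clients tibble with `art_start_date`.
#' @return `labeled` with columns `time_on_art_months` (calendar months,
#'   fractional), `is_first_visit_after_initiation`, and `art_stratum`
#'   (factor with levels `first_visit_after_initiation`, `months_0_6`,
#'   `months_7_12`, `months_gt_12`; first-visit rows carry the first-visit
#'   level).
#' @export
time_on_art_stratum <- function(labeled, clients) {
  start <- clients$art_start_date[match(labeled$client_id, clients$client_id)]
  if (anyNA(start)) {
    stop("linkage error: visit client_id missing from clients or ",
         "art_start_date absent", call. = FALSE)
  }
  if (any(labeled$scheduled_date < start)) {
    stop("visit scheduled before art_start_date", call. = FALSE)
  }
  months_on_art <- calendar_months_between(start, labeled$scheduled_date)
  out <- labeled
  out$time_on_art_months <- months_on_art
  out <- out |>
    dplyr::group_by(.data$client_id) |>
    dplyr::arrange(.data$scheduled_date, .by_group = TRUE) |>
    dplyr::mutate(
      is_first_visit_after_initiation = dplyr::row_number() == 1L
    ) |>
    dplyr::ungroup()
  out$art_stratum <- factor(
    ifelse(out$is_first_visit_after_initiation, "first_visit_after_initiation",
      ifelse(out$time_on_art_months <= 6, "months_0_6",
        ifelse(out$time_on_art_months <= 12, "months_7_12", "months_gt_12")
      )
    ),
    levels = c("first_visit_after_initiation", "months_0_6", "months_7_12",
               "months_gt_12")
  )
  out
}

# Calendar months elapsed between two date vectors (date arithmetic, not
# 30-day blocks); exact integers at month boundaries, fractional otherwise.
calendar_months_between <- function(from, to) {
  lubridate::interval(from, to) / months(1)
}
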