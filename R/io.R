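# CSV round-trip for cohorts: clients.csv + visits.csv, ISO-8601 dates,
# empty string = absent.

client_schema <- function() {
  list(
    client_id = "character", sex = "character", birth_date = "date",
    employment = "character", payday_day_of_month = "integer",
    household_size_others = "integer", travel_time_min = "numeric",
    disclosed_status = "logical", has_hiv_info = "logical",
    planned_to_test_today = "logical", prepared_to_start_today = "logical",
    prior_hiv_test_history = "logical", year_first_tested_positive = "integer",
    cd4_screening = "numeric", phone_number_on_file = "logical",
    attends_other_facilities = "logical", art_start_date = "date"
  )
}

visit_schema <- function() {
  list(
    client_id = "character", facility_id = "character",
    scheduled_date = "date", attended_date = "date",
    regimen_code = "character", vl_value = "numeric", vl_date = "date",
    tb_symptom_count = "integer"
  )
}

format_for_csv <- function(df, schema) {
  out <- df
  for (nm in names(schema)) {
    v <- df[[nm]]
    out[[nm]] <- switch(schema[[nm]],
      date = ifelse(is.na(v), "", format(v, "%Y-%m-%d")),
      logical = ifelse(is.na(v), "", ifelse(v, "true", "false")),
      ifelse(is.na(v), "", as.character(v))
    )
  }
  out
}

parse_from_csv <- function(df, schema, file) {
  extra <- setdiff(names(df), names(schema))
  if (length(extra) > 0) {
    stop("schema error in ", file, ": unknown column(s) ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols) > 0) {
    stop("schema error in ", file, ": missing required column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- df[names(schema)]
  for (nm in names(schema)) {
    raw <- as.character(df[[nm]])
    blank <- is.na(raw) | raw == ""
    out[[nm]] <- switch(schema[[nm]],
      date = {
        v <- as.Date(rep(NA_character_, length(raw)))
        ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", raw) &
          !is.na(suppressWarnings(as.Date(raw, format = "%Y-%m-%d")))
        if (any(!blank & !ok)) {
          bad <- which(!blank & !ok)[1]
          stop("schema error in ", file, ": malformed date in column '", nm,
               "' at row ", bad, " ('", raw[bad], "')", call. = FALSE)
        }
        v[!blank] <- as.Date(raw[!blank], format = "%Y-%m-%d")
        v
      },
      logical = {
        low <- tolower(raw)
        bad <- !blank & !low %in% c("true", "false")
        if (any(bad)) {
          stop("schema error in ", file, ": non-boolean value in column '",
               nm, "' at row ", which(bad)[1], call. = FALSE)
        }
        ifelse(blank, NA, low == "true")
      },
      integer = {
        v <- suppressWarnings(as.integer(raw))
        if (any(!blank & is.na(v))) {
          stop("schema error in ", file, ": non-integer value in column '",
               nm, "' at row ", which(!blank & is.na(v))[1], call. = FALSE)
        }
        v
      },
      numeric = {
        v <- suppressWarnings(as.numeric(raw))
        if (any(!blank & is.na(v))) {
          stop("schema error in ", file, ": non-numeric value in column '",
               nm, "' at row ", which(!blank & is.na(v))[1], call. = FALSE)
        }
        v
      },
      ifelse(blank, NA_character_, raw)
    )
  }
  tibble::as_tibble(out)
}

validate_cohort <- function(clients, visits) {
  dup <- duplicated(visits[c("client_id", "scheduled_date")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop("schema error: duplicated (client_id, scheduled_date) at visits row ",
         i, " (", visits$client_id[i], ", ", visits$scheduled_date[i], ")",
         call. = FALSE)
  }
  early <- !is.na(visits$attended_date) &
    visits$attended_date < visits$scheduled_date - 28
  if (any(early)) {
    i <- which(early)[1]
    stop("schema error: attended_date more than 28 days before ",
         "scheduled_date at visits row ", i, " (", visits$client_id[i], ")",
         call. = FALSE)
  }
  start <- clients$art_start_date[match(visits$client_id, clients$client_id)]
  before_art <- !is.na(start) & visits$scheduled_date < start
  if (any(before_art)) {
    i <- which(before_art)[1]
    stop("schema error: visit scheduled before ART start at visits row ", i,
         " (", visits$client_id[i], ")", call. = FALSE)
  }
  if (any(!is.na(clients$household_size_others) &
          clients$household_size_others < 0)) {
    stop("schema error: negative household_size_others", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a cohort to CSV files
#'
#' Writes `clients.csv` and `visits.csv` into `path` with ISO-8601 dates and
#' empty strings for absent values, such that [read_cohort()] round-trips the
#' records exactly.
#'
#' @param clients,visits Tibbles as produced by [generate_cohort()].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(clients, visits, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(format_for_csv(clients, client_schema()),
                   file.path(path, "clients.csv"), row.names = FALSE)
  utils::write.csv(format_for_csv(visits, visit_schema()),
                   file.path(path, "visits.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a cohort from CSV files
#'
#' Reads and validates `clients.csv` and `visits.csv` written by
#' [write_cohort()] (or prepared externally with the same schema). Schema
#' violations — unknown or missing columns, malformed dates, duplicated
#' `(client_id, scheduled_date)` pairs, attendance more than 28 days before
#' schedule, visits scheduled before ART start — raise errors naming the
#' offending column and row.
#'
#' @param path Directory containing `clients.csv` and `visits.csv`.
#' @return A list with tibbles `clients` and `visits`.
#' @export
read_cohort <- function(path) {
  read_one <- function(file, schema) {
    f <- file.path(path, file)
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
    raw <- utils::read.csv(f, colClasses = "character", check.names = FALSE)
    parse_from_csv(raw, schema, file)
  }
  clients <- read_one("clients.csv", client_schema())
  visits <- read_one("visits.csv", visit_schema())
  validate_cohort(clients, visits)
  list(clients = clients, visits = visits)
}
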