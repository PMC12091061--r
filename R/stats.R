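#' Build a 2x2 exposure-outcome table
#'
#' Container for the event counts feeding crude relative-risk estimation:
#' events and totals in an exposed group and a reference group.
#'
#' @param exposed_events Number of events (e.g. IIT at next visit) in the
#'   exposed group (`a`).
#' @param exposed_total Number of visits in the exposed group (`n1`).
#' @param reference_events Number of events in the reference group (`c`).
#' @param reference_total Number of visits in the reference group (`n0`).
#'
#' @return An object of class `two_by_two`.
#' @examples
#' two_by_two(72756, 559658, 41974, 699573)
#' @export
two_by_two <- function(exposed_events, exposed_total,
                       reference_events, reference_total) {
  counts <- c(exposed_events, exposed_total, reference_events, reference_total)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("two_by_two counts must be non-negative integers", call. = FALSE)
  }
  if (exposed_total <= 0 || reference_total <= 0) {
    stop("group totals must be positive", call. = FALSE)
  }
  if (exposed_events > exposed_total || reference_events > reference_total) {
    stop("events cannot exceed group totals", call. = FALSE)
  }
  structure(
    list(
      exposed_events = as.numeric(exposed_events),
      exposed_total = as.numeric(exposed_total),
      reference_events = as.numeric(reference_events),
      reference_total = as.numeric(reference_total)
    ),
    class = "two_by_two"
  )
}

#' Crude relative risk with a log-method confidence interval
#'
#' Estimates the crude relative risk `RR = (a/n1) / (c/n0)` between an exposed
#' and a reference group, with the Katz log-method confidence interval
#' `exp(ln RR +/- z * sqrt(1/a - 1/n1 + 1/c - 1/n0))`. This is the estimator
#' used throughout the triage and archetype tables; no adjustment is made for
#' repeated visits per client (the estimate is deliberately crude).
#'
#' @param t A [two_by_two()] table, or the exposed event count `a` when the
#'   remaining counts are given positionally.
#' @param n1,c,n0 Exposed total, reference events, reference total (only when
#'   `t` is a bare count).
#' @param confidence Confidence level, default 0.95.
#'
#' @return A list of class `rr_result` with elements `rr`, `ci_low`,
#'   `ci_high`, and `z` (the standard-normal quantile used).
#'   When the exposed group has zero events the RR is returned with
#'   `NA` confidence limits (flagged undefined rather than silently
#'   continuity-corrected).
#' @examples
#' crude_rr(two_by_two(72756, 559658, 41974, 699573)) # RR 2.17 (2.14-2.19)
#' @export
crude_rr <- function(t, n1 = NULL, c = NULL, n0 = NULL, confidence = 0.95) {
  if (!inherits(t, "two_by_two")) {
    t <- two_by_two(t, n1, c, n0)
  }
  if (confidence <= 0 || confidence >= 1) {
    stop("confidence must be in (0, 1)", call. = FALSE)
  }
  a <- t$exposed_events
  n1 <- t$exposed_total
  cc <- t$reference_events
  n0 <- t$reference_total
  if (cc == 0) {
    stop("reference group has zero events: relative risk undefined", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  rr <- (a / n1) / (cc / n0)
  if (a == 0) {
    res <- list(rr = rr, ci_low = NA_real_, ci_high = NA_real_, z = z)
  } else {
    se <- sqrt(1 / a - 1 / n1 + 1 / cc - 1 / n0)
    res <- list(
      rr = rr,
      ci_low = exp(log(rr) - z * se),
      ci_high = exp(log(rr) + z * se),
      z = z
    )
  }
  structure(res, class = "rr_result")
}

#' @export
print.rr_result <- function(x, ...) {
  cat(format_rr(x), "\n")
  invisible(x)
}

#' Format a relative-risk result for table rendering
#'
#' Rounds half-up to two decimals only at presentation time, producing cells
#' such as `"2.17 (2.14-2.19)"`.
#'
#' @param x An `rr_result`, or `NULL`/`NA` for an undefined cell.
#' @param reference Render the reference-group marker `"Ref"` instead.
#' @return A character scalar.
#' @export
format_rr <- function(x, reference = FALSE) {
  if (isTRUE(reference)) return("Ref")
  if (is.null(x) || (length(x) == 1 && is.na(x[[1]]))) return("N/A")
  fmt <- function(v) {
    if (is.na(v)) return("NA")
    # round half-up at 2 decimals
    sprintf("%.2f", floor(v * 100 + 0.5) / 100)
  }
  sprintf("%s (%s-%s)", fmt(x$rr), fmt(x$ci_low), fmt(x$ci_high))
}

#' Frequency and proportion table
#'
#' Simple per-group event frequencies and percentages, computed at full
#' precision; rounding happens only when rendering.
#'
#' @param groups A named list, each element a length-2 numeric
#'   `c(events, total)`.
#' @return A tibble with columns `group`, `n`, `events`, `percent`
#'   (`NA` percent when the denominator is zero).
#' @examples
#' proportion_table(list(all = c(146881, 1399145)))
#' @export
proportion_table <- function(groups) {
  stopifnot(is.list(groups), length(groups) > 0, !is.null(names(groups)))
  rows <- purrr::imap(groups, function(g, nm) {
    stopifnot(length(g) == 2, all(g >= 0), g[1] <= g[2] || g[2] == 0)
    tibble::tibble(
      group = nm,
      n = g[2],
      events = g[1],
      percent = if (g[2] == 0) NA_real_ else 100 * g[1] / g[2]
    )
  })
  dplyr::bind_rows(rows)
}
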