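# Threshold approach: green/yellow/red triage of scored visits by empirical
# score percentile, doubling-rate cutoff calibration, and stratified tables.

#' Assign triage bins by score percentile
#'
#' Visits with the lowest scores (up to the first cut percentile, default
#' the lowest 50%) are `green` (low risk), the middle band (default 40%)
#' `yellow` (moderate risk), and the top band (default 10%) `red` (high
#' risk). Cutpoints are the order statistics of the scores themselves; all
#' scores tied at a cutpoint value go to the lower-risk bin (conservative:
#' ties never inflate the red bin). If all scores are identical every visit
#' is green and a warning is emitted.
#'
#' @param scores Numeric risk scores (at least one).
#' @param cut_percentiles Pair `c(p1, p2)` with `0 < p1 < p2 < 1`,
#'   default `c(0.50, 0.90)`.
#' @return A factor with levels `green`, `yellow`, `red`, plus attributes
#'   `cut_percentiles` and `score_cutpoints` (the realized score values).
#' @examples
#' table(assign_bins(seq_len(100) / 100))
#' @export
assign_bins <- function(scores, cut_percentiles = c(0.50, 0.90)) {
  if (length(scores) == 0) stop("no scores to bin", call. = FALSE)
  if (anyNA(scores)) stop("scores must not contain NA", call. = FALSE)
  p1 <- cut_percentiles[1]; p2 <- cut_percentiles[2]
  if (!(p1 > 0 && p1 < p2 && p2 < 1)) {
    stop("cut_percentiles must satisfy 0 < p1 < p2 < 1", call. = FALSE)
  }
  n <- length(scores)
  srt <- sort(scores)
  s1 <- srt[ceiling(p1 * n)]
  s2 <- srt[ceiling(p2 * n)]
  bins <- factor(
    ifelse(scores <= s1, "green", ifelse(scores <= s2, "yellow", "red")),
    levels = c("green", "yellow", "red")
  )
  if (all(bins == "green")) {
    warning("all scores tied at or below the first cutpoint: ",
            "every visit assigned green", call. = FALSE)
  }
  attr(bins, "cut_percentiles") <- c(p1, p2)
  attr(bins, "score_cutpoints") <- c(s1, s2)
  bins
}

#' Calibrate cutoffs to the rate-doubling criterion
#'
#' Grid-searches percentile pairs `(p1, p2)` for cutoffs at which the IIT
#' rate in each bin is twice that of the bin below — the design rationale of
#' the 50/90 default. Two objectives are available. The default,
#' `method = "ml"`, fits, for each candidate pair, the constrained binomial
#' model with bin rates `(r, 2r, 4r)` by maximum likelihood and selects the
#' pair with the highest likelihood; because it weighs every visit and
#' requires within-bin homogeneity, it identifies the change points far more
#' precisely than ratio matching when events are sparse.
#' `method = "lsq"` minimizes the direct ratio-matching criterion
#' `(log(rate_y/rate_g) - log 2)^2 + (log(rate_r/rate_y) - log 2)^2`.
#' Candidates with an event-free or empty bin are skipped; if every
#' candidate is skipped, an error is raised. Deterministic.
#'
#' @param scores Numeric risk scores.
#' @param iit_next_labels Logical IIT-at-next-visit outcomes, same length.
#' @param method `"ml"` (constrained-likelihood, default) or `"lsq"`
#'   (log-ratio least squares).
#' @param p1_grid,p2_step Grid for the first percentile (default
#'   `seq(0.2, 0.8, 0.01)`) and step for the second (from `p1 + 0.05` to
#'   0.98).
#' @return Numeric `c(p1, p2)` with attribute `objective` (the minimized
#'   value: negative log-likelihood for `"ml"`, squared log-ratio deviation
#'   for `"lsq"`).
#' @export
calibrate_doubling_cutoffs <- function(scores, iit_next_labels,
                                       method = c("ml", "lsq"),
                                       p1_grid = seq(0.20, 0.80, by = 0.01),
                                       p2_step = 0.01) {
  method <- match.arg(method)
  keep <- !is.na(iit_next_labels)
  scores <- scores[keep]
  y <- iit_next_labels[keep]
  n <- length(scores)
  if (n < 10) stop("need at least 10 labeled scored visits", call. = FALSE)
  ord <- order(scores)
  y_sorted <- as.numeric(y[ord])
  s_sorted <- scores[ord]
  cum_ev <- cumsum(y_sorted)
  total_ev <- cum_ev[n]
  # index of the last observation tied with the value at rank k
  # (ties at a cutpoint belong to the lower bin)
  runs <- rle(s_sorted)
  tie_end_at <- rep(cumsum(runs$lengths), runs$lengths)
  tie_end <- function(k) tie_end_at[k]
  best <- NULL
  best_obj <- Inf
  for (p1 in p1_grid) {
    k1 <- tie_end(ceiling(p1 * n))
    for (p2 in seq(p1 + 0.05, 0.98, by = p2_step)) {
      k2 <- tie_end(ceiling(p2 * n))
      if (k2 <= k1 || k2 >= n) next
      n_g <- k1; n_y <- k2 - k1; n_r <- n - k2
      e_g <- cum_ev[k1]; e_y <- cum_ev[k2] - cum_ev[k1]; e_r <- total_ev - cum_ev[k2]
      if (min(e_g, e_y, e_r) == 0 || min(n_g, n_y, n_r) == 0) next
      obj <- if (method == "ml") {
        negll <- function(r) {
          -(e_g * log(r) + (n_g - e_g) * log(1 - r) +
              e_y * log(2 * r) + (n_y - e_y) * log(1 - 2 * r) +
              e_r * log(4 * r) + (n_r - e_r) * log(1 - 4 * r))
        }
        stats::optimize(negll, c(1e-6, 0.25 - 1e-6))$objective
      } else {
        (log((e_y / n_y) / (e_g / n_g)) - log(2))^2 +
          (log((e_r / n_r) / (e_y / n_y)) - log(2))^2
      }
      if (obj < best_obj) {
        best_obj <- obj
        best <- c(p1, p2)
      }
    }
  }
  if (is.null(best)) {
    stop("no candidate cutoff pair had events in every bin", call. = FALSE)
  }
  attr(best, "objective") <- best_obj
  best
}

#' Triage table: IIT at next visit by bin and time on ART
#'
#' Cross-tabulates triage bins against the next-visit IIT outcome, overall
#' and within each time-on-ART stratum when available, with the crude
#' relative risk of each bin versus green. Visits without an observed next
#' visit are excluded; a stratum whose green bin has no events yields
#' undefined RR rows.
#'
#' @param bins Factor from [assign_bins()], aligned with `labeled`.
#' @param labeled Tibble carrying `iit_next_visit` (and optionally
#'   `art_stratum`) for the same visits.
#' @return A tibble with one row per stratum x bin (plus `all`-visit rows
#'   and per-stratum `all`-bin rows): `stratum`, `bin`, `n_visits`,
#'   `n_iit_next`, `iit_rate`, `rr`, `ci_low`, `ci_high` (`NA` RR for the
#'   green reference and undefined cells).
#' @export
triage_table <- function(bins, labeled) {
  stopifnot(length(bins) == nrow(labeled))
  keep <- !is.na(labeled$iit_next_visit)
  df <- tibble::tibble(
    bin = bins[keep],
    iit_next = labeled$iit_next_visit[keep],
    stratum = if ("art_stratum" %in% names(labeled)) {
      as.character(labeled$art_stratum)[keep]
    } else {
      rep(NA_character_, sum(keep))
    }
  )
  strata <- c("all", sort(unique(stats::na.omit(df$stratum))))
  rows <- list()
  for (st in strata) {
    sub <- if (st == "all") df else df[df$stratum %in% st, ]
    if (nrow(sub) == 0) next
    counts <- sub |>
      dplyr::group_by(.data$bin, .drop = FALSE) |>
      dplyr::summarise(n_visits = dplyr::n(),
                       n_iit_next = sum(.data$iit_next), .groups = "drop")
    g <- counts[counts$bin == "green", ]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      stratum = st, bin = "all",
      n_visits = nrow(sub), n_iit_next = sum(sub$iit_next),
      iit_rate = mean(sub$iit_next), rr = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_
    )
    for (b in levels(df$bin)) {
      ct <- counts[counts$bin == b, ]
      rr <- ci_lo <- ci_hi <- NA_real_
      if (b != "green" && ct$n_visits > 0 && g$n_visits > 0 &&
          g$n_iit_next > 0) {
        est <- crude_rr(two_by_two(ct$n_iit_next, ct$n_visits,
                                   g$n_iit_next, g$n_visits))
        rr <- est$rr; ci_lo <- est$ci_low; ci_hi <- est$ci_high
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        stratum = st, bin = b,
        n_visits = ct$n_visits, n_iit_next = ct$n_iit_next,
        iit_rate = if (ct$n_visits > 0) ct$n_iit_next / ct$n_visits else NA_real_,
        rr = rr, ci_low = ci_lo, ci_high = ci_hi
      )
    }
  }
  dplyr::bind_rows(rows)
}
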