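# Synthetic EMR cohort generator: longitudinal visit schedules with
# covariate-linked disengagement risk, lateness mixtures and re-engagement.

#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical conditions the generator emulates: cohort size,
#' follow-up duration, the target marginal interruption-in-treatment (IIT)
#' rate, a lateness mixture over attendance-delay categories, covariate
#' effects on the latent disengagement propensity, and re-engagement
#' dynamics after a missed visit.
#'
#' @param n_clients Number of clients to simulate (>= 0).
#' @param max_followup Follow-up duration in months (> 0).
#' @param base_iit_rate Target marginal probability that a scheduled visit is
#'   missed (not attended within 28 days). Per-client disengagement
#'   probabilities are mean-normalized so this marginal holds in expectation
#'   regardless of covariate effects or client-level noise.
#' @param lateness_mixture Named probabilities for the four attendance-delay
#'   categories `on_time` (attended on or up to 5 days before schedule),
#'   `late_1_3`, `late_4_28`, and `late_gt_28`; must sum to 1 and the
#'   `late_gt_28` mass must equal `base_iit_rate` (it is the same marginal).
#' @param covariate_effects Named numeric vector of log-risk effects on the
#'   disengagement propensity. Supported names:
#'   `male`, `age_lt_25`, `unemployed`, `lives_alone`, `travel_gt_20`,
#'   `no_phone`, `attends_other_facilities`, `not_prepared`, `undisclosed`,
#'   `no_prior_test`.
#' @param archetype_multipliers Named risk multipliers applied on top of the
#'   per-client probability. `returning_after_disengagement` multiplies the
#'   per-visit miss probability once a client has missed any earlier visit;
#'   any covariate-indicator name applies statically to carriers.
#' @param client_noise_sd Standard deviation of the client-level normal noise
#'   added to the propensity logit (persistent heterogeneity).
#' @param return_prob Probability that a visit drawn `late_gt_28` is
#'   eventually attended late (29-120 days) rather than never attended.
#' @param reengage_prob Probability that a never-attended visit is followed by
#'   a re-engagement visit (scheduled 60-150 days later); otherwise the
#'   client's visit stream ends.
#' @param lab_prob Probability that viral-load results (per visit) and the
#'   screening CD4 (per client) are recorded; exercises absent-value handling.
#' @param early_interval_days,late_interval_days,n_early_visits Scheduling
#'   rule: the first `n_early_visits` follow-up visits are
#'   `early_interval_days` apart (monthly), later visits
#'   `late_interval_days` apart (two-monthly).
#' @param seed Integer seed; fans out into independent per-client substreams
#'   so adding clients does not perturb earlier ones.
#'
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_clients = 1000,
                             max_followup = 24,
                             base_iit_rate = 0.12,
                             lateness_mixture = c(
                               on_time = 0.55, late_1_3 = 0.18,
                               late_4_28 = 1 - 0.55 - 0.18 - base_iit_rate,
                               late_gt_28 = base_iit_rate
                             ),
                             covariate_effects = c(
                               male = 0.2, age_lt_25 = 0.5,
                               attends_other_facilities = 0.4,
                               travel_gt_20 = 0.25, lives_alone = 0.3,
                               not_prepared = 0.3
                             ),
                             archetype_multipliers = c(
                               returning_after_disengagement = 1.0
                             ),
                             client_noise_sd = 0.7,
                             return_prob = 0.6,
                             reengage_prob = 0.7,
                             lab_prob = 0.7,
                             early_interval_days = 28,
                             late_interval_days = 56,
                             n_early_visits = 3,
                             seed = 1L) {
  cfg <- list(
    n_clients = n_clients, max_followup = max_followup,
    base_iit_rate = base_iit_rate, lateness_mixture = lateness_mixture,
    covariate_effects = covariate_effects,
    archetype_multipliers = archetype_multipliers,
    client_noise_sd = client_noise_sd, return_prob = return_prob,
    reengage_prob = reengage_prob, lab_prob = lab_prob,
    early_interval_days = early_interval_days,
    late_interval_days = late_interval_days,
    n_early_visits = n_early_visits, seed = as.integer(seed)
  )
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  if (cfg$n_clients < 0) stop("n_clients must be >= 0", call. = FALSE)
  if (cfg$max_followup <= 0) stop("max_followup must be > 0", call. = FALSE)
  probs <- c(cfg$base_iit_rate, cfg$return_prob, cfg$reengage_prob,
             cfg$lab_prob, cfg$lateness_mixture)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  mix <- cfg$lateness_mixture
  needed <- c("on_time", "late_1_3", "late_4_28", "late_gt_28")
  if (!setequal(names(mix), needed)) {
    stop("lateness_mixture must have components ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(mix) - 1) > 1e-8) {
    stop("lateness_mixture must sum to 1", call. = FALSE)
  }
  if (abs(mix[["late_gt_28"]] - cfg$base_iit_rate) > 1e-8) {
    stop("lateness_mixture['late_gt_28'] must equal base_iit_rate ",
         "(they describe the same marginal)", call. = FALSE)
  }
  bad <- setdiff(names(cfg$covariate_effects), names(covariate_indicator_fns()))
  if (length(bad) > 0) {
    stop("unknown covariate_effects name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad_m <- setdiff(names(cfg$archetype_multipliers),
                   c("returning_after_disengagement",
                     names(covariate_indicator_fns())))
  if (length(bad_m) > 0) {
    stop("unknown archetype_multipliers name(s): ",
         paste(bad_m, collapse = ", "), call. = FALSE)
  }
  if (any(cfg$archetype_multipliers < 0)) {
    stop("archetype_multipliers must be non-negative", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

# Named indicator functions mapping a clients tibble to 0/1 carriers;
# age is evaluated at ART start.
covariate_indicator_fns <- function() {
  list(
    male = function(cl) as.numeric(cl$sex == "M"),
    age_lt_25 = function(cl) {
      age <- as.numeric(cl$art_start_date - cl$birth_date) / 365.25
      as.numeric(age < 25)
    },
    unemployed = function(cl) as.numeric(cl$employment == "unemployed"),
    lives_alone = function(cl) as.numeric(cl$household_size_others == 0),
    travel_gt_20 = function(cl) as.numeric(cl$travel_time_min > 20),
    no_phone = function(cl) as.numeric(!cl$phone_number_on_file),
    attends_other_facilities = function(cl) as.numeric(cl$attends_other_facilities),
    not_prepared = function(cl) as.numeric(!cl$prepared_to_start_today),
    undisclosed = function(cl) as.numeric(!cl$disclosed_status),
    no_prior_test = function(cl) as.numeric(!cl$prior_hiv_test_history)
  )
}

# Deterministic per-client substream seed below 2^31.
client_seed <- function(seed, i, stream) {
  s <- (as.double(seed) * 2654435761 + as.double(i) * 40503 + stream * 97) %%
    2147483629
  as.integer(s)
}

draw_one_client <- function(i, cfg) {
  set.seed(client_seed(cfg$seed, i, 1L))
  art_start <- as.Date("2016-01-01") + sample.int(730, 1) - 1
  sex <- if (stats::runif(1) < 0.64) "F" else "M"
  age0 <- min(max(round(stats::rnorm(1, 35, 12)), 15), 75)
  birth_date <- art_start - round(age0 * 365.25) - sample.int(365, 1) + 1
  employment <- sample(c("employed", "unemployed", "unknown"), 1,
                       prob = c(0.45, 0.45, 0.10))
  tibble::tibble(
    client_id = sprintf("C%05d", i),
    sex = sex,
    birth_date = birth_date,
    employment = employment,
    payday_day_of_month = if (employment == "employed")
      as.integer(sample(25:31, 1)) else NA_integer_,
    household_size_others = as.integer(stats::rpois(1, 1.8)),
    travel_time_min = as.numeric(min(max(round(stats::rlnorm(1, log(25), 0.6)), 1), 180)),
    disclosed_status = stats::runif(1) < 0.7,
    has_hiv_info = stats::runif(1) < 0.8,
    planned_to_test_today = stats::runif(1) < 0.5,
    prepared_to_start_today = stats::runif(1) < 0.75,
    prior_hiv_test_history = stats::runif(1) < 0.6,
    year_first_tested_positive = as.integer(
      as.integer(format(art_start, "%Y")) - stats::rgeom(1, 0.5)
    ),
    cd4_screening = if (stats::runif(1) < cfg$lab_prob)
      as.numeric(round(stats::rlnorm(1, log(350), 0.7))) else NA_real_,
    phone_number_on_file = stats::runif(1) < 0.85,
    attends_other_facilities = stats::runif(1) < 0.15,
    art_start_date = art_start
  )
}

draw_client_visits <- function(client, p_client, cfg) {
  set.seed(client_seed(cfg$seed, match_client_index(client$client_id), 2L))
  mix <- cfg$lateness_mixture
  attended_mix <- mix[c("on_time", "late_1_3", "late_4_28")]
  horizon <- client$art_start_date + round(cfg$max_followup * 30.4375)
  mult_return <- cfg$archetype_multipliers[["returning_after_disengagement"]] %||% 1
  sched <- client$art_start_date + cfg$early_interval_days
  k <- 1L
  prior_iit <- FALSE
  regimen <- "TLD"
  n_max <- ceiling(cfg$max_followup * 31 / cfg$early_interval_days) + 2L
  v_sched <- v_att <- rep(as.Date(NA), n_max)
  v_reg <- character(n_max)
  v_vl <- rep(NA_real_, n_max)
  v_vld <- rep(as.Date(NA), n_max)
  v_tb <- integer(n_max)
  while (sched <= horizon && k <= n_max) {
    p_v <- p_client * (if (prior_iit) mult_return else 1)
    p_v <- min(p_v, 0.95)
    if (stats::runif(1) < 0.05) regimen <- if (regimen == "TLD") "TEE" else "TLD"
    missed <- stats::runif(1) < p_v
    if (missed) {
      prior_iit <- TRUE
      attended <- if (stats::runif(1) < cfg$return_prob) {
        sched + sample(29:120, 1)
      } else {
        as.Date(NA)
      }
    } else {
      cat_idx <- sample.int(3, 1, prob = attended_mix / sum(attended_mix))
      delay <- switch(cat_idx, sample(-5:0, 1), sample(1:3, 1), sample(4:28, 1))
      attended <- sched + delay
    }
    has_vl <- !is.na(attended) && stats::runif(1) < cfg$lab_prob
    v_sched[k] <- sched
    v_att[k] <- attended
    v_reg[k] <- regimen
    if (has_vl) {
      v_vl[k] <- as.numeric(if (stats::runif(1) < 0.8) sample(0:49, 1)
                            else round(stats::rlnorm(1, 8, 1.5)))
      v_vld[k] <- attended
    }
    v_tb[k] <- as.integer(stats::rbinom(1, 4, 0.05))
    if (missed && is.na(attended)) {
      if (stats::runif(1) < cfg$reengage_prob) {
        sched <- sched + sample(60:150, 1)
      } else {
        k <- k + 1L
        break
      }
    } else {
      gap <- if (k < cfg$n_early_visits) cfg$early_interval_days else cfg$late_interval_days
      sched <- sched + gap
    }
    k <- k + 1L
  }
  n <- k - 1L
  if (n == 0L) return(empty_visits())
  tibble::tibble(
    client_id = client$client_id,
    facility_id = "F001",
    scheduled_date = v_sched[seq_len(n)],
    attended_date = v_att[seq_len(n)],
    regimen_code = v_reg[seq_len(n)],
    vl_value = v_vl[seq_len(n)],
    vl_date = v_vld[seq_len(n)],
    tb_symptom_count = v_tb[seq_len(n)]
  )
}

match_client_index <- function(client_id) {
  as.integer(sub("^C", "", client_id))
}

#' Generate a synthetic longitudinal cohort
#'
#' Simulates clients and their scheduled/attended clinic visits. Each client
#' carries a latent disengagement propensity: a logistic function of
#' covariates (via `covariate_effects`) plus persistent client-level noise,
#' mean-normalized so the marginal per-visit miss probability equals
#' `base_iit_rate`. Each scheduled visit draws an attendance delay from the
#' lateness mixture tilted by the client's propensity; a visit drawn in the
#' `>28 days` category is attended late or never, and a never-attended visit
#' is followed by a re-engagement visit with probability `reengage_prob`.
#' Deterministic given the config seed.
#'
#' @param config A [generator_config()].
#' @return A list with tibbles `clients` and `visits` (sorted by client and
#'   scheduled date).
#' @examples
#' cohort <- generate_cohort(generator_config(n_clients = 20, seed = 7))
#' nrow(cohort$visits)
#' @export
generate_cohort <- function(config) {
  config <- validate_generator_config(config)
  if (config$n_clients == 0) {
    return(list(clients = empty_clients(), visits = empty_visits()))
  }
  clients <- dplyr::bind_rows(
    lapply(seq_len(config$n_clients), draw_one_client, cfg = config)
  )
  # latent propensity: logit(base) + X beta + client noise, then
  # mean-normalized on the probability scale to hit the target marginal
  eta <- stats::qlogis(config$base_iit_rate)
  fns <- covariate_indicator_fns()
  x_eta <- rep(eta, nrow(clients))
  for (nm in names(config$covariate_effects)) {
    x_eta <- x_eta + config$covariate_effects[[nm]] * fns[[nm]](clients)
  }
  noise <- vapply(seq_len(config$n_clients), function(i) {
    set.seed(client_seed(config$seed, i, 3L))
    stats::rnorm(1, 0, config$client_noise_sd)
  }, numeric(1))
  p_raw <- stats::plogis(x_eta + noise)
  p <- p_raw * config$base_iit_rate / mean(p_raw)
  # static archetype multipliers apply to carrier subgroups
  for (nm in setdiff(names(config$archetype_multipliers),
                     "returning_after_disengagement")) {
    p <- p * ifelse(fns[[nm]](clients) == 1,
                    config$archetype_multipliers[[nm]], 1)
  }
  p <- pmin(pmax(p, 1e-4), 0.95)
  visits <- dplyr::bind_rows(
    lapply(seq_len(config$n_clients), function(i) {
      draw_client_visits(clients[i, ], p[i], config)
    })
  )
  visits <- dplyr::arrange(visits, .data$client_id, .data$scheduled_date)
  list(clients = clients, visits = visits)
}

empty_clients <- function() {
  tibble::tibble(
    client_id = character(), sex = character(),
    birth_date = as.Date(character()), employment = character(),
    payday_day_of_month = integer(), household_size_others = integer(),
    travel_time_min = numeric(), disclosed_status = logical(),
    has_hiv_info = logical(), planned_to_test_today = logical(),
    prepared_to_start_today = logical(), prior_hiv_test_history = logical(),
    year_first_tested_positive = integer(), cd4_screening = numeric(),
    phone_number_on_file = logical(), attends_other_facilities = logical(),
    art_start_date = as.Date(character())
  )
}

empty_visits <- function() {
  tibble::tibble(
    client_id = character(), facility_id = character(),
    scheduled_date = as.Date(character()), attended_date = as.Date(character()),
    regimen_code = character(), vl_value = numeric(),
    vl_date = as.Date(character()), tb_symptom_count = integer()
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
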