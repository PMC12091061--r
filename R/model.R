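# Imbalance-corrected boosting classifier scoring each visit for the risk
# that the next scheduled visit is missed.

#' Model configuration
#'
#' @param algorithm `"adaboost"` (adaptive boosting of depth-1 decision
#'   stumps, the primary algorithm) or `"gradient_boost"` (delegates to
#'   xgboost as an optional alternative).
#' @param n_estimators Number of boosting rounds (default 200, the library
#'   default for the named algorithm).
#' @param learning_rate Positive shrinkage applied to each round's weight.
#' @param rebalance Class-rebalancing mode applied to the training set:
#'   `"downsample"` the majority class to the minority size, `"upsample"` the
#'   minority with replacement to the majority size, or `"none"`.
#' @param test_fraction Fraction of visits held out for testing, in (0, 1).
#' @param split_unit `"visit"` (visits split independently; clients may
#'   straddle sets, mirroring the visit-level split design),
#'   `"client"` (leakage-safe: no client appears in both sets), or
#'   `"time"` (hold out the most recent `test_months` of visits).
#' @param test_months Hold-out window in months for `split_unit = "time"`.
#' @param top_k_features Optional count for parsimonious retraining on the
#'   top-ranked features.
#' @param seed Integer seed governing splitting, rebalancing and training.
#' @return A list of class `model_config`.
#' @export
model_config <- function(algorithm = c("adaboost", "gradient_boost"),
                         n_estimators = 200, learning_rate = 1.0,
                         rebalance = c("downsample", "upsample", "none"),
                         test_fraction = 0.2,
                         split_unit = c("visit", "client", "time"),
                         test_months = 4, top_k_features = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm)
  rebalance <- match.arg(rebalance)
  split_unit <- match.arg(split_unit)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  }
  if (n_estimators < 1 || learning_rate <= 0) {
    stop("n_estimators must be >= 1 and learning_rate > 0", call. = FALSE)
  }
  structure(
    list(algorithm = algorithm, n_estimators = as.integer(n_estimators),
         learning_rate = learning_rate, rebalance = rebalance,
         test_fraction = test_fraction, split_unit = split_unit,
         test_months = test_months, top_k_features = top_k_features,
         seed = as.integer(seed)),
    class = "model_config"
  )
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Split featurized visits into training and test sets
#'
#' Only visits with an observed next-visit outcome (`iit_next_visit` not
#' absent) are split. The visit-level split is stratified by outcome;
#' the client-level split keeps every client's visits together; the
#' time-based split holds out the most recent months of visits.
#' Deterministic given `config$seed`.
#'
#' @param fv Feature tibble from [build_features()] with `iit_next_visit`.
#' @param config A [model_config()].
#' @return A list with tibbles `train` and `test`.
#' @export
split_train_test <- function(fv, config) {
  fv <- fv[!is.na(fv$iit_next_visit), ]
  n_pos <- sum(fv$iit_next_visit)
  n_neg <- sum(!fv$iit_next_visit)
  if (config$split_unit == "visit" && (n_pos < 2 || n_neg < 2)) {
    stop("too few outcomes in a class to stratify the split", call. = FALSE)
  }
  with_seed(config$seed, {
    if (config$split_unit == "visit") {
      test_idx <- unlist(lapply(split(seq_len(nrow(fv)), fv$iit_next_visit),
                                function(idx) {
        sample(idx, round(length(idx) * config$test_fraction))
      }))
    } else if (config$split_unit == "client") {
      ids <- unique(fv$client_id)
      test_ids <- sample(ids, round(length(ids) * config$test_fraction))
      test_idx <- which(fv$client_id %in% test_ids)
    } else { # time
      cutoff <- max(fv$scheduled_date) %m-% months(config$test_months)
      test_idx <- which(fv$scheduled_date > cutoff)
    }
    list(train = fv[-test_idx, ], test = fv[test_idx, ])
  })
}

#' Rebalance a training set's outcome classes
#'
#' Random down-sampling reduces the majority class to the minority-class
#' size; up-sampling resamples the minority class with replacement up to the
#' majority size. Class counts are equal afterward. The test set is never
#' touched.
#'
#' @param train Training tibble with `iit_next_visit`.
#' @param mode `"downsample"`, `"upsample"`, or `"none"`.
#' @param seed Integer seed.
#' @return The rebalanced tibble.
#' @export
rebalance <- function(train, mode = c("downsample", "upsample", "none"),
                      seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "none") return(train)
  y <- train$iit_next_visit
  if (length(unique(y)) < 2) {
    stop("cannot rebalance a single-class training set", call. = FALSE)
  }
  pos <- which(y)
  neg <- which(!y)
  minority <- if (length(pos) <= length(neg)) pos else neg
  majority <- if (length(pos) <= length(neg)) neg else pos
  with_seed(seed, {
    idx <- if (mode == "downsample") {
      c(minority, sample(majority, length(minority)))
    } else {
      c(majority, sample(minority, length(majority), replace = TRUE))
    }
    train[sort(idx), ]
  })
}

stump_control <- function() {
  rpart::rpart.control(maxdepth = 1, minsplit = 2, minbucket = 1, cp = 0,
                       xval = 0, maxcompete = 0, maxsurrogate = 0,
                       usesurrogate = 0)
}

#' Train the boosting classifier
#'
#' Fits AdaBoost (discrete boosting of depth-1 decision stumps): at each
#' round a weighted stump is fit, its weighted error determines its vote
#' weight `alpha = lr * 0.5 * log((1 - err) / err)`, and misclassified
#' observations are up-weighted. The scorer maps a feature vector to a risk
#' score in \[0, 1\] via the logistic transform of the normalized weighted-vote
#' margin, monotone in predicted risk. With
#' `algorithm = "gradient_boost"` an xgboost logistic model is fit instead.
#' Deterministic given `config$seed`.
#'
#' @param train Rebalanced training tibble (features plus `iit_next_visit`),
#'   or an encoded list from [encode_for_model()].
#' @param config A [model_config()].
#' @return A fitted scorer of class `iit_scorer`.
#' @export
train_classifier <- function(train, config) {
  if (is.data.frame(train)) {
    enc <- encode_for_model(train)
  } else {
    enc <- train
  }
  x <- enc$x
  y <- enc$y
  if (is.null(y) || anyNA(y)) {
    stop("training data must carry complete iit_next_visit labels",
         call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop("non-finite values in encoded features", call. = FALSE)
  }
  if (config$algorithm == "gradient_boost") {
    if (!requireNamespace("xgboost", quietly = TRUE)) {
      stop("algorithm 'gradient_boost' requires the xgboost package",
           call. = FALSE)
    }
    booster <- with_seed(config$seed, xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    eta = config$learning_rate, max_depth = 3,
                    nthread = 1, seed = config$seed),
      data = xgboost::xgb.DMatrix(x, label = as.numeric(y), nthread = 1),
      nrounds = config$n_estimators, verbose = 0
    ))
    return(structure(list(algorithm = "gradient_boost", booster = booster,
                          metadata = enc$metadata, config = config),
                     class = "iit_scorer"))
  }
  n <- nrow(x)
  w <- rep(1 / n, n)
  yf <- factor(y, levels = c(FALSE, TRUE))
  df <- data.frame(x, check.names = FALSE)
  stumps <- list()
  alphas <- numeric(0)
  with_seed(config$seed, {
    for (m in seq_len(config$n_estimators)) {
      fit <- rpart::rpart(.y ~ ., data = cbind(df, .y = yf), weights = w,
                          method = "class", control = stump_control())
      pred <- stats::predict(fit, df, type = "class")
      mis <- pred != yf
      err <- sum(w[mis])
      if (err >= 0.5) break
      err <- max(err, 1e-10)
      alpha <- config$learning_rate * 0.5 * log((1 - err) / err)
      stumps[[length(stumps) + 1L]] <- fit
      alphas[length(alphas) + 1L] <- alpha
      if (err <= 1e-10) break
      w <- w * exp(alpha * ifelse(mis, 1, -1))
      w <- w / sum(w)
    }
  })
  if (length(stumps) == 0) {
    # no stump beat chance (e.g. constant features): fall back to the
    # training prevalence as a constant scorer
    base <- mean(y)
    return(structure(list(algorithm = "adaboost", stumps = list(),
                          alphas = numeric(0), constant = base,
                          metadata = enc$metadata, config = config),
                     class = "iit_scorer"))
  }
  structure(list(algorithm = "adaboost", stumps = stumps, alphas = alphas,
                 constant = NULL, metadata = enc$metadata, config = config),
            class = "iit_scorer")
}

#' Score visits with a fitted classifier
#'
#' Produces one probability-like risk score in \[0, 1\] per visit: the
#' likelihood that the next scheduled visit will not be attended on time.
#' Encoding reuses the training column metadata; a column mismatch is an
#' error. Deterministic.
#'
#' @param scorer Fitted `iit_scorer`.
#' @param fv Feature tibble (or encoded list) to score.
#' @return Numeric vector of scores.
#' @export
score_visits <- function(scorer, fv) {
  enc <- if (is.data.frame(fv)) encode_for_model(fv, scorer$metadata) else fv
  x <- enc$x
  if (!identical(colnames(x), encoded_colnames(scorer))) {
    stop("column mismatch between scorer and features", call. = FALSE)
  }
  if (scorer$algorithm == "gradient_boost") {
    dm <- xgboost::xgb.DMatrix(x, nthread = 1)
    return(as.numeric(stats::predict(scorer$booster, dm)))
  }
  if (length(scorer$stumps) == 0) {
    return(rep(scorer$constant, nrow(x)))
  }
  df <- data.frame(x, check.names = FALSE)
  margin <- rep(0, nrow(x))
  for (m in seq_along(scorer$stumps)) {
    h <- as.numeric(stats::predict(scorer$stumps[[m]], df, type = "class") ==
                      "TRUE")
    margin <- margin + scorer$alphas[m] * (2 * h - 1)
  }
  margin <- margin / sum(scorer$alphas)
  stats::plogis(2 * margin)
}

encoded_colnames <- function(scorer) {
  md <- scorer$metadata
  nms <- character(0)
  for (nm in md$feature_cols) {
    if (nm %in% names(md$levels)) {
      nms <- c(nms, paste0(nm, "_", md$levels[[nm]]), paste0(nm, "_other"),
               paste0(nm, "_missing"))
    } else {
      nms <- c(nms, nm, paste0(nm, "_missing"))
    }
  }
  nms
}

#' Evaluate a scorer on held-out visits
#'
#' Confusion-matrix metrics at a fixed score threshold plus threshold-free
#' AUC: accuracy, sensitivity, specificity, positive and negative predictive
#' value, and the counts entering each.
#'
#' @param scorer Fitted `iit_scorer`.
#' @param test Held-out feature tibble with observed `iit_next_visit`.
#' @param threshold Score threshold for a positive (IIT) prediction,
#'   default 0.5.
#' @return A list of class `model_metrics`.
#' @export
evaluate <- function(scorer, test, threshold = 0.5) {
  test <- test[!is.na(test$iit_next_visit), ]
  y <- test$iit_next_visit
  if (length(unique(y)) < 2) {
    stop("test set lacks both outcome classes: AUC undefined", call. = FALSE)
  }
  scores <- score_visits(scorer, test)
  pred <- scores > threshold
  tp <- sum(pred & y); fp <- sum(pred & !y)
  fn <- sum(!pred & y); tn <- sum(!pred & !y)
  auc <- as.numeric(pROC::auc(
    response = y, predictor = scores, levels = c(FALSE, TRUE),
    direction = "<", quiet = TRUE
  ))
  structure(list(
    accuracy = (tp + tn) / length(y),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    auc = auc,
    n_test = length(y),
    n_positive_predictions = tp + fp,
    n_negative_predictions = tn + fn
  ), class = "model_metrics")
}

#' Rank features by importance
#'
#' For AdaBoost, each stump's split variable accrues that stump's vote
#' weight (`alpha`); one-hot and missingness columns are aggregated back to
#' their source feature. For gradient boosting, xgboost's gain importance is
#' aggregated the same way. Ranking is deterministic given the training
#' seed.
#'
#' @param scorer Fitted `iit_scorer`.
#' @return A tibble with `feature` and `importance`, sorted descending.
#' @export
feature_importance <- function(scorer) {
  md <- scorer$metadata
  base_of <- function(col) {
    for (nm in md$feature_cols) {
      if (col == nm || startsWith(col, paste0(nm, "_"))) return(nm)
    }
    col
  }
  imp <- stats::setNames(numeric(length(md$feature_cols)), md$feature_cols)
  if (scorer$algorithm == "gradient_boost") {
    tab <- xgboost::xgb.importance(model = scorer$booster)
    for (i in seq_len(nrow(tab))) {
      b <- base_of(tab$Feature[i])
      imp[b] <- imp[b] + tab$Gain[i]
    }
  } else {
    for (m in seq_along(scorer$stumps)) {
      fr <- scorer$stumps[[m]]$frame
      if (nrow(fr) > 1) {
        var <- as.character(fr$var[1])
        b <- base_of(var)
        imp[b] <- imp[b] + scorer$alphas[m]
      }
    }
  }
  tibble::tibble(feature = names(imp), importance = as.numeric(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$feature)
}

#' Reduce a feature frame to the top-k most important features
#'
#' @param fv Feature tibble.
#' @param importance Ranking from [feature_importance()].
#' @param k Number of features to keep (at most the number available).
#' @return `fv` restricted to identifier columns plus the top `k` features.
#' @export
select_top_k <- function(fv, importance, k) {
  avail <- intersect(importance$feature, names(fv))
  if (k > length(avail)) {
    stop("k exceeds the number of available features (", length(avail), ")",
         call. = FALSE)
  }
  keep <- utils::head(avail, k)
  fv[c(intersect(feature_id_cols(), names(fv)), keep)]
}

#' Bootstrap stability of feature selection and performance
#'
#' Refits the full split/rebalance/train pipeline on `B` bootstrap resamples
#' of the visits and reports, per feature, the fraction of refits in which
#' it enters the top-k by importance, and the 5th/50th/95th percentiles of
#' each evaluation metric.
#'
#' @param fv Feature tibble with `iit_next_visit`.
#' @param config A [model_config()]; `top_k_features` (default 11) defines
#'   the selection set.
#' @param B Number of bootstrap refits (>= 2).
#' @return A list with tibbles `selection_frequency` and `metric_quantiles`.
#' @export
bootstrap_stability <- function(fv, config, B) {
  if (B < 2) stop("B must be >= 2", call. = FALSE)
  k <- config$top_k_features %||% 11L
  fv <- fv[!is.na(fv$iit_next_visit), ]
  sel <- list()
  mets <- list()
  for (b in seq_len(B)) {
    cfg_b <- config
    cfg_b$seed <- as.integer((config$seed + 7919 * b) %% 2147483647)
    boot <- with_seed(cfg_b$seed, fv[sample.int(nrow(fv), replace = TRUE), ])
    parts <- split_train_test(boot, cfg_b)
    tr <- rebalance(parts$train, cfg_b$rebalance, seed = cfg_b$seed)
    scorer <- train_classifier(tr, cfg_b)
    imp <- feature_importance(scorer)
    sel[[b]] <- utils::head(imp$feature, k)
    m <- evaluate(scorer, parts$test)
    mets[[b]] <- tibble::tibble(
      metric = c("accuracy", "sensitivity", "specificity", "ppv", "npv", "auc"),
      value = c(m$accuracy, m$sensitivity, m$specificity, m$ppv, m$npv, m$auc)
    )
  }
  all_feats <- setdiff(names(fv), feature_id_cols())
  freq <- vapply(all_feats, function(f) {
    mean(vapply(sel, function(s) f %in% s, logical(1)))
  }, numeric(1))
  qtab <- dplyr::bind_rows(mets) |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      q05 = stats::quantile(.data$value, 0.05, na.rm = TRUE),
      q50 = stats::quantile(.data$value, 0.50, na.rm = TRUE),
      q95 = stats::quantile(.data$value, 0.95, na.rm = TRUE),
      .groups = "drop"
    )
  list(
    selection_frequency = tibble::tibble(
      feature = names(freq), frequency = as.numeric(freq)
    ) |> dplyr::arrange(dplyr::desc(.data$frequency), .data$feature),
    metric_quantiles = qtab
  )
}
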