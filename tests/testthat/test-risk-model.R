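# Splitting, rebalancing, boosting, scoring, evaluation, importance,
# bootstrap stability.

fake_features <- function(n_pos = 20, n_neg = 80, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    client_id = sprintf("C%04d", sample(1:40, n_pos + n_neg, replace = TRUE)),
    scheduled_date = as.Date("2020-01-01") + sample(0:720, n_pos + n_neg,
                                                    replace = TRUE),
    f1 = rnorm(n_pos + n_neg),
    f2 = rnorm(n_pos + n_neg),
    iit_next_visit = rep(c(TRUE, FALSE), c(n_pos, n_neg))
  ))
}

test_that("visit-level splits honour the test fraction and the seed", {
  fv <- fake_features()
  cfg <- model_config(test_fraction = 0.2, seed = 5)
  parts <- split_train_test(fv, cfg)
  expect_identical(nrow(parts$train), 80L)
  expect_identical(nrow(parts$test), 20L)
  again <- split_train_test(fv, cfg)
  expect_identical(parts$train, again$train)
  expect_identical(parts$test, again$test)
  expect_error(
    split_train_test(fv[c(1, 21:40), ], cfg),
    "too few"
  )
})

test_that("client-level splits keep every client on one side", {
  fv <- fake_features(50, 150)
  parts <- split_train_test(fv, model_config(split_unit = "client", seed = 2))
  expect_length(intersect(parts$train$client_id, parts$test$client_id), 0)
  expect_identical(nrow(parts$train) + nrow(parts$test), nrow(fv))
})

test_that("the time-based split holds out the most recent months", {
  fv <- fake_features(50, 150)
  parts <- split_train_test(fv, model_config(split_unit = "time",
                                             test_months = 4))
  expect_gt(min(parts$test$scheduled_date), max(parts$train$scheduled_date))
})

test_that("rebalancing equalizes class counts and modes behave as stated", {
  fv <- fake_features(100, 900)
  down <- rebalance(fv, "downsample", seed = 3)
  expect_identical(as.integer(table(down$iit_next_visit)), c(100L, 100L))
  up <- rebalance(fv, "upsample", seed = 3)
  expect_identical(as.integer(table(up$iit_next_visit)), c(900L, 900L))
  expect_identical(rebalance(fv, "none"), fv)
  expect_error(rebalance(fv[fv$iit_next_visit, ], "downsample"),
               "single-class")
  # upsampling only adds copies of existing minority rows
  expect_true(all(up$f1[up$iit_next_visit] %in% fv$f1[fv$iit_next_visit]))
})

test_that("a linearly separable problem is classified perfectly", {
  withr::with_seed(11, {
    n <- 200
    y <- rep(c(TRUE, FALSE), each = n / 2)
    fv <- tibble::tibble(
      client_id = sprintf("C%03d", 1:n),
      f1 = ifelse(y, 5, -5) + rnorm(n, 0, 0.3),
      iit_next_visit = y
    )
  })
  cfg <- model_config(n_estimators = 10, seed = 4)
  parts <- split_train_test(fv, cfg)
  scorer <- train_classifier(parts$train, cfg)
  m <- evaluate(scorer, parts$test)
  expect_identical(m$sensitivity, 1)
  expect_identical(m$specificity, 1)
  expect_identical(m$auc, 1)
})

test_that("randomly shuffled labels score near-chance AUC", {
  co <- default_cohort()
  fv <- co$features[!is.na(co$features$iit_next_visit), ]
  fv$iit_next_visit <- withr::with_seed(88, sample(fv$iit_next_visit))
  cfg <- model_config(n_estimators = 40, seed = 2)
  parts <- split_train_test(fv, cfg)
  scorer <- train_classifier(rebalance(parts$train, "downsample", 2), cfg)
  m <- evaluate(scorer, parts$test)
  # null band: about 3 SE of the Mann-Whitney AUC at this test size
  expect_lt(abs(m$auc - 0.5), 0.1)
})

test_that("strong injected covariate effects yield informative discrimination", {
  sc <- signal_cohort()
  expect_gt(nrow(sc$features), 5000)
  expect_gt(sc$metrics$auc, 0.6)
})

test_that("scores are probability-like, deterministic, and constant on constant features", {
  sc <- signal_cohort()
  s <- sc$scores
  expect_true(all(s >= 0 & s <= 1))
  expect_identical(s, score_visits(sc$scorer, sc$features))
  const <- tibble::tibble(
    client_id = c("A", "B"),
    f1 = c(1, 1), f2 = c(2, 2),
    iit_next_visit = c(TRUE, FALSE)
  )
  cs <- train_classifier(const, model_config(n_estimators = 5, seed = 1))
  expect_length(unique(score_visits(cs, const)), 1L)
})

test_that("high-propensity carriers stochastically dominate in score", {
  sc <- signal_cohort()
  carriers <- sc$cohort$clients$client_id[
    sc$cohort$clients$attends_other_facilities
  ]
  in_grp <- sc$features$client_id %in% carriers
  w <- wilcox.test(sc$scores[in_grp], sc$scores[!in_grp],
                   alternative = "greater")
  expect_lt(w$p.value, 0.01)
})

test_that("confusion-matrix metrics match hand arithmetic", {
  scorer <- prediction_scorer()
  # TP=3, FP=1, FN=2, TN=4 via the prediction feature
  test <- tibble::tibble(
    client_id = sprintf("X%02d", 1:10),
    f = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
    iit_next_visit = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE,
                       FALSE, FALSE, FALSE, FALSE)
  )
  m <- evaluate(scorer, test)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$npv, 2 / 3)
  expect_identical(m$n_test, 10L)
  expect_identical(m$n_positive_predictions, 4L)
  expect_identical(m$n_negative_predictions, 6L)
})

test_that("metric identities hold against a brute-force confusion oracle", {
  scorer <- prediction_scorer()
  withr::with_seed(303, {
    for (i in 1:10) {
      n <- 40
      pred <- sample(c(0, 1), n, replace = TRUE)
      y <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (length(unique(y)) < 2) next
      test <- tibble::tibble(client_id = sprintf("r%02d", 1:n), f = pred,
                             iit_next_visit = y)
      m <- evaluate(scorer, test)
      tp <- sum(pred == 1 & y); fp <- sum(pred == 1 & !y)
      fn <- sum(pred == 0 & y); tn <- sum(pred == 0 & !y)
      expect_equal(m$accuracy, (tp + tn) / n)
      if (tp + fp > 0) expect_equal(m$ppv * (tp + fp), tp)
      expect_identical(m$n_positive_predictions + m$n_negative_predictions,
                       m$n_test)
    }
  })
})

test_that("AUC is invariant under strictly monotone transformation of the margin", {
  sc <- signal_cohort()
  boosted <- sc$scorer
  boosted$alphas <- boosted$alphas * 3  # monotone rescaling of the vote margin
  m1 <- evaluate(sc$scorer, sc$parts$test)
  m2 <- evaluate(boosted, sc$parts$test)
  expect_false(identical(score_visits(boosted, sc$parts$test),
                         score_visits(sc$scorer, sc$parts$test)))
  expect_equal(m1$auc, m2$auc)
})

test_that("single-class test sets make the AUC an explicit error", {
  scorer <- prediction_scorer()
  test <- tibble::tibble(client_id = "a", f = 1, iit_next_visit = TRUE)
  expect_error(evaluate(scorer, test), "AUC undefined")
})

test_that("a lone signal-bearing feature ranks first in importance", {
  withr::with_seed(21, {
    n <- 600
    y <- runif(n) < 0.3
    fv <- tibble::tibble(
      client_id = sprintf("C%03d", 1:n),
      signal = ifelse(y, 1, 0) + rnorm(n, 0, 0.1),
      noise1 = rnorm(n), noise2 = rnorm(n)
    )
    fv$iit_next_visit <- y
  })
  scorer <- train_classifier(fv, model_config(n_estimators = 20, seed = 3))
  imp <- feature_importance(scorer)
  expect_identical(imp$feature[1], "signal")
})

test_that("top-k selection reduces the frame and retrains cleanly", {
  sc <- signal_cohort()
  imp <- feature_importance(sc$scorer)
  all_feats <- setdiff(names(sc$features), iitriage:::feature_id_cols())
  full <- select_top_k(sc$features, imp, length(all_feats))
  expect_setequal(names(full), names(sc$features))
  expect_error(select_top_k(sc$features, imp, length(all_feats) + 1), "exceeds")
  cfg <- model_config(n_estimators = 30, seed = 9, top_k_features = 11)
  reduced <- select_top_k(sc$features, imp, 11)
  parts <- split_train_test(reduced, cfg)
  scorer11 <- train_classifier(rebalance(parts$train, "downsample", 9), cfg)
  m <- evaluate(scorer11, parts$test)
  expect_true(is.finite(m$auc))
})

test_that("bootstrap stability reports valid frequencies and ordered quantiles", {
  withr::with_seed(41, {
    n <- 400
    y <- runif(n) < 0.3
    fv <- tibble::tibble(
      client_id = sprintf("C%03d", sample(1:50, n, replace = TRUE)),
      scheduled_date = as.Date("2020-01-01") + sample(0:700, n, replace = TRUE),
      signal = ifelse(y, 1, 0) + rnorm(n, 0, 0.1),
      noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n)
    )
    fv$iit_next_visit <- y
  })
  cfg <- model_config(n_estimators = 15, seed = 6, top_k_features = 2)
  bs <- bootstrap_stability(fv, cfg, B = 10)
  expect_true(all(bs$selection_frequency$frequency >= 0 &
                    bs$selection_frequency$frequency <= 1))
  expect_true(all(bs$metric_quantiles$q05 <= bs$metric_quantiles$q50 + 1e-12))
  expect_true(all(bs$metric_quantiles$q50 <= bs$metric_quantiles$q95 + 1e-12))
  # the planted signal enters the top-k in every refit
  expect_equal(
    bs$selection_frequency$frequency[bs$selection_frequency$feature == "signal"],
    1
  )
  expect_error(bootstrap_stability(fv, cfg, B = 1), "B must be")
  # identical call, identical result
  expect_identical(bs, bootstrap_stability(fv, cfg, B = 10))
})

test_that("gradient boosting is available as an alternative algorithm", {
  skip_if_not_installed("xgboost")
  fv <- fake_features(60, 140)
  cfg <- model_config(algorithm = "gradient_boost", n_estimators = 20,
                      seed = 2)
  parts <- split_train_test(fv, cfg)
  scorer <- train_classifier(parts$train, cfg)
  s <- score_visits(scorer, parts$test)
  expect_true(all(s >= 0 & s <= 1))
  expect_true(is.finite(evaluate(scorer, parts$test)$auc))
})
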