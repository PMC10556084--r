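# Minimal synthetic feature table: n site-years, each with days 60..120 and
# two features under the caller's control.
toy_table <- function(event_doys, feature_fun, doys = 60:120) {
  do.call(rbind, lapply(seq_along(event_doys), function(i) {
    data.frame(
      site_year = sprintf("S%02d", i),
      doy = doys,
      feat = feature_fun(i, doys),
      stringsAsFactors = FALSE
    )
  }))
}

test_that("correlation screen retains direct proxies and drops noise", {
  ev_doys <- c(70, 80, 90, 100, 110, 75, 85, 95, 105, 115)
  events <- data.frame(
    site_year = sprintf("S%02d", seq_along(ev_doys)), event_doy = ev_doys
  )
  # feature constant per site-year and equal to its event DOY -> r = 1
  ft <- toy_table(ev_doys, function(i, d) rep(ev_doys[i], length(d)))
  sc <- correlation_screen(ft, events, ref_doy = 60)
  expect_equal(unname(sc$r["feat"]), 1)
  expect_true("feat" %in% sc$retained)
  # negated proxy -> r = -1, still retained on |r|
  ft_neg <- toy_table(ev_doys, function(i, d) rep(-ev_doys[i], length(d)))
  sc_neg <- correlation_screen(ft_neg, events, ref_doy = 60)
  expect_equal(unname(sc_neg$r["feat"]), -1)
  expect_true("feat" %in% sc_neg$retained)
  expect_error(correlation_screen(ft[1:61, ], events[1, ], ref_doy = 60), ">= 3")
})

test_that("independent noise features fall below the screening cutoff", {
  n <- 38
  ev_doys <- withr::with_seed(31, sample(65:115, n, replace = TRUE))
  events <- data.frame(
    site_year = sprintf("S%02d", seq_len(n)), event_doy = ev_doys
  )
  noise <- withr::with_seed(32, rnorm(n))
  ft <- toy_table(ev_doys, function(i, d) rep(noise[i], length(d)))
  sc <- correlation_screen(ft, events, ref_doy = 60)
  expect_lt(abs(sc$r["feat"]), 0.3)
  expect_false("feat" %in% sc$retained)
  # a zero-variance feature is dropped with a warning
  ft$flat <- 1
  expect_warning(sc2 <- correlation_screen(ft, events, ref_doy = 60), "flat")
  expect_false("flat" %in% sc2$retained)
})

test_that("binary assembly labels exactly the event day inside the window", {
  w <- stage_window("budburst")
  events <- data.frame(site_year = c("A", "B"), event_doy = c(95, 80))
  ft <- rbind(
    data.frame(site_year = "A", doy = 60:110, feat = 1),
    data.frame(site_year = "B", doy = 60:110, feat = 2)
  )
  ds <- assemble_binary(ft, events, w)
  expect_equal(nrow(ds), 2 * 36) # DOY 65..100 inclusive
  expect_equal(sum(ds$label), 2)
  expect_equal(ds$doy[ds$label == 1 & ds$site_year == "A"], 95)
  # an event outside the window drops its site-year with a warning
  events2 <- data.frame(site_year = c("A", "B"), event_doy = c(120, 80))
  expect_warning(ds2 <- assemble_binary(ft, events2, w), "A")
  expect_equal(unique(ds2$site_year), "B")
  expect_equal(sum(ds2$label), 1)
})

test_that("rebalancing reaches the target ratio deterministically", {
  ds <- data.frame(
    site_year = "S", doy = 1:33, feat = rnorm(33),
    label = c(rep(1, 3), rep(0, 30))
  )
  over <- rebalance(ds, "oversample", seed = 9)
  expect_equal(sum(over$label == 1), 30)
  expect_equal(sum(over$label == 0), 30)
  under <- rebalance(ds, "undersample", seed = 9)
  expect_equal(sum(under$label == 1), 3)
  expect_equal(sum(under$label == 0), 3)
  # bit-identical under the same seed
  expect_identical(rebalance(ds, "oversample", seed = 9), over)
  expect_identical(rebalance(ds, "undersample", seed = 9), under)
  one_class <- ds[ds$label == 0, ]
  expect_error(rebalance(one_class, "oversample"), "both classes")
})

test_that("train/test splits are disjoint, complete and reproducible", {
  ds <- data.frame(
    site_year = rep(sprintf("S%02d", 1:10), each = 10),
    doy = rep(1:10, 10), feat = rnorm(100),
    label = rep(c(1, rep(0, 9)), 10)
  )
  sp <- split_train_test(ds, seed = 4)
  expect_equal(nrow(sp$train), 80)
  expect_equal(nrow(sp$test), 20)
  key <- function(d) paste(d$site_year, d$doy)
  expect_length(intersect(key(sp$train), key(sp$test)), 0)
  expect_setequal(c(key(sp$train), key(sp$test)), key(ds))
  sp2 <- split_train_test(ds, seed = 4)
  expect_identical(sp2$train, sp$train)
  # grouped mode holds out whole site-years by name
  spg <- split_train_test(ds, grouped = TRUE, holdout = c("S02", "S07"))
  expect_setequal(unique(spg$test$site_year), c("S02", "S07"))
  expect_equal(nrow(spg$test), 20)
  expect_false(any(spg$train$site_year %in% c("S02", "S07")))
})

test_that("LOOCV matches an explicit leave-one-out loop", {
  ds <- data.frame(
    site_year = "S", doy = 1:8, feat = c(1, 2, 3, 4, 5, 6, 7, 8),
    label = c(0, 0, 0, 0, 1, 1, 1, 1)
  )
  # deterministic learner: predicted probability = mean training label,
  # recording every training-set size seen
  sizes <- integer(0)
  mean_learner <- structure(
    list(
      name = "mean",
      fit = function(x, y) {
        sizes <<- c(sizes, length(y))
        mean(y)
      },
      predict = function(model, x) rep(model, nrow(x))
    ),
    class = "vc_learner"
  )
  cv <- loocv(ds, mean_learner, "feat")
  expect_equal(sizes, rep(7, 8)) # 8 folds, each trained on n-1 rows
  manual <- vapply(
    1:8, function(i) mean(ds$label[-i]), numeric(1)
  )
  expect_equal(cv$scores, manual)
  expect_equal(cv$n_failed, 0)
  # a failing fold is recorded, not fatal
  flaky <- structure(
    list(
      name = "flaky",
      fit = function(x, y) if (x[1, 1] == 2) stop("boom") else mean(y),
      predict = function(model, x) rep(model, nrow(x))
    ),
    class = "vc_learner"
  )
  cv2 <- loocv(ds, flaky, "feat")
  expect_equal(cv2$n_failed, 1)
  expect_true(is.na(cv2$scores[1])) # fold 1 trains with row 2 first
  expect_error(loocv(ds[1, ], mean_learner, "feat"), "n >= 2")
})

test_that("metrics match the confusion-matrix formulas", {
  # scores engineered to give TP=8, FP=2, FN=2, TN=88 at threshold 0.5
  labels <- c(rep(1, 10), rep(0, 90))
  scores <- c(
    rep(0.9, 8), rep(0.1, 2), # positives: 8 caught, 2 missed
    rep(0.9, 2), rep(0.1, 88) # negatives: 2 false alarms
  )
  m <- evaluate(scores, labels, threshold = 0.5)
  expect_equal(c(m$tp, m$fp, m$fn, m$tn), c(8, 2, 2, 88))
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.8)
  expect_equal(m$accuracy, 0.96)
  expect_equal(m$f1, 8 / (8 + (2 + 2) / 2))
  # perfectly separating scores give AUC 1
  sep <- evaluate(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(sep$auc, 1)
  # one-class labels: AUC undefined
  expect_true(is.na(evaluate(c(0.2, 0.7), c(1, 1))$auc))
  expect_error(evaluate(1:3 / 10, c(0, 1)), "equal length")
})

test_that("rank-based AUC equals the concordant-pair fraction", {
  for (i in 1:25) {
    labels <- withr::with_seed(100 + i, rbinom(20, 1, 0.4))
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    # coarse scores force ties
    scores <- withr::with_seed(200 + i, round(runif(20), 1))
    expect_equal(
      evaluate(scores, labels)$auc,
      auc_bruteforce(scores, labels)
    )
  }
})

test_that("AUC agrees with an external ROC implementation", {
  skip_if_not_installed("pROC")
  labels <- withr::with_seed(7, rbinom(50, 1, 0.3))
  scores <- withr::with_seed(8, runif(50))
  expect_equal(
    evaluate(scores, labels)$auc,
    as.numeric(pROC::auc(pROC::roc(
      labels, scores,
      quiet = TRUE, direction = "<", levels = c(0, 1)
    )))
  )
})

test_that("event dates are extracted as the mean of reliable days", {
  w <- stage_window("budburst")
  probs <- data.frame(doy = 65:100, prob = 0)
  probs$prob[probs$doy %in% c(92, 96)] <- 0.8
  expect_equal(extract_event_date(probs, w), 94)
  probs2 <- data.frame(doy = 140:175, prob = 0)
  probs2$prob[probs2$doy == 150] <- 0.6
  expect_equal(extract_event_date(probs2, stage_window("flowering")), 150)
  # nothing reliable: no prediction
  none <- data.frame(doy = 65:100, prob = 0.2)
  expect_true(is.na(extract_event_date(none, w)))
  bad <- data.frame(doy = 65:70, prob = c(0.5, 1.2, 0, 0, 0, 0))
  expect_error(extract_event_date(bad, w), "probabilities")
})

test_that("RMSE in days handles exclusions and exact cases", {
  expect_equal(as.numeric(rmse_days(100, 102)), 2)
  expect_equal(as.numeric(rmse_days(c(100, 104), c(100, 104))), 0)
  expect_equal(as.numeric(rmse_days(c(100, 104), c(102, 104))), sqrt(2))
  r <- rmse_days(c(100, NA, 104), c(102, 110, 104))
  expect_equal(as.numeric(r), sqrt(2))
  expect_equal(attr(r, "n_excluded"), 1)
  expect_error(rmse_days(NA_integer_, 100), "no usable")
})

test_that("every learner in the benchmark set fits and scores", {
  withr::with_seed(55, {
    n <- 120
    x <- cbind(a = rnorm(n), b = rnorm(n))
    y <- as.integer(x[, 1] + 0.3 * rnorm(n) > 0)
  })
  ds <- data.frame(site_year = "S", doy = 1:120, a = x[, 1], b = x[, 2],
    label = y
  )
  for (nm in c("xgboost", "random_forest", "svm", "knn")) {
    lr <- make_learner(nm, seed = 5)
    m <- lr$fit(as.matrix(ds[, c("a", "b")]), ds$label)
    p <- lr$predict(m, as.matrix(ds[, c("a", "b")]))
    expect_length(p, n)
    expect_true(all(p >= 0 & p <= 1))
    # a separable direction must be learnable well above chance
    expect_gt(evaluate(p, ds$label)$auc, 0.8)
  }
})
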