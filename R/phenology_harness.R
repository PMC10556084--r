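# Windowed binary-event classification harness for phenology dates.
#
# Each day of a stage-specific window is a row labelled 1 on the observed
# event date and 0 otherwise; a classifier trained on daily weather features
# scores every day, and the predicted date is the average of above-threshold
# days. Class imbalance (one positive among dozens of negatives per
# site-year) is handled by over/under-sampling of the training partition.

#' Phenological stage window
#'
#' Default day-of-year windows within which each stage is searched:
#' budburst 65-100, flowering 140-175, veraison 190-230.
#'
#' @param stage One of `"budburst"`, `"flowering"`, `"veraison"`.
#' @param doy_start,doy_end Window bounds (defaults per stage).
#' @return Object of class `stage_window`.
#' @export
stage_window <- function(stage = c("budburst", "flowering", "veraison"),
                         doy_start = NULL, doy_end = NULL) {
  stage <- match.arg(stage)
  defaults <- list(
    budburst = c(65, 100), flowering = c(140, 175), veraison = c(190, 230)
  )
  b <- defaults[[stage]]
  if (is.null(doy_start)) doy_start <- b[1]
  if (is.null(doy_end)) doy_end <- b[2]
  if (doy_start >= doy_end) stop("doy_start must precede doy_end", call. = FALSE)
  structure(
    list(stage = stage, doy_start = doy_start, doy_end = doy_end),
    class = "stage_window"
  )
}

#' Screen features by correlation with the event date
#'
#' Pearson r of each feature against the event day of year, one point per
#' site-year; features with |r| above the cutoff are retained. By default
#' each feature is taken as of a common reference day (`ref_doy`), so the
#' correlation across site-years reflects between-site climate differences;
#' with `ref_doy = NULL` the feature is taken as of each site-year's own
#' event date, in which case any cumulative feature also carries the
#' mechanical growth of a cumulant with elapsed time.
#'
#' @param feature_table Stacked [phenology_features()] tables with a
#'   `site_year` column.
#' @param events `data.frame` with `site_year` and `event_doy`.
#' @param cutoff Absolute-correlation retention cutoff (default 0.3).
#' @param ref_doy Common day of year at which features are sampled, or
#'   `NULL` for sampling at each observed event date.
#' @return List with `r` (named vector over features) and `retained`
#'   (character). Zero-variance features are dropped with a warning.
#' @export
correlation_screen <- function(feature_table, events, cutoff = 0.3,
                               ref_doy = NULL) {
  if (nrow(events) < 3) stop("need >= 3 site-years", call. = FALSE)
  feats <- setdiff(names(feature_table), c("site_year", "date", "doy"))
  at_event <- if (is.null(ref_doy)) {
    merge(events, feature_table,
      by.x = c("site_year", "event_doy"), by.y = c("site_year", "doy")
    )
  } else {
    merge(events, feature_table[feature_table$doy == ref_doy, , drop = FALSE],
      by = "site_year"
    )
  }
  r <- vapply(feats, function(f) {
    v <- at_event[[f]]
    if (stats::sd(v) == 0 || stats::sd(at_event$event_doy) == 0) {
      return(NA_real_)
    }
    stats::cor(v, at_event$event_doy)
  }, numeric(1))
  if (anyNA(r)) {
    warning(
      "zero-variance feature(s) dropped: ",
      paste(names(r)[is.na(r)], collapse = ", "),
      call. = FALSE
    )
  }
  list(r = r, retained = names(r)[!is.na(r) & abs(r) > cutoff])
}

#' Assemble the windowed binary dataset
#'
#' One row per (site-year, day) inside the stage window, labelled 1 only on
#' the observed event day. Site-years whose event falls outside the window
#' are excluded with a warning.
#'
#' @param feature_table Stacked feature tables with `site_year`.
#' @param events `data.frame` with `site_year` and `event_doy`.
#' @param window A [stage_window()].
#' @return Object of class `binary_dataset`: data.frame with `site_year`,
#'   `doy`, `label` and feature columns; attribute `window`.
#' @export
assemble_binary <- function(feature_table, events, window) {
  inside <- events$event_doy >= window$doy_start &
    events$event_doy <= window$doy_end
  if (any(!inside)) {
    warning(
      "event outside ", window$stage, " window, site-year(s) excluded: ",
      paste(events$site_year[!inside], collapse = ", "),
      call. = FALSE
    )
  }
  events <- events[inside, , drop = FALSE]
  rows <- feature_table[
    feature_table$site_year %in% events$site_year &
      feature_table$doy >= window$doy_start &
      feature_table$doy <= window$doy_end, ,
    drop = FALSE
  ]
  ev <- stats::setNames(events$event_doy, events$site_year)
  rows$label <- as.integer(rows$doy == ev[as.character(rows$site_year)])
  rows$date <- NULL
  rownames(rows) <- NULL
  structure(rows, class = c("binary_dataset", "data.frame"), window = window)
}

#' Rebalance a binary dataset
#'
#' Oversampling replicates positive rows (sampling with replacement) until
#' the positive:negative ratio reaches `target_ratio`; undersampling thins
#' the negative class instead. Deterministic under a fixed seed.
#'
#' @param dataset A `binary_dataset` (or data.frame with a `label` column).
#' @param strategy `"oversample"` or `"undersample"`.
#' @param target_ratio Desired positives / negatives (default 1).
#' @param seed Integer RNG seed.
#' @return Rebalanced dataset of the same class.
#' @export
rebalance <- function(dataset, strategy = c("oversample", "undersample"),
                      target_ratio = 1, seed = 1) {
  strategy <- match.arg(strategy)
  pos <- which(dataset$label == 1)
  neg <- which(dataset$label == 0)
  if (length(pos) == 0 || length(neg) == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  keep <- withr::with_seed(seed, {
    if (strategy == "oversample") {
      n_target <- round(target_ratio * length(neg))
      extra <- if (n_target > length(pos)) {
        sample(pos, n_target - length(pos), replace = TRUE)
      } else {
        integer(0)
      }
      c(pos, extra, neg)
    } else {
      n_target <- round(length(pos) / target_ratio)
      c(pos, sample(neg, min(n_target, length(neg))))
    }
  })
  out <- dataset[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "window") <- attr(dataset, "window")
  out
}

#' Train/test split
#'
#' Random 80:20 row split, or grouped mode holding out whole site-years so
#' no site-year straddles the partition (the configuration used when whole
#' vineyards serve as the test set).
#'
#' @param dataset A `binary_dataset`.
#' @param ratio Training fraction (default 0.8).
#' @param seed Integer RNG seed.
#' @param grouped Hold out whole site-years instead of rows.
#' @param holdout In grouped mode, either the number of site-years to hold
#'   out (sampled under `seed`) or a character vector naming them.
#' @return List with `train` and `test` data frames (disjoint, union = input).
#' @export
split_train_test <- function(dataset, ratio = 0.8, seed = 1,
                             grouped = FALSE, holdout = NULL) {
  if (nrow(dataset) < 5) stop("need n >= 5 rows", call. = FALSE)
  if (grouped) {
    units <- unique(dataset$site_year)
    held <- if (is.character(holdout)) {
      holdout
    } else {
      k <- if (is.null(holdout)) max(1, round((1 - ratio) * length(units))) else holdout
      withr::with_seed(seed, sample(units, k))
    }
    test_idx <- dataset$site_year %in% held
  } else {
    n <- nrow(dataset)
    n_train <- ceiling(ratio * n)
    train_rows <- withr::with_seed(seed, sample.int(n, n_train))
    test_idx <- !(seq_len(n) %in% train_rows)
  }
  keep_attr <- function(d) {
    rownames(d) <- NULL
    attr(d, "window") <- attr(dataset, "window")
    d
  }
  list(
    train = keep_attr(dataset[!test_idx, , drop = FALSE]),
    test = keep_attr(dataset[test_idx, , drop = FALSE])
  )
}

feature_matrix <- function(dataset, features) {
  as.matrix(dataset[, features, drop = FALSE])
}

#' Pluggable classification learners
#'
#' Uniform fit/predict closures over the benchmark set: gradient-boosted
#' trees (default), random forest, support-vector machine and k-nearest
#' neighbours. `fit(x, y)` takes a numeric matrix and 0/1 labels;
#' `predict(model, x)` returns positive-class probabilities.
#'
#' @param name One of `"xgboost"`, `"random_forest"`, `"svm"`, `"knn"`.
#' @param seed Integer seed forwarded to stochastic learners.
#' @param ... Tuning parameters passed to the underlying engine.
#' @return Object of class `vc_learner`: list with `name`, `fit`, `predict`.
#' @export
make_learner <- function(name = c("xgboost", "random_forest", "svm", "knn"),
                         seed = 1, ...) {
  name <- match.arg(name)
  dots <- list(...)
  fit_fun <- switch(name,
    xgboost = function(x, y) {
      params <- utils::modifyList(
        list(
          objective = "binary:logistic", max_depth = 4, eta = 0.1,
          nthread = 1
        ),
        dots[setdiff(names(dots), "nrounds")]
      )
      nrounds <- if (is.null(dots$nrounds)) 150 else dots$nrounds
      withr::with_seed(seed, xgboost::xgb.train(
        params = params,
        data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
        nrounds = nrounds, verbose = 0
      ))
    },
    random_forest = function(x, y) {
      args <- utils::modifyList(
        list(x = x, y = factor(y, levels = c(0, 1)), ntree = 300),
        dots
      )
      withr::with_seed(seed, do.call(randomForest::randomForest, args))
    },
    svm = function(x, y) {
      args <- utils::modifyList(
        list(
          x = x, y = factor(y, levels = c(0, 1)),
          probability = TRUE, kernel = "radial"
        ),
        dots
      )
      withr::with_seed(seed, do.call(e1071::svm, args))
    },
    knn = function(x, y) {
      k <- if (is.null(dots$k)) 5 else dots$k
      mu <- colMeans(x)
      sd <- apply(x, 2, stats::sd)
      sd[sd == 0] <- 1
      list(x = scale(x, mu, sd), y = factor(y, levels = c(0, 1)),
           mu = mu, sd = sd, k = k)
    }
  )
  predict_fun <- switch(name,
    xgboost = function(model, x) {
      stats::predict(model, xgboost::xgb.DMatrix(x, nthread = 1))
    },
    random_forest = function(model, x) {
      stats::predict(model, x, type = "prob")[, "1"]
    },
    svm = function(model, x) {
      p <- stats::predict(model, x, probability = TRUE)
      attr(p, "probabilities")[, "1"]
    },
    knn = function(model, x) {
      xs <- scale(x, model$mu, model$sd)
      pred <- withr::with_seed(seed, {
        class::knn(model$x, xs, model$y, k = model$k, prob = TRUE)
      })
      p_win <- attr(pred, "prob")
      ifelse(pred == "1", p_win, 1 - p_win)
    }
  )
  structure(
    list(name = name, fit = fit_fun, predict = predict_fun),
    class = "vc_learner"
  )
}

#' Leave-one-out cross-validation
#'
#' n folds; fold i trains on the other n-1 rows and scores row i. A learner
#' failure on a fold marks that fold failed and the run continues.
#'
#' @param dataset A `binary_dataset` (training partition).
#' @param learner A [make_learner()] object.
#' @param features Feature columns to use.
#' @return List with `scores` (out-of-fold probabilities, `NA` for failed
#'   folds), `labels` and `n_failed`.
#' @export
loocv <- function(dataset, learner, features) {
  n <- nrow(dataset)
  if (n < 2) stop("LOOCV needs n >= 2", call. = FALSE)
  x <- feature_matrix(dataset, features)
  y <- dataset$label
  scores <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    scores[i] <- tryCatch(
      {
        m <- learner$fit(x[-i, , drop = FALSE], y[-i])
        as.numeric(learner$predict(m, x[i, , drop = FALSE]))
      },
      error = function(e) NA_real_
    )
  }
  list(scores = scores, labels = y, n_failed = sum(is.na(scores)))
}

#' Classification metrics at a threshold
#'
#' Confusion counts at the given probability threshold plus the derived
#' metrics: `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `accuracy = (TP+TN)/n`, `F1 = TP/(TP + (FP+FN)/2)` and threshold-free
#' AUC by the rank (Mann-Whitney) statistic with ties counted one half.
#'
#' @param scores Predicted positive-class probabilities.
#' @param labels 0/1 labels.
#' @param threshold Classification threshold (score >= threshold is
#'   positive).
#' @return Object of class `eval_metrics`: list of `tp`, `tn`, `fp`, `fn`,
#'   `precision`, `recall`, `accuracy`, `f1`, `auc` (NA when only one class
#'   is present). `NA` scores (failed folds) are dropped pairwise.
#' @export
evaluate <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  ok <- !is.na(scores)
  scores <- scores[ok]
  labels <- labels[ok]
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  auc <- if (n1 == 0 || n0 == 0) {
    NA_real_
  } else {
    r <- rank(scores) # ties averaged -> ties count 1/2
    (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  structure(
    list(
      tp = tp, tn = tn, fp = fp, fn = fn,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      accuracy = (tp + tn) / length(labels),
      f1 = if (2 * tp + fp + fn > 0) tp / (tp + (fp + fn) / 2) else NA_real_,
      auc = auc
    ),
    class = "eval_metrics"
  )
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(
    paste0(
      "TP %d  TN %d  FP %d  FN %d\n",
      "precision %.3f  recall %.3f  accuracy %.3f  F1 %.3f  AUC %s\n"
    ),
    x$tp, x$tn, x$fp, x$fn, x$precision, x$recall, x$accuracy, x$f1,
    ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))
  ))
  invisible(x)
}

#' Extract a predicted event date from daily probabilities
#'
#' The predicted day of year is the mean of all in-window days whose
#' probability reaches the reliability threshold, rounded to the nearest
#' whole day; `NA` (no prediction) when no day qualifies.
#'
#' @param daily_probabilities `data.frame` with `doy` and `prob` covering
#'   the window.
#' @param window A [stage_window()].
#' @param threshold Reliability threshold on the probability.
#' @return Integer DOY or `NA_integer_`.
#' @export
extract_event_date <- function(daily_probabilities, window, threshold = 0.5) {
  p <- daily_probabilities$prob
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  inw <- daily_probabilities$doy >= window$doy_start &
    daily_probabilities$doy <= window$doy_end
  hits <- daily_probabilities$doy[inw & !is.na(p) & p >= threshold]
  if (length(hits) == 0) {
    return(NA_integer_)
  }
  as.integer(round(mean(hits)))
}

#' RMSE of predicted event dates, in days
#'
#' @param predicted_doys,observed_doys Paired vectors; pairs where the
#'   prediction is `NA` (no prediction) are excluded and counted.
#' @return Numeric with attribute `n_excluded`. Errors if no pair remains.
#' @export
rmse_days <- function(predicted_doys, observed_doys) {
  if (length(predicted_doys) != length(observed_doys)) {
    stop("paired vectors required", call. = FALSE)
  }
  ok <- !is.na(predicted_doys) & !is.na(observed_doys)
  if (!any(ok)) stop("no usable prediction pairs", call. = FALSE)
  out <- sqrt(mean((predicted_doys[ok] - observed_doys[ok])^2))
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' End-to-end phenology experiment
#'
#' The full harness on a multi-site-year feature table: correlation screen,
#' windowed binary assembly, grouped train/test split, training-partition
#' rebalancing, classifier fit, per-site-year date extraction and
#' RMSE-in-days scoring. Resampling follows the split and touches only the
#' training partition, so no test-row information leaks into training.
#'
#' @param feature_table Stacked [phenology_features()] tables with
#'   `site_year`.
#' @param events `data.frame` with `site_year`, `event_doy`.
#' @param window A [stage_window()].
#' @param learner A [make_learner()] object.
#' @param screen_cutoff Correlation-screen cutoff; screened-out features are
#'   not fed to the classifier.
#' @param strategy Rebalancing strategy for the training partition.
#' @param threshold Date-extraction reliability threshold.
#' @param holdout Number (or names) of site-years held out for testing.
#' @param seed Integer seed driving split, rebalance and learner.
#' @param run_loocv Also compute leave-one-out validation metrics on the
#'   training partition (slower).
#' @return List: `screen`, `features`, `model`, `train_metrics`,
#'   `valid_metrics` (LOOCV, if requested), `test_metrics`, `predictions`
#'   (data.frame site_year, observed_doy, predicted_doy), `rmse_days`.
#' @export
run_phenology_experiment <- function(feature_table, events, window,
                                     learner = make_learner("xgboost"),
                                     screen_cutoff = 0.3,
                                     strategy = "oversample",
                                     threshold = 0.5,
                                     holdout = NULL, seed = 1,
                                     run_loocv = FALSE) {
  screen <- correlation_screen(
    feature_table, events, screen_cutoff,
    ref_doy = window$doy_start - 1
  )
  feats <- screen$retained
  if (length(feats) == 0) {
    stop("no feature survived the correlation screen", call. = FALSE)
  }
  dataset <- assemble_binary(feature_table, events, window)
  split <- split_train_test(dataset,
    seed = seed, grouped = TRUE, holdout = holdout
  )
  train <- rebalance(split$train, strategy, seed = seed)
  model <- learner$fit(feature_matrix(train, feats), train$label)
  train_scores <- learner$predict(model, feature_matrix(train, feats))
  valid_metrics <- if (run_loocv) {
    cv <- loocv(train, learner, feats)
    evaluate(cv$scores, cv$labels, threshold)
  } else {
    NULL
  }
  test <- split$test
  test_scores <- learner$predict(model, feature_matrix(test, feats))
  held <- unique(test$site_year)
  obs <- stats::setNames(events$event_doy, events$site_year)
  preds <- vapply(held, function(sy) {
    sel <- test$site_year == sy
    extract_event_date(
      data.frame(doy = test$doy[sel], prob = test_scores[sel]),
      window, threshold
    )
  }, integer(1))
  pred_df <- data.frame(
    site_year = held,
    observed_doy = as.integer(obs[as.character(held)]),
    predicted_doy = preds
  )
  list(
    screen = screen,
    features = feats,
    model = model,
    train_metrics = evaluate(train_scores, train$label, threshold),
    valid_metrics = valid_metrics,
    test_metrics = evaluate(test_scores, test$label, threshold),
    predictions = pred_df,
    rmse_days = rmse_days(pred_df$predicted_doy, pred_df$observed_doy)
  )
}

#' Benchmark the learner set on one stage
#'
#' Runs [run_phenology_experiment()] for each learner and lays the metrics
#' out as one row per (model, phase) with the metric columns, the layout
#' used to compare classifier families per stage.
#'
#' @inheritParams run_phenology_experiment
#' @param learners Character vector of learner names.
#' @return `data.frame`: `model`, `phase` (train/valid/test), `auc`,
#'   `accuracy`, `recall`, `precision`, `f1`, `rmse_days`.
#' @export
benchmark_phenology <- function(feature_table, events, window,
                                learners = c(
                                  "xgboost", "random_forest", "svm", "knn"
                                ),
                                seed = 1, ...) {
  rows <- list()
  for (nm in learners) {
    res <- run_phenology_experiment(
      feature_table, events, window,
      learner = make_learner(nm, seed = seed), seed = seed, ...
    )
    for (phase in c("train_metrics", "valid_metrics", "test_metrics")) {
      m <- res[[phase]]
      if (is.null(m)) next
      rows[[length(rows) + 1]] <- data.frame(
        model = nm,
        phase = sub("_metrics", "", phase),
        auc = m$auc, accuracy = m$accuracy, recall = m$recall,
        precision = m$precision, f1 = m$f1,
        rmse_days = if (phase == "test_metrics") {
          as.numeric(res$rmse_days)
        } else {
          NA_real_
        }
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
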