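#' Annual demand series
#'
#' An ordered (year, value) series with consecutive years and non-negative
#' values; the input to the forecast-evaluation harness.
#'
#' @param year integer years, strictly increasing by 1.
#' @param value non-negative values (e.g. annual patient visits).
#' @return data frame of class `phc_series` with columns `year`, `value`.
#' @export
annual_series <- function(year, value) {
  year <- as.integer(year)
  value <- as.numeric(value)
  stopifnot(length(year) == length(value), length(year) >= 2L)
  if (any(diff(year) != 1L)) {
    stop("years must be consecutive (strictly increasing by 1)", call. = FALSE)
  }
  if (any(!is.finite(value) | value < 0)) {
    stop("series values must be finite and non-negative", call. = FALSE)
  }
  structure(data.frame(year = year, value = value),
            class = c("phc_series", "data.frame"))
}

#' Sequential train/test split
#'
#' Splits the series so that the last `n_test` observations form the test
#' tail; no shuffling, order preserved. With a 33-year series and
#' `n_test = 4` this is the 29/4 protocol (train through year 29, test the
#' final four years).
#'
#' @param series an [annual_series()].
#' @param n_test number of trailing test years (>= 1, < length).
#' @return list with elements `train` and `test`, both `phc_series`.
#' @export
sequential_split <- function(series, n_test) {
  stopifnot(inherits(series, "phc_series"))
  n <- nrow(series)
  n_test <- as.integer(n_test)
  if (n_test < 1L || n_test >= n) {
    stop("n_test must satisfy 1 <= n_test < length(series)", call. = FALSE)
  }
  idx <- seq_len(n - n_test)
  list(train = annual_series(series$year[idx], series$value[idx]),
       test = annual_series(series$year[-idx], series$value[-idx]))
}

#' Lagged supervised pairs from a series
#'
#' Builds (value_{t-lag} -> value_t) pairs; features use only past values,
#' so no pair's feature year reaches its target year.
#'
#' @param series an [annual_series()].
#' @param lag positive lag in years (default 1: single-time-step features).
#' @return data frame `feature_year, target_year, feature, target`.
#' @export
make_lag_features <- function(series, lag = 1L) {
  stopifnot(inherits(series, "phc_series"))
  lag <- as.integer(lag)
  stopifnot(lag >= 1L)
  n <- nrow(series)
  if (n < lag + 1L) stop("series too short for this lag", call. = FALSE)
  i <- seq_len(n - lag)
  data.frame(feature_year = series$year[i],
             target_year = series$year[i + lag],
             feature = series$value[i],
             target = series$value[i + lag])
}

#' Forecast error metrics
#'
#' \eqn{MAE = \frac1n \sum |y_i - \hat y_i|},
#' \eqn{MAPE = \frac{100}{n} \sum |(y_i - \hat y_i)/y_i|} (percent),
#' \eqn{MSE = \frac1n \sum (y_i - \hat y_i)^2}, \eqn{RMSE = \sqrt{MSE}}.
#'
#' @param y true values (all non-zero; MAPE is undefined otherwise).
#' @param yhat predictions, same length.
#' @return list of class `phc_forecast_eval`: `n`, `y`, `yhat`, `MAE`,
#'   `MAPE`, `MSE`, `RMSE`.
#' @examples
#' evaluate_forecast(c(100, 200), c(110, 180))  # MAE 15, MAPE 10%
#' @export
evaluate_forecast <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  if (length(y) < 1L) stop("need at least one point", call. = FALSE)
  if (any(y == 0)) stop("MAPE undefined: true value of zero", call. = FALSE)
  err <- y - yhat
  mse <- mean(err^2)
  structure(list(n = length(y), y = y, yhat = yhat,
                 MAE = mean(abs(err)),
                 MAPE = 100 * mean(abs(err / y)),
                 MSE = mse,
                 RMSE = sqrt(mse)),
            class = "phc_forecast_eval")
}

#' @export
print.phc_forecast_eval <- function(x, ...) {
  cat(sprintf("forecast evaluation on %d points: MAE %.4f | MAPE %.2f%% | MSE %.4f | RMSE %.4f\n",
              x$n, x$MAE, x$MAPE, x$MSE, x$RMSE))
  invisible(x)
}

#' Regressor contracts
#'
#' The harness treats regressors as pluggable fit/predict contracts: a list
#' with a `name`, `fit(x, y, seed)` returning a model, and
#' `predict(model, x)` returning predictions. The built-in set keeps the
#' harness fully testable with no machine-learning dependency:
#' `regressor_persistence()` predicts the feature itself (last observed
#' value) and `regressor_linear()` fits ordinary least squares. Wrappers for
#' random forest (`randomForest`), support-vector regression (`e1071`) and
#' the lasso (`glmnet`) are provided when those packages are installed.
#'
#' @param ntree number of trees for the random forest.
#' @return a regressor contract (class `phc_regressor`).
#' @name regressors
NULL

new_regressor <- function(name, fit, predict) {
  structure(list(name = name, fit = fit, predict = predict),
            class = "phc_regressor")
}

#' @rdname regressors
#' @export
regressor_persistence <- function() {
  new_regressor("persistence",
                fit = function(x, y, seed) list(),
                predict = function(model, x) x)
}

#' @rdname regressors
#' @export
regressor_linear <- function() {
  new_regressor("linear",
                fit = function(x, y, seed) stats::lm(y ~ x, data.frame(x = x, y = y)),
                predict = function(model, x)
                  unname(stats::predict(model, data.frame(x = x))))
}

#' @rdname regressors
#' @export
regressor_rf <- function(ntree = 500L) {
  if (!requireNamespace("randomForest", quietly = TRUE)) {
    stop("package 'randomForest' is required for regressor_rf()", call. = FALSE)
  }
  new_regressor("random_forest",
                fit = function(x, y, seed) {
                  set.seed(seed)
                  randomForest::randomForest(data.frame(x = x), y, ntree = ntree)
                },
                predict = function(model, x)
                  unname(stats::predict(model, data.frame(x = x))))
}

#' @rdname regressors
#' @export
regressor_svr <- function() {
  if (!requireNamespace("e1071", quietly = TRUE)) {
    stop("package 'e1071' is required for regressor_svr()", call. = FALSE)
  }
  new_regressor("svr",
                fit = function(x, y, seed)
                  e1071::svm(data.frame(x = x), y, type = "eps-regression"),
                predict = function(model, x)
                  unname(stats::predict(model, data.frame(x = x))))
}

#' @rdname regressors
#' @export
regressor_lasso <- function() {
  if (!requireNamespace("glmnet", quietly = TRUE)) {
    stop("package 'glmnet' is required for regressor_lasso()", call. = FALSE)
  }
  # glmnet needs >= 2 columns; duplicate the single lag feature
  new_regressor("lasso",
                fit = function(x, y, seed) {
                  set.seed(seed)
                  glmnet::cv.glmnet(cbind(x = x, x2 = x), y, alpha = 1,
                                    nfolds = 5)
                },
                predict = function(model, x)
                  as.numeric(stats::predict(model, cbind(x = x, x2 = x),
                                            s = "lambda.min")))
}

#' Compare regressors on the same held-out tail
#'
#' Applies [sequential_split()], fits each contract on the training lag
#' pairs, predicts the test tail one step ahead from the preceding observed
#' value, and evaluates all four metrics on the identical test years. A
#' failing regressor is marked failed; the others are unaffected.
#'
#' @param series an [annual_series()].
#' @param regressors named list of regressor contracts (see [regressors]).
#' @param n_test trailing test length.
#' @param lag feature lag in years.
#' @param seed integer seed threaded to stochastic regressors.
#' @return data frame `model, status, MAE, MAPE, MSE, RMSE` plus per-metric
#'   rank columns (`rank_RMSE`, ...; rank 1 = best).
#' @export
compare_models <- function(series, regressors, n_test, lag = 1L, seed = 1L) {
  stopifnot(length(regressors) >= 1L)
  if (is.null(names(regressors)) || any(names(regressors) == "")) {
    names(regressors) <- vapply(regressors, `[[`, "", "name")
  }
  split <- sequential_split(series, n_test)
  train_pairs <- make_lag_features(split$train, lag)
  # test features: the observed value `lag` years before each test year
  feat_idx <- match(split$test$year - lag, series$year)
  stopifnot(!anyNA(feat_idx))
  x_test <- series$value[feat_idx]
  y_test <- split$test$value

  rows <- lapply(names(regressors), function(nm) {
    reg <- regressors[[nm]]
    res <- tryCatch({
      model <- reg$fit(train_pairs$feature, train_pairs$target, seed)
      ev <- evaluate_forecast(y_test, reg$predict(model, x_test))
      data.frame(model = nm, status = "ok", MAE = ev$MAE, MAPE = ev$MAPE,
                 MSE = ev$MSE, RMSE = ev$RMSE, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(model = nm, status = paste("failed:", conditionMessage(e)),
                 MAE = NA_real_, MAPE = NA_real_, MSE = NA_real_,
                 RMSE = NA_real_, stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  for (mcol in c("MAE", "MAPE", "MSE", "RMSE")) {
    out[[paste0("rank_", mcol)]] <- rank(out[[mcol]], na.last = "keep",
                                         ties.method = "min")
  }
  rownames(out) <- NULL
  out
}

#' Direct multi-step forecast
#'
#' Direct strategy (default): one model per horizon step h, each trained on
#' (value_{t-h} -> value_t) pairs and applied to the last observed value, so
#' no prediction is ever fed back as an input. The recursive strategy (one
#' 1-step model iterated on its own predictions) is available for
#' comparison.
#'
#' @param series an [annual_series()].
#' @param horizon number of future years (>= 1).
#' @param regressor a regressor contract (see [regressors]).
#' @param strategy `"direct"` or `"recursive"`.
#' @param seed integer seed threaded to stochastic regressors.
#' @return data frame `year, prediction, strategy, seed`.
#' @export
direct_multistep_forecast <- function(series, horizon, regressor,
                                      strategy = c("direct", "recursive"),
                                      seed = 1L) {
  stopifnot(inherits(series, "phc_series"))
  strategy <- match.arg(strategy)
  horizon <- as.integer(horizon)
  if (horizon < 1L) stop("horizon must be at least 1", call. = FALSE)
  last_year <- series$year[nrow(series)]
  last_value <- series$value[nrow(series)]
  years <- last_year + seq_len(horizon)

  pred <- numeric(horizon)
  if (strategy == "direct") {
    for (h in seq_len(horizon)) {
      pairs <- make_lag_features(series, lag = h)
      model <- regressor$fit(pairs$feature, pairs$target, seed)
      pred[h] <- regressor$predict(model, last_value)
    }
  } else {
    pairs <- make_lag_features(series, lag = 1L)
    model <- regressor$fit(pairs$feature, pairs$target, seed)
    current <- last_value
    for (h in seq_len(horizon)) {
      current <- regressor$predict(model, current)
      pred[h] <- current
    }
  }
  data.frame(year = years, prediction = pred, strategy = strategy,
             seed = as.integer(seed))
}
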