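test_that("series validation enforces consecutive years and non-negative values", {
  expect_s3_class(annual_series(2000:2004, 1:5), "phc_series")
  expect_error(annual_series(c(2000, 2002, 2003), 1:3), "consecutive")
  expect_error(annual_series(2000:2002, c(1, -1, 2)), "non-negative")
})

test_that("sequential split keeps order and concatenates back to the original", {
  s <- generate_series("linear", n_years = 33, noise = 0.1, seed = 5)
  sp <- sequential_split(s, 4)
  expect_equal(nrow(sp$train), 29)
  expect_equal(sp$train$year, 1990:2018)
  expect_equal(sp$test$year, 2019:2022)
  expect_equal(c(sp$train$value, sp$test$value), s$value)
  expect_error(sequential_split(s, 0), "n_test")
  expect_error(sequential_split(s, 33), "n_test")
})

test_that("lag features use only past values", {
  s <- annual_series(2001:2003, c(1, 2, 3))
  lf <- make_lag_features(s)
  expect_equal(lf$feature, c(1, 2))
  expect_equal(lf$target, c(2, 3))
  expect_true(all(lf$feature_year < lf$target_year))
  expect_error(make_lag_features(annual_series(2001:2002, c(1, 2)), lag = 2),
               "too short")
})

test_that("error metrics match hand arithmetic and the RMSE identity", {
  ev <- evaluate_forecast(c(100, 200), c(110, 180))
  expect_equal(ev$MAE, 15)
  expect_equal(ev$MAPE, 10)
  expect_equal(ev$MSE, 250)
  expect_equal(ev$RMSE, sqrt(250))
  one <- evaluate_forecast(2, 1)
  expect_equal(c(one$MAE, one$MAPE, one$MSE, one$RMSE), c(1, 50, 1, 1))
  perf <- evaluate_forecast(c(3, 4), c(3, 4))
  expect_equal(c(perf$MAE, perf$MAPE, perf$MSE, perf$RMSE), rep(0, 4))
  expect_error(evaluate_forecast(c(1, 0), c(1, 1)), "MAPE undefined")
  expect_error(evaluate_forecast(1:3, 1:2), "length mismatch")
})

test_that("metric scaling laws hold under common rescaling", {
  set.seed(7)
  y <- runif(10, 50, 100); yhat <- y + rnorm(10)
  a <- evaluate_forecast(y, yhat)
  b <- evaluate_forecast(3 * y, 3 * yhat)
  expect_equal(b$MAPE, a$MAPE)
  expect_equal(b$MAE, 3 * a$MAE)
  expect_equal(b$RMSE, 3 * a$RMSE)
  expect_equal(b$MSE, 9 * a$MSE)
  expect_equal(a$RMSE^2, a$MSE)
  expect_gte(a$RMSE, a$MAE)
})

test_that("compare_models evaluates all contracts on the identical tail", {
  s <- generate_series("linear", n_years = 20, noise = 0, seed = 1)
  tab <- compare_models(s, list(regressor_persistence(), regressor_linear()),
                        n_test = 4)
  expect_equal(tab$model, c("persistence", "linear"))
  expect_true(all(tab$status == "ok"))
  # on a noiseless linear trend OLS on the lag is exact, persistence is not
  expect_lt(tab$RMSE[tab$model == "linear"], 1e-8)
  expect_gt(tab$RMSE[tab$model == "persistence"], 0.1)
  expect_equal(tab$rank_RMSE, c(2L, 1L))

  # constant series: persistence is perfect
  cs <- annual_series(2000:2010, rep(5, 11))
  tab2 <- compare_models(cs, list(regressor_persistence()), n_test = 3)
  expect_equal(tab2$RMSE, 0)

  # a failing regressor does not poison the others
  broken <- structure(list(name = "broken",
                           fit = function(x, y, seed) stop("boom"),
                           predict = function(m, x) x),
                      class = "phc_regressor")
  tab3 <- compare_models(s, list(regressor_persistence(), broken), n_test = 4)
  expect_equal(tab3$status[1], "ok")
  expect_match(tab3$status[2], "failed")
  expect_true(is.na(tab3$RMSE[2]))
})

test_that("identical regressors give identical rows under a fixed seed", {
  s <- generate_series("logistic", n_years = 25, noise = 0.2, seed = 3)
  tab <- compare_models(s, list(a = regressor_linear(), b = regressor_linear()),
                        n_test = 4, seed = 11)
  expect_equal(tab$RMSE[1], tab$RMSE[2])
  expect_equal(tab$MAPE[1], tab$MAPE[2])
})

test_that("shuffling the test tail changes metrics but never the fitted model", {
  s <- generate_series("linear", n_years = 15, noise = 0.3, seed = 9)
  sp <- sequential_split(s, 4)
  pairs <- make_lag_features(sp$train)
  fit1 <- regressor_linear()$fit(pairs$feature, pairs$target, 1)
  shuffled <- s
  shuffled$value[12:15] <- rev(shuffled$value[12:15])
  sp2 <- sequential_split(shuffled, 4)
  pairs2 <- make_lag_features(sp2$train)
  fit2 <- regressor_linear()$fit(pairs2$feature, pairs2$target, 1)
  expect_equal(coef(fit1), coef(fit2))
})

test_that("direct multi-step differs from recursive on a curved series", {
  years <- 2000:2014
  s <- annual_series(years, 2 + 0.05 * (seq_along(years) - 1)^2)
  dir <- direct_multistep_forecast(s, 3, regressor_linear(), "direct")
  rec <- direct_multistep_forecast(s, 3, regressor_linear(), "recursive")
  expect_equal(dir$year, 2015:2017)
  expect_equal(nrow(dir), 3)
  expect_false(isTRUE(all.equal(dir$prediction, rec$prediction)))
  # persistence on a constant series: both strategies return the constant
  cs <- annual_series(2000:2009, rep(4, 10))
  d1 <- direct_multistep_forecast(cs, 1, regressor_persistence(), "direct")
  expect_equal(d1$prediction, 4)
  expect_error(direct_multistep_forecast(cs, 0, regressor_persistence()),
               "horizon")
})
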