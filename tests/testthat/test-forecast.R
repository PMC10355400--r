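# Sliding windows, the rolling-retrain scheme, clipping and forecast MAE.

.std_series <- function(n, seed = 1L, gappy_at = integer()) {
  set.seed(seed)
  h <- hours_from("2018-01-01 00:00", n)
  feats <- matrix(rnorm(5 * n), n, 5, dimnames = list(NULL,
                                                      c("T", "d", "v1", "v2", "v3")))
  feats[gappy_at, 1] <- NA
  SensorSeries(h, feats, standardized = TRUE)
}

test_that("window construction counts and ordering follow the contract", {
  s <- .std_series(50)
  w <- makeWindows(s, 24L)
  expect_identical(length(w$hours), 50L - 24L + 1L)
  expect_identical(w$hours[1], seriesHours(s)[24])
  expect_true(all(diff(as.numeric(w$hours)) > 0))
  expect_equal(w$X[1, , ], sensorFeatures(s)[1:24, ], ignore_attr = TRUE)

  w1 <- makeWindows(s, 1L)
  expect_identical(length(w1$hours), 50L)
  expect_identical(dim(w1$X)[2], 1L)

  expect_identical(length(makeWindows(.std_series(5), 24L)$hours), 0L)
  expect_error(makeWindows(SensorSeries(hours_from("2018-01-01 00:00", 3),
                                        matrix(0, 3, 5, dimnames = list(NULL,
                                          c("T", "d", "v1", "v2", "v3")))),
                           2L), "standardized")
})

test_that("one gappy hour removes exactly eta windows", {
  eta <- 6L
  full <- makeWindows(.std_series(60, seed = 2L), eta)
  gapped <- makeWindows(.std_series(60, seed = 2L, gappy_at = 30L), eta)
  expect_identical(length(full$hours) - length(gapped$hours), eta)
  lost <- setdiff(as.numeric(full$hours), as.numeric(gapped$hours))
  expect_identical(length(lost), 6L)
})

test_that("forecast MAE matches hand evaluation and requires overlap", {
  h <- hours_from("2018-01-01 00:00", 2)
  p <- ActivitySeries(h, c(0.2, 0.4))
  t <- ActivitySeries(h, c(0.3, 0.1))
  expect_equal(forecastMae(p, t), 0.2)
  expect_identical(forecastMae(p, p), 0)
  expect_equal(forecastMae(ActivitySeries(h, c(0, 0)),
                           ActivitySeries(h, c(1, 1))), 1)
  t2 <- ActivitySeries(hours_from("2019-01-01 00:00", 2), c(0.3, 0.1))
  expect_error(forecastMae(p, t2), "overlap")
})

test_that("the best-constant baseline is the median", {
  s <- ActivitySeries(hours_from("2018-01-01 00:00", 5),
                      c(0, 0, 0.2, 1, NA))
  bc <- bestConstantMae(s)
  expect_identical(bc$constant, 0.1)
  expect_equal(bc$mae, mean(abs(c(0, 0, 0.2, 1) - 0.1)))
})

test_that("rolling forecast learns a constant target, clips, and is seeded", {
  n <- 24 * 28
  set.seed(8)
  h <- hours_from("2018-01-01 00:00", n)
  feats <- matrix(rnorm(5 * n), n, 5,
                  dimnames = list(NULL, c("T", "d", "v1", "v2", "v3")))
  sens <- SensorSeries(h, feats)
  truth <- ActivitySeries(h, rep(0.7, n))
  cfg <- ForecastConfig(window_length = 6L, train_span = 336L,
                        predict_span = 168L, epochs = 30L, hidden_size = 8L,
                        seed = 3L)
  fc <- rollingForecast(sens, truth, cfg)
  v <- seriesValues(fc@predicted)
  expect_true(all(v >= 0 & v <= 1, na.rm = TRUE))
  expect_true(all(abs(v - 0.7) < 0.1, na.rm = TRUE))
  expect_identical(nrow(fc@weekly_log),
                   length(seq(336, n - 1, by = 168)))
  # weekly models are independent and fully reproducible from their seeds
  fc2 <- rollingForecast(sens, truth, cfg)
  expect_identical(seriesValues(fc2@predicted), v)
})

test_that("weeks with mostly-missing training targets are skipped", {
  n <- 24 * 10
  set.seed(9)
  h <- hours_from("2018-01-01 00:00", n)
  feats <- matrix(rnorm(5 * n), n, 5,
                  dimnames = list(NULL, c("T", "d", "v1", "v2", "v3")))
  vals <- rep(0.5, n); vals[1:170] <- NA
  cfg <- ForecastConfig(window_length = 6L, train_span = 168L,
                        predict_span = 24L, epochs = 2L, seed = 1L)
  expect_warning(
    fc <- rollingForecast(SensorSeries(h, feats), ActivitySeries(h, vals),
                          cfg),
    "skipped")
  expect_identical(fc@weekly_log$n_predicted[1], 0L)
})
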