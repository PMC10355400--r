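# Two-step median aggregation, feature assembly, standardization and gap
# policies.

test_that("hourly current aggregation matches the worked median example", {
  hour <- as.POSIXct("2018-01-01 12:00:00", tz = "UTC")
  ts <- hour + 60 * c(-30, -20, -10, 0, 10, 20)
  rec <- data.frame(timestamp = ts, value = c(1, 2, 3, 4, 5, 100))
  expect_identical(aggregateCurrent(rec, hour), 3.5)
  # constant series stays constant; empty window is missing
  expect_identical(aggregateCurrent(data.frame(timestamp = ts, value = 7),
                                    hour), 7)
  expect_true(is.na(aggregateCurrent(rec, hour + 7200)))
  expect_error(aggregateCurrent(rec, hour, "T"), "current components only")
})

test_that("two-step median equals the brute-force oracle on 1-second data", {
  set.seed(17)
  hour <- as.POSIXct("2018-03-01 06:00:00", tz = "UTC")
  for (i in 1:100) {
    n <- sample(50:400, 1)
    ts <- as.numeric(hour) + sort(runif(n, -1800, 1799))
    vals <- rnorm(n)
    rec <- data.frame(timestamp = as.POSIXct(ts, tz = "UTC",
                                             origin = "1970-01-01"),
                      value = vals)
    got <- aggregateCurrent(rec, hour)
    expect_equal(got, bf_two_step_median(ts, vals, hour), tolerance = 1e-12)
    # order invariance
    perm <- sample(n)
    expect_identical(aggregateCurrent(rec[perm, ], hour), got)
  }
})

test_that("feature assembly flags gappy hours and rejects duplicates", {
  h <- hours_from("2018-01-01 00:00", 3)
  s <- buildFeatureSeries(h, T = c(7, 7, 7), d = c(258, 258, 258),
                          v1 = c(0.1, NA, 0.2), v2 = rep(0, 3),
                          v3 = rep(0, 3))
  expect_identical(isGappy(s), c(FALSE, TRUE, FALSE))
  expect_error(buildFeatureSeries(h[c(1, 1, 2)], 1:3, 1:3, 1:3, 1:3, 1:3),
               "duplicated")
  empty <- buildFeatureSeries(h[0], numeric(), numeric(), numeric(),
                              numeric(), numeric())
  expect_identical(nrow(sensorFeatures(empty)), 0L)
})

test_that("standardization uses population moments and round-trips", {
  h <- hours_from("2018-01-01 00:00", 3)
  s <- buildFeatureSeries(h, T = c(1, 2, 3), d = c(1, 2, 3), v1 = c(1, 2, 3),
                          v2 = c(1, 2, 3), v3 = c(1, 2, 3))
  out <- standardizeSensors(s)
  expect_equal(sensorFeatures(out$series)[, "T"],
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  again <- standardizeSensors(out$series, params = list(
    mean = setNames(numeric(5), c("T", "d", "v1", "v2", "v3")),
    sd = setNames(rep(1, 5), c("T", "d", "v1", "v2", "v3"))))
  expect_equal(sensorFeatures(again$series), sensorFeatures(out$series),
               tolerance = 1e-12)
  back <- unstandardizeSensors(out$series, out$params)
  expect_equal(sensorFeatures(back), sensorFeatures(s), tolerance = 1e-10)
  szero <- buildFeatureSeries(h, T = c(1, 1, 1), d = c(1, 2, 3),
                              v1 = c(1, 2, 3), v2 = c(1, 2, 3),
                              v3 = c(1, 2, 3))
  expect_error(standardizeSensors(szero), "'T'")
})

test_that("standardization can be fitted on a window and applied later", {
  h <- hours_from("2018-01-01 00:00", 10)
  set.seed(5)
  s <- buildFeatureSeries(h, T = rnorm(10, 7), d = rnorm(10, 258),
                          v1 = rnorm(10), v2 = rnorm(10), v3 = rnorm(10))
  fit <- standardizeSensors(s, fit_hours = h[1:5])
  f <- sensorFeatures(fit$series)[1:5, ]
  expect_equal(colMeans(f), setNames(rep(0, 5), colnames(f)),
               tolerance = 1e-6)
  expect_equal(apply(f, 2, function(v) mean(v^2)),
               setNames(rep(1, 5), colnames(f)), tolerance = 1e-6)
})

test_that("gap policies fill short gaps and report long ones", {
  h <- hours_from("2018-01-01 00:00", 12)
  v <- rnorm(12)
  feats <- cbind(T = v, d = v, v1 = v, v2 = v, v3 = v)
  feats[3, "v2"] <- NA            # 1-hour gap
  feats[6:10, "v3"] <- NA         # 5-hour gap
  s <- SensorSeries(h, feats)
  clean <- fillGaps(SensorSeries(h, cbind(T = v, d = v, v1 = v, v2 = v,
                                          v3 = v)))
  expect_identical(nrow(clean$report), 0L)
  drop <- fillGaps(s, "drop_windows")
  expect_identical(sum(drop$report$status == "missing"), 6L)
  ff <- fillGaps(s, "ffill_limit", 3L)
  expect_identical(sensorFeatures(ff$series)[3, "v2"],
                   sensorFeatures(s)[2, "v2"])
  expect_true(all(is.na(sensorFeatures(ff$series)[6:10, "v3"])))
  expect_error(fillGaps(s, "interpolate"), "unknown gap policy")
})
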