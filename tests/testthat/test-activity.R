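# Weighted per-image activity, hourly windowing, the visibility filter,
# the penalty MAE and series stitching.

test_that("image activity implements the weighted mean with the indicator", {
  allpos <- mk_patchset(p = c(0.9, 0.2, 0.4), k_hat = 1L)
  expect_identical(imageActivity(allpos)$a, 1)

  two <- mk_patchset(p = c(0.5, 0.25), k_hat = c(1L, 0L))
  expect_equal(imageActivity(two)$a, 0.5 / 0.75)

  with_small <- mk_patchset(p = c(0.5, 0.05), k_hat = c(1L, 0L))
  expect_identical(imageActivity(with_small)$a, 1)   # indicator excludes p=0.05
  expect_identical(imageActivity(with_small)$n_patches, 1L)

  none <- mk_patchset(p = c(0.05, 0.02), k_hat = c(1L, 1L))
  expect_true(is.na(imageActivity(none)$a))

  mixed <- combinePatchSets(mk_patchset(0.5, k_hat = 1L, image_id = "a"),
                            mk_patchset(0.5, k_hat = 1L, image_id = "b"))
  expect_error(imageActivity(mixed), "multiple images")
})

test_that("hourly aggregation uses the half-open 30-minute window", {
  acts <- data.frame(
    timestamp = as.POSIXct(c("2018-01-03 10:10:00", "2018-01-03 10:40:00"),
                           tz = "UTC"),
    a = c(0.2, 0.8))
  s <- hourlySeries(acts, "C_r", "G1")
  expect_identical(format(seriesHours(s), "%H:%M"), c("10:00", "11:00"))
  expect_identical(seriesValues(s), c(0.2, 0.8))

  one <- hourlySeries(data.frame(
    timestamp = as.POSIXct("2018-01-03 10:00:00", tz = "UTC"), a = 0.4))
  expect_identical(seriesValues(one), 0.4)

  grid <- hours_from("2018-01-03 10:00", 3)
  sparse <- hourlySeries(acts, hours = grid)
  expect_true(is.na(seriesValues(sparse)[3]))   # empty window is NA, not 0

  cut <- hourlySeries(data.frame(
    timestamp = as.POSIXct(c("2019-04-06 23:00:00", "2019-04-07 00:10:00"),
                           tz = "UTC"), a = c(0.5, 0.9)),
    campaign = "G2", hours = hours_from("2019-04-06 23:00", 2))
  expect_identical(seriesValues(cut), c(0.5, NA))  # cutoff excludes the second
})

test_that("the visibility filter excludes strictly-below-threshold images", {
  rs <- data.frame(image_id = c("a", "b", "c"), pixels = c(0, 500, 1000))
  expect_identical(blueVisibilityFilter(rs, 0), c("a", "b", "c"))
  expect_identical(blueVisibilityFilter(rs, 500), c("b", "c"))  # at threshold kept
  expect_equal(blueVisibilityThreshold(rs, c("b", "c")), 0.25 * 750)
})

test_that("MAE with penalty covers all four presence cases", {
  pred <- data.frame(image_id = c("a", "b"), coral = "C_r", a = c(0.3, 0.6))
  truth <- data.frame(image_id = c("a", "b"), coral = "C_r", a = c(0.2, 0.8))
  expect_equal(maeWithPenalty(pred, truth), 0.15)
  expect_identical(maeWithPenalty(pred, pred), 0)
  # coral present in truth, nothing estimated -> error 1
  p2 <- data.frame(image_id = "a", coral = "C_r", a = NA_real_)
  t2 <- data.frame(image_id = "a", coral = "C_r", a = 0.7)
  expect_identical(maeWithPenalty(p2, t2), 1)
  # estimate where the coral is absent -> error 1
  expect_identical(maeWithPenalty(t2, p2), 1)
  # both agree the coral is absent -> 0
  expect_identical(maeWithPenalty(p2, p2), 0)
})

test_that("final series stitch partitions exactly at interval boundaries", {
  h1 <- hours_from("2018-01-01 00:00", 48)
  s1 <- ActivitySeries(h1, rep(0.2, 48))
  s2 <- ActivitySeries(h1, rep(0.8, 48))
  bounds <- as.POSIXct(c("2018-01-01 00:00:00", "2018-01-01 12:00:00",
                         "2018-01-03 00:00:00"), tz = "UTC")
  out <- assembleFinalSeries(list(s1, s2), bounds)
  v <- seriesValues(out)
  expect_identical(v[1:12], rep(0.2, 12))
  expect_identical(v[13:48], rep(0.8, 36))
  expect_error(assembleFinalSeries(list(s1, NULL), bounds), "unassigned")
  single <- assembleFinalSeries(list(s1), bounds[c(1, 3)])
  expect_identical(seriesValues(single), seriesValues(s1))
  expect_identical(selectModelPair(c(a = 0.02, b = 0.01, c = 0.03)), "b")
})
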