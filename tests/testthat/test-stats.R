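# Alignment, Spearman correlation with t-test, Gaussian smoothing and
# low-activity period detection.

test_that("series alignment keeps exactly the common present hours", {
  h <- hours_from("2018-01-01 00:00", 15)
  x <- ActivitySeries(h[1:10], c(runif(8), NA, 0.5))
  y <- ActivitySeries(h, runif(15))
  al <- alignSeries(x, y)
  expect_identical(al$N, 9L)
  expect_identical(as.numeric(al$hours), as.numeric(h[c(1:8, 10)]))
  z <- ActivitySeries(hours_from("2019-01-01 00:00", 4), runif(4))
  expect_error(alignSeries(x, z), "no overlapping")
})

test_that("spearman matches the definitional example set", {
  expect_identical(spearmanRho(1:7, (1:7)^3), 1)
  expect_identical(spearmanRho(1:7, rev(1:7)), -1)
  expect_equal(spearmanRho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(spearmanRho(rep(1, 5), 1:5), "constant")
  expect_error(spearmanRho(1:3, 1:4), "length")
})

test_that("the t-test follows its closed form and conventions", {
  tst <- spearmanTest(0.5, 27)
  expect_equal(tst$t, 0.5 * sqrt(25) / sqrt(0.75), tolerance = 1e-12)
  expect_equal(tst$t, 2.886751, tolerance = 1e-6)
  z <- spearmanTest(0, 30)
  expect_identical(z$t, 0)
  expect_identical(z$p, 1)
  expect_identical(spearmanTest(-0.4, 40)$p, spearmanTest(0.4, 40)$p)
  expect_warning(res <- spearmanTest(1, 10), "diverges")
  expect_identical(res$p, 0)
  expect_error(spearmanTest(0.5, 2), "N >= 3")
})

test_that("correlateSeries returns one row per sensor variable", {
  set.seed(2)
  h <- hours_from("2018-01-01 00:00", 60)
  a <- ActivitySeries(h, runif(60))
  s <- SensorSeries(h, matrix(rnorm(300), 60, 5,
                              dimnames = list(NULL, c("T", "d", "v1", "v2", "v3"))))
  ct <- correlateSeries(a, s)
  expect_identical(ct$variable, c("T", "d", "v1", "v2", "v3"))
  expect_true(all(ct$N == 60L))
  expect_true(all(abs(ct$r_s) <= 1))
})

test_that("gaussian smoothing preserves constants, ranges, and flags gaps", {
  h <- hours_from("2018-01-01 00:00", 100)
  const <- gaussianSmooth(ActivitySeries(h, rep(0.37, 100)), 10)
  expect_equal(seriesValues(const$series), rep(0.37, 100), tolerance = 1e-12)

  v <- runif(100)
  sm <- gaussianSmooth(ActivitySeries(h, v), 5)
  out <- seriesValues(sm$series)
  expect_true(all(out >= min(v) - 1e-12 & out <= max(v) + 1e-12))
  expect_true(sm$flagged[1] && sm$flagged[100])
  expect_false(any(sm$flagged[2:99]))

  # an isolated hour is returned unchanged and flagged
  lone <- ActivitySeries(h[c(1, 5, 9)], c(NA, 0.8, NA))
  sml <- gaussianSmooth(lone, 10)
  expect_identical(seriesValues(sml$series)[5], 0.8)
  expect_true(sml$flagged[5])
})

test_that("an impulse smooths to the renormalized discrete kernel", {
  n <- 201
  h <- hours_from("2018-01-01 00:00", n)
  v <- rep(0, n); v[101] <- 1
  sm <- gaussianSmooth(ActivitySeries(h, v), 10)
  K <- ceiling(40)
  kern <- dnorm(-K:K, 0, 10); kern <- kern / sum(kern)
  mid <- seriesValues(sm$series)[101 + (-30:30)]
  expect_equal(mid, kern[K + 1 + (-30:30)], tolerance = 1e-10)
})

test_that("low-activity periods follow the one-peak rule", {
  day <- 24
  # flat zero over 10 days: one period of 10 days
  h <- hours_from("2018-01-01 00:00", 10 * day)
  flat <- ActivitySeries(h, rep(0, 10 * day))
  lp <- detectLowActivity(flat, 0.1, min_days = 5)
  expect_identical(nrow(lp), 1L)
  expect_identical(lp$duration_days, 10L)
  expect_identical(lp$peaks, 0L)

  # two separated peaks: no single period spans both
  h2 <- hours_from("2018-01-01 00:00", 20 * day)
  v2 <- rep(0, 20 * day)
  v2[5 * day] <- 0.5
  v2[15 * day] <- 0.5
  lp2 <- detectLowActivity(ActivitySeries(h2, v2), 0.1, min_days = 5)
  expect_gt(nrow(lp2), 1L)
  for (i in seq_len(nrow(lp2)))
    expect_lte(lp2$peaks[i], 1L)

  # a single short peak within 20 flat days: one period of 20 days
  v3 <- rep(0.05, 20 * day)
  v3[10 * day] <- 0.3
  lp3 <- detectLowActivity(ActivitySeries(h2, v3), 0.1, min_days = 5)
  expect_identical(nrow(lp3), 1L)
  expect_identical(lp3$duration_days, 20L)
  expect_identical(lp3$peaks, 1L)

  # high sustained activity yields no period
  lp4 <- detectLowActivity(ActivitySeries(h, rep(0.8, 10 * day)), 0.1, 5)
  expect_identical(nrow(lp4), 0L)
})
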