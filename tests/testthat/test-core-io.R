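# Domain types, gamma correction, polygon rasterization and file round-trips.

test_that("gamma correction follows the power law and preserves [0,1]", {
  expect_identical(gammaCorrect(0, 0.3), 0)
  expect_identical(gammaCorrect(1, 0.3), 1)
  expect_equal(gammaCorrect(0.5, 0.3), 0.5^0.3, tolerance = 1e-15)
  x <- seq(0, 1, by = 0.01)
  expect_equal(gammaCorrect(x, 1), x)
  expect_error(gammaCorrect(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(gammaCorrect(0.5, gamma = -1), "positive")
})

test_that("gamma correction is strictly monotone and bijective on [0,1]", {
  for (g in c(0.3, 1, 2.7)) {
    x <- sort(runif(200))
    y <- gammaCorrect(x, g)
    expect_true(all(diff(y) > 0))
    expect_equal(gammaCorrect(y, 1 / g), x, tolerance = 1e-12)
  }
})

test_that("rasterization matches hand counts and override semantics", {
  rect <- PolygonAnnotation("C_r", cbind(c(2, 11, 11, 2), c(3, 3, 12, 12)), "i")
  expect_true(all(maskLabels(rasterizeAnnotations(list(), 20, 20)) == 0))
  m <- rasterizeAnnotations(list(rect), 20, 20)
  expect_identical(sum(maskLabels(m) == 1L), 100L)
  ov <- PolygonAnnotation("background_override",
                          cbind(c(2, 11, 11, 2), c(3, 3, 7, 7)), "i")
  m2 <- rasterizeAnnotations(list(rect, ov), 20, 20)
  expect_identical(sum(maskLabels(m2) == 1L), 50L)
  blue <- PolygonAnnotation("C_b", cbind(c(5, 15, 15, 5), c(5, 5, 15, 15)), "i")
  expect_error(rasterizeAnnotations(list(rect, blue), 20, 20), "ambiguous")
  other <- PolygonAnnotation("C_r", cbind(c(0, 3, 3), c(0, 0, 3)), "j")
  expect_error(rasterizeAnnotations(list(rect, other), 20, 20), "multiple images")
})

test_that("rasterization agrees with the per-pixel point-in-polygon oracle", {
  set.seed(41)
  for (rep in 1:100) {
    nv <- sample(3:7, 1)
    verts <- cbind(runif(nv, -2, 33), runif(nv, -2, 33))
    poly <- PolygonAnnotation("C_r", verts, "i")
    got <- maskLabels(rasterizeAnnotations(list(poly), 32, 32)) == 1L
    expect_identical(got, bf_rasterize(verts, 32, 32))
  }
})

test_that("activity and sensor series round-trip losslessly through CSV", {
  h <- hours_from("2018-02-01 00:00", 5)
  a <- ActivitySeries(h, c(0.1, NA, 0.987654321012345, NA, 1), "C_b", "G2")
  f <- tempfile(fileext = ".csv")
  writeActivityCSV(a, f)
  b <- readActivityCSV(f, "C_b", "G2")
  expect_identical(as.numeric(seriesHours(b)), as.numeric(h))
  expect_identical(seriesValues(b), seriesValues(a))

  s <- SensorSeries(h, cbind(T = c(7.1, NA, 7.3, 7.2, 7.5),
                             d = 258 + runif(5), v1 = rnorm(5),
                             v2 = rnorm(5), v3 = c(NA, rnorm(4))))
  fs <- tempfile(fileext = ".csv")
  writeSensorCSV(s, fs)
  s2 <- readSensorCSV(fs)
  expect_equal(sensorFeatures(s2), sensorFeatures(s), tolerance = 1e-12)
  expect_identical(isGappy(s2), c(TRUE, TRUE, FALSE, FALSE, FALSE))
})

test_that("series CSV readers reject malformed input, naming the row", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("timestamp,value", "2018-01-01 10:00:00,0.5",
               "2018-01-01 10:30:00,0.2"), f)
  expect_error(readActivityCSV(f), "non-hourly.*2")
  writeLines(c("timestamp,value", "not-a-time,0.5"), f)
  expect_error(readActivityCSV(f), "malformed timestamp")
})

test_that("mask PNG and annotation JSON round-trip exactly", {
  lab <- matrix(sample(0:2, 300, replace = TRUE), 15, 20)
  m <- LabelMask(lab, "native", "predicted")
  f <- tempfile(fileext = ".png")
  writeMaskPNG(m, f)
  expect_identical(maskLabels(readMaskPNG(f)), lab)

  polys <- list(PolygonAnnotation("C_r", cbind(c(1, 5, 3), c(1, 1, 4)), "a"),
                PolygonAnnotation("background_override",
                                  cbind(c(0, 2, 2, 0), c(0, 0, 2, 2)), "a"))
  fj <- tempfile(fileext = ".json")
  writeAnnotations(polys, fj)
  back <- readAnnotations(fj)
  expect_identical(back[[1]]@vertices, polys[[1]]@vertices)
  expect_identical(back[[2]]@target, "background_override")
})

test_that("image manifest parsing applies defaults and rejects bad enums", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("image_id,path,timestamp,sensor,angle",
               "a,images/a.png,2018-01-01 10:00:00,K0,",
               "b,images/b.png,2018-01-01 11:00:00,K1,theta2"), f)
  man <- readImageManifest(f)
  expect_identical(man$angle, c("unknown", "theta2"))
  writeLines(c("image_id,path,timestamp,sensor,angle",
               "a,images/a.png,2018-01-01 10:00:00,K7,theta0"), f)
  expect_error(readImageManifest(f), "sensor")
  expect_error(readImageManifest(tempfile()), "not found")
})

test_that("domain type validity rules hold", {
  px <- array(runif(12 * 10 * 3), c(12, 10, 3))
  rec <- ImageRecord("x", "2018-01-05 10:30:00", px, "K1", "theta1")
  expect_identical(rec@campaign, "G1")
  expect_error(ImageRecord("x", "2018-01-05 10:30:00", px, campaign = "G2"),
               "inconsistent")
  expect_error(ImageRecord("x", "2025-01-01 00:00:00", px), "outside")
  expect_error(LabelMask(matrix(c(0L, 3L), 1, 2)), "0, 1, 2")
  expect_error(ActivitySeries(hours_from("2018-01-01 00:00", 2), c(0.2, 1.4)),
               "\\[0, 1\\]")
  expect_error(ActivitySeries(rev(hours_from("2018-01-01 00:00", 2)),
                              c(0.2, 0.4)), "increasing")
  expect_error(new("PolygonAnnotation", target = "C_r",
                   vertices = cbind(1:2, 1:2), image_id = "i"), "3")
})

test_that("campaign tagging follows the configured date ranges", {
  expect_identical(campaignOf("2018-06-13 12:00:00"), "G1")
  expect_identical(campaignOf("2018-06-13 13:00:00"), "G1prime")
  expect_identical(campaignOf("2019-01-15 00:00:00"), "G2")
  expect_true(is.na(campaignOf("2020-01-01 00:00:00")))
})
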