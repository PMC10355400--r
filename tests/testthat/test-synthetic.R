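# The synthetic scene/campaign/sensor generator: determinism, occlusion
# semantics, schedule arithmetic, and the causal link between sensors and
# the latent activity signal.

test_that("scene rendering is deterministic and occluders shrink the mask", {
  sp <- sceneSpec(seed = 5L)
  a <- renderScene(sp)
  b <- renderScene(sp)
  expect_identical(a$image@pixels, b$image@pixels)
  expect_identical(maskLabels(a$mask), maskLabels(b$mask))
  expect_identical(a$states, b$states)

  clean_red <- sum(maskLabels(a$mask) == 1L)
  geom_center <- which(maskLabels(a$mask) == 1L, arr.ind = TRUE)
  cen <- round(colMeans(geom_center))
  fouled <- renderScene(sceneSpec(
    seed = 5L, biofouling = list(centers = cbind(cen[2], cen[1]),
                                 radius = 10, opacity = 0.8)))
  expect_lt(sum(maskLabels(fouled$mask) == 1L), clean_red)
  # sub-occluding opacity leaves the mask untouched
  faint <- renderScene(sceneSpec(
    seed = 5L, biofouling = list(centers = cbind(cen[2], cen[1]),
                                 radius = 10, opacity = 0.3)))
  expect_identical(sum(maskLabels(faint$mask) == 1L), clean_red)
})

test_that("the distant colony appears only at its visible angles", {
  expect_identical(sum(maskLabels(renderScene(
    sceneSpec(angle = "theta0"))$mask) == 2L), 0L)
  expect_gt(sum(maskLabels(renderScene(
    sceneSpec(angle = "theta1"))$mask) == 2L), 0L)
})

test_that("rendered extended-cell fractions track the requested fraction", {
  sc <- renderScene(sceneSpec(extended_fraction_red = 0.7, seed = 3L))
  st <- sc$states[sc$states$coral == "C_r", ]
  n <- nrow(st)
  expect_gt(n, 20)
  # binomial sampling tolerance at ~3 sd
  expect_lt(abs(mean(st$extended) - 0.7), 3 * sqrt(0.7 * 0.3 / n))
})

test_that("campaign schedules produce the configured scene counts", {
  cs <- campaignSpec(start = "2018-01-01 00:00:00", end = "2018-01-02 00:00:00",
                     images_per_hour = 1L, sensors = "K0",
                     scene = sceneSpec(image_size = c(64L, 80L)),
                     fish_probability = 0, seed = 2L)
  camp <- simulateCampaign(cs)
  expect_length(camp$scenes, 24L)

  cs2 <- campaignSpec(start = "2018-01-01 00:00:00", end = "2018-01-01 02:00:00",
                      images_per_hour = 3L, sensors = c("K0", "K1"),
                      scene = sceneSpec(image_size = c(64L, 80L)),
                      fish_probability = 0, seed = 2L)
  camp2 <- simulateCampaign(cs2)
  expect_length(camp2$scenes, 12L)
  # image timestamps stay inside the hour-centred windows of their hour
  off <- as.numeric(camp2$manifest$timestamp) %% 3600
  expect_true(all(off %in% c(0, 2400, 1200)))
})

test_that("a suppressed latent driver renders every cell retracted", {
  ss <- sensorSpec(start = "2018-01-01 00:00:00", end = "2018-01-01 06:00:00",
                   weights = list(vmag = numeric(4)), bias = -50, seed = 4L)
  cs <- campaignSpec(start = "2018-01-01 00:00:00",
                     end = "2018-01-01 06:00:00", sensor_spec = ss,
                     scene = sceneSpec(image_size = c(64L, 80L)),
                     fish_probability = 0, seed = 4L)
  camp <- simulateCampaign(cs)
  states <- do.call(rbind, lapply(camp$scenes, `[[`, "states"))
  expect_false(any(states$extended))
})

test_that("sensor simulation is seeded and a zero driver gives a* = 0.5", {
  ss <- sensorSpec(start = "2018-01-01 00:00:00", end = "2018-01-02 00:00:00",
                   weights = list(vmag = numeric(4)), bias = 0, seed = 9L)
  a <- simulateSensors(ss)
  b <- simulateSensors(ss)
  expect_identical(a$raw$value, b$raw$value)
  expect_true(all(abs(seriesValues(a$latent) - 0.5) < 1e-12, na.rm = TRUE))
})

test_that("a current-driven latent signal correlates with current magnitude", {
  ss <- sensorSpec(start = "2018-01-01 00:00:00", end = "2018-01-29 00:00:00",
                   weights = list(vmag = c(2, 0, 0, 0)), seed = 10L)
  sim <- simulateSensors(ss)
  feats <- sensorFeatures(sim$hourly)
  vmag <- sqrt(rowSums(feats[, c("v1", "v2", "v3")]^2))
  keep <- !is.na(seriesValues(sim$latent))
  expect_gt(spearmanRho(seriesValues(sim$latent)[keep], vmag[keep]), 0)
})

test_that("per-hour rendered activity reproduces the latent driver", {
  cs <- campaignSpec(start = "2018-01-02 00:00:00", end = "2018-01-03 00:00:00",
                     sensor_spec = sensorSpec(start = "2018-01-01 00:00:00",
                                              end = "2018-01-03 00:00:00",
                                              seed = 6L),
                     fish_probability = 0, seed = 6L)
  camp <- simulateCampaign(cs)
  dev <- abs(seriesValues(camp$truth$C_r) - seriesValues(camp$latent))
  expect_true(all(dev <= 0.15, na.rm = TRUE))
  # every generated mask respects the label-set invariant
  for (sc in camp$scenes)
    expect_true(all(maskLabels(sc$mask) %in% 0:2))
})

test_that("campaign directories round-trip through the on-disk layout", {
  cs <- campaignSpec(start = "2018-01-01 00:00:00", end = "2018-01-01 04:00:00",
                     scene = sceneSpec(image_size = c(64L, 80L)),
                     fish_probability = 0, seed = 3L)
  camp <- simulateCampaign(cs)
  d <- file.path(tempdir(), "camp_rt")
  writeCampaignDir(camp, d, cs)
  man <- readImageManifest(file.path(d, "manifest.csv"))
  expect_identical(nrow(man), 4L)
  px <- readImageArray(file.path(d, man$path[1]))
  expect_lt(max(abs(px - camp$scenes[[1]]$image@pixels)), 1 / 255)
  m <- readMaskPNG(file.path(d, "masks", paste0(man$image_id[2], ".png")))
  expect_identical(maskLabels(m), maskLabels(camp$scenes[[2]]$mask))
  tr <- readActivityCSV(file.path(d, "truth_activity_C_r.csv"))
  expect_equal(seriesValues(tr), seriesValues(camp$truth$C_r),
               tolerance = 1e-12)
  unlink(d, recursive = TRUE)
})
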