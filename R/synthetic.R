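# Synthetic observatory campaigns: two coral colonies of differing
# brightness/contrast rendered into noisy scenes with growing biofouling and
# transient fish occluders, plus tidal/autocorrelated sensor series whose
# lagged, standardized values causally drive a known latent activity signal.
# Every stage of the pipeline is testable against these fixtures.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.logistic <- function(x) 1 / (1 + exp(-x))

#' Scene specification for the synthetic renderer
#'
#' Describes one synthetic observatory scene: a near, bright "red" colony
#' with a top-bright illumination gradient (the flash illuminates its upper
#' parts more strongly), a distant, dim, blue-tinted colony whose visibility
#' depends on the camera angle, per-colony extended-polyp fractions, growing
#' biofouling spots and an optional transient fish occluder.
#'
#' @param image_size `(H, W)` in pixels.
#' @param angle camera angle preset (`"theta0"`, `"theta1"`, `"theta2"`).
#' @param extended_fraction_red,extended_fraction_blue probability that a
#'   colony surface cell is rendered with extended polyps.
#' @param blue_visible_angles angles at which the distant colony is in frame.
#' @param biofouling list with `centers` (k x 2 matrix of (x, y)), `radius`
#'   (px) and `opacity` in `[0, 1]`; spots with opacity >= 0.5 occlude the
#'   mask (assigned to background, like all occluders).
#' @param fish_probability probability that a fish swims through the frame.
#' @param noise_sd additive Gaussian pixel noise standard deviation.
#' @param cell_size polyp surface-cell size in pixels (the granularity at
#'   which extended/retracted state is rendered and recorded).
#' @param shape_seed seed fixing the colony outlines (constant within a
#'   campaign: the colonies do not move).
#' @param seed seed for the per-scene randomness (polyp states, stipples,
#'   noise, fish).
#' @return a validated `SceneSpec` list.
#' @export
sceneSpec <- function(image_size = c(256L, 320L), angle = "theta1",
                      extended_fraction_red = 0.5,
                      extended_fraction_blue = 0.5,
                      blue_visible_angles = c("theta1", "theta2"),
                      biofouling = list(centers = NULL, radius = 0, opacity = 0),
                      fish_probability = 0, noise_sd = 0.02, cell_size = 16L,
                      shape_seed = 42L, seed = 1L) {
  stopifnot(length(image_size) == 2L, image_size >= 64L)
  if (extended_fraction_red < 0 || extended_fraction_red > 1 ||
      extended_fraction_blue < 0 || extended_fraction_blue > 1)
    stop("extended fractions must lie in [0, 1]")
  if (fish_probability < 0 || fish_probability > 1)
    stop("fish_probability must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!angle %in% c("theta0", "theta1", "theta2")) stop("unknown angle")
  spec <- list(image_size = as.integer(image_size), angle = angle,
               extended_fraction_red = extended_fraction_red,
               extended_fraction_blue = extended_fraction_blue,
               blue_visible_angles = blue_visible_angles,
               biofouling = biofouling, fish_probability = fish_probability,
               noise_sd = noise_sd, cell_size = as.integer(cell_size),
               shape_seed = as.integer(shape_seed), seed = as.integer(seed))
  class(spec) <- "SceneSpec"
  spec
}

# wobbly-ellipse colony footprint on the pixel grid (TRUE inside)
.colony_footprint <- function(H, W, cx, cy, rx, ry, wobble) {
  x <- matrix(rep(0:(W - 1), each = H), H, W)
  y <- matrix(rep(0:(H - 1), W), H, W)
  dx <- (x - cx) / rx
  dy <- (y - cy) / ry
  rho <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx)
  lim <- 1 + wobble$a1 * sin(3 * phi + wobble$p1) +
    wobble$a2 * sin(5 * phi + wobble$p2)
  rho <= lim
}

# colony geometry derived from the shape seed; angle shifts the view
.scene_geometry <- function(spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  shift <- switch(spec$angle, theta0 = -round(0.04 * W), theta1 = 0L,
                  theta2 = round(0.04 * W))
  .with_seed(spec$shape_seed, {
    wob_r <- list(a1 = runif(1, 0.05, 0.12), p1 = runif(1, 0, 2 * pi),
                  a2 = runif(1, 0.03, 0.08), p2 = runif(1, 0, 2 * pi))
    wob_b <- list(a1 = runif(1, 0.05, 0.12), p1 = runif(1, 0, 2 * pi),
                  a2 = runif(1, 0.03, 0.08), p2 = runif(1, 0, 2 * pi))
    list(red = list(cx = 0.68 * W + shift, cy = 0.55 * H,
                    rx = 0.20 * W, ry = 0.33 * H, wobble = wob_r),
         blue = list(cx = 0.18 * W + shift, cy = 0.42 * H,
                     rx = 0.11 * W, ry = 0.17 * H, wobble = wob_b))
  })
}

# paint filled discs (vectorized over small neighbourhoods)
.paint_dots <- function(img, centers, radius, color, clipmask = NULL) {
  H <- dim(img)[1]; W <- dim(img)[2]
  r <- ceiling(radius)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dy^2 + off$dx^2 <= radius^2, ]
  for (i in seq_len(nrow(centers))) {
    yy <- centers[i, 2] + off$dy
    xx <- centers[i, 1] + off$dx
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    yy <- yy[ok]; xx <- xx[ok]
    if (!is.null(clipmask)) {
      keep <- clipmask[cbind(yy, xx)]
      yy <- yy[keep]; xx <- xx[keep]
    }
    if (!length(yy)) next
    for (ch in 1:3) img[cbind(yy, xx, ch)] <- color[ch]
  }
  img
}

#' Render one synthetic observatory scene
#'
#' Draws the two colony footprints, their polyp-state texture (extended
#' polyps appear as bright high-frequency stipple, retracted surfaces stay
#' smooth), the top-bright illumination gradient on the near colony, the
#' biofouling and fish occluders, and additive noise. Occluded pixels are
#' assigned to background in the ground-truth mask. Deterministic given the
#' spec's seeds.
#'
#' @param spec a [sceneSpec()].
#' @param image_id,timestamp,camera_sensor,campaign metadata for the
#'   returned [ImageRecord-class].
#' @return list with `image` ([ImageRecord-class]), `mask`
#'   ([LabelMask-class], ground truth) and `states`, a data.frame of polyp
#'   surface cells (coral, cell_x, cell_y, extended).
#' @export
renderScene <- function(spec, image_id = "scene",
                        timestamp = .as_utc("2018-01-01 12:00:00"),
                        camera_sensor = "K0", campaign = NA) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  geom <- .scene_geometry(spec)
  red_fp <- .colony_footprint(H, W, geom$red$cx, geom$red$cy, geom$red$rx,
                              geom$red$ry, geom$red$wobble)
  blue_visible <- spec$angle %in% spec$blue_visible_angles
  blue_fp <- if (blue_visible)
    .colony_footprint(H, W, geom$blue$cx, geom$blue$cy, geom$blue$rx,
                      geom$blue$ry, geom$blue$wobble)
  else matrix(FALSE, H, W)
  if (any(red_fp & blue_fp)) stop("colony footprints overlap; adjust geometry")
  if (sum(red_fp) == 0L || (blue_visible && sum(blue_fp) == 0L))
    stop("colony footprint larger than image or out of frame")

  .with_seed(spec$seed, {
    img <- array(0.06, c(H, W, 3))
    img <- img + array(rnorm(H * W, 0, 0.01), c(H, W, 3))

    # near colony: reddish, brighter towards the top (flash illumination)
    grad <- matrix(rep(seq(1.25, 0.55, length.out = H), W), H, W)
    base_r <- c(0.72, 0.32, 0.28)
    for (ch in 1:3) {
      layer <- img[, , ch]
      layer[red_fp] <- (base_r[ch] * grad)[red_fp]
      img[, , ch] <- layer
    }
    # distant colony: uniform, dim, blue-tinted
    base_b <- c(0.10, 0.14, 0.30)
    for (ch in 1:3) {
      layer <- img[, , ch]
      layer[blue_fp] <- base_b[ch]
      img[, , ch] <- layer
    }

    # polyp surface cells and their extended/retracted state
    cs <- spec$cell_size
    states <- list()
    paint_states <- function(img, fp, frac, dotcol, coral) {
      rows <- which(fp, arr.ind = TRUE)
      if (!nrow(rows)) return(list(img = img, st = NULL))
      cx_rng <- range((rows[, 2] - 1L) %/% cs)
      cy_rng <- range((rows[, 1] - 1L) %/% cs)
      st <- list(); n <- 0L
      for (cyc in cy_rng[1]:cy_rng[2]) {
        for (cxc in cx_rng[1]:cx_rng[2]) {
          y0 <- cyc * cs + 1L; x0 <- cxc * cs + 1L
          y1 <- min(H, y0 + cs - 1L); x1 <- min(W, x0 + cs - 1L)
          cover <- fp[y0:y1, x0:x1]
          if (mean(cover) < 0.3) next
          ext <- runif(1) < frac
          n <- n + 1L
          st[[n]] <- data.frame(coral = coral, cell_x = cxc, cell_y = cyc,
                                extended = ext)
          if (ext) {
            ndots <- 9L
            dots <- cbind(sample(x0:x1, ndots, replace = TRUE),
                          sample(y0:y1, ndots, replace = TRUE))
            img <- .paint_dots(img, dots, 1.6, dotcol, clipmask = fp)
          }
        }
      }
      list(img = img, st = if (n) do.call(rbind, st) else NULL)
    }
    pr <- paint_states(img, red_fp, spec$extended_fraction_red,
                       c(1.0, 0.85, 0.8), "C_r")
    img <- pr$img
    pb <- if (blue_visible)
      paint_states(img, blue_fp, spec$extended_fraction_blue,
                   c(0.65, 0.75, 1.0), "C_b")
    else list(img = img, st = NULL)
    img <- pb$img
    states <- rbind(pr$st, pb$st)

    labels <- matrix(0L, H, W)
    labels[red_fp] <- 1L
    labels[blue_fp] <- 2L

    # biofouling spots: drawn with their opacity, occluding the mask once
    # opacity reaches 0.5
    bf <- spec$biofouling
    if (!is.null(bf$centers) && nrow(bf$centers) && bf$radius > 0 &&
        bf$opacity > 0) {
      spot <- c(0.10, 0.13, 0.09)
      r <- bf$radius
      off <- expand.grid(dy = -ceiling(r):ceiling(r), dx = -ceiling(r):ceiling(r))
      off <- off[off$dy^2 + off$dx^2 <= r^2, ]
      for (i in seq_len(nrow(bf$centers))) {
        yy <- bf$centers[i, 2] + off$dy
        xx <- bf$centers[i, 1] + off$dx
        ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
        yy <- yy[ok]; xx <- xx[ok]
        for (ch in 1:3)
          img[cbind(yy, xx, ch)] <- (1 - bf$opacity) * img[cbind(yy, xx, ch)] +
            bf$opacity * spot[ch]
        if (bf$opacity >= 0.5) labels[cbind(yy, xx)] <- 0L
      }
    }

    # transient fish occluder: opaque gray ellipse, assigned to background
    if (runif(1) < spec$fish_probability) {
      fx <- runif(1, 0.15 * W, 0.85 * W); fy <- runif(1, 0.2 * H, 0.8 * H)
      frx <- 0.06 * W; fry <- 0.025 * H
      x <- matrix(rep(0:(W - 1), each = H), H, W)
      y <- matrix(rep(0:(H - 1), W), H, W)
      fish <- ((x - fx) / frx)^2 + ((y - fy) / fry)^2 <= 1
      for (ch in 1:3) {
        layer <- img[, , ch]
        layer[fish] <- c(0.55, 0.55, 0.6)[ch]
        img[, , ch] <- layer
      }
      labels[fish] <- 0L
    }

    img <- img + array(rnorm(H * W * 3, 0, spec$noise_sd), c(H, W, 3))
    img <- pmin(pmax(img, 0), 1)

    rec <- ImageRecord(image_id, timestamp, img, camera_sensor, spec$angle,
                       campaign = campaign)
    list(image = rec, mask = LabelMask(labels, "native", "ground_truth"),
         states = states)
  })
}

#' Sensor-simulation specification
#'
#' Parameters of the synthetic environmental series: depth as mean level
#' plus an M2 tidal harmonic (12.42 h period), currents as AR(1) processes
#' at 10-minute (optionally 1-second) native resolution, temperature as a
#' slow drift, and a latent hourly activity signal
#' `a*(t) = logistic(b + sum_lag w_lag . drivers(t - lag))` over the lagged
#' standardized drivers (T, d, v1, v2, v3 and the current magnitude |v|).
#'
#' @param start,end campaign bounds (POSIXct or parseable strings).
#' @param depth_mean,tidal_amp,tidal_period_h,depth_noise_sd depth model (m).
#' @param temp_mean,temp_drift_amp,temp_noise_sd temperature model (deg C).
#' @param current_phi,current_sd AR(1) coefficient (per 10-min step) and
#'   stationary standard deviation of each current component (m/s).
#' @param current_resolution `"10min"` (default) or `"1s"` (tiny spans only).
#' @param lags driver lags in hours used by the latent signal.
#' @param weights named list mapping driver name (`"T"`, `"d"`, `"v1"`,
#'   `"v2"`, `"v3"`, `"vmag"`) to a numeric vector of per-lag weights.
#' @param bias latent-signal intercept.
#' @param seed RNG seed.
#' @return a validated `SensorSpec` list.
#' @export
sensorSpec <- function(start = "2018-01-01 00:00:00",
                       end = "2018-01-29 00:00:00",
                       depth_mean = 258, tidal_amp = 0.6,
                       tidal_period_h = 12.42, depth_noise_sd = 0.03,
                       temp_mean = 7.5, temp_drift_amp = 0.4,
                       temp_noise_sd = 0.04,
                       current_phi = 0.97, current_sd = 0.08,
                       current_resolution = "10min",
                       lags = 0:3,
                       weights = list(vmag = c(2.0, 1.4, 0.8, 0.4),
                                      T = c(1.0, 0, 0, 0)),
                       bias = 0, seed = 1L) {
  start <- .as_utc(start); end <- .as_utc(end)
  if (end <= start) stop("end must be after start")
  if (!current_resolution %in% c("10min", "1s"))
    stop("current_resolution must be '10min' or '1s'")
  for (w in names(weights))
    if (length(weights[[w]]) != length(lags))
      stop("weight vector for '", w, "' must have one entry per lag")
  spec <- list(start = start, end = end, depth_mean = depth_mean,
               tidal_amp = tidal_amp, tidal_period_h = tidal_period_h,
               depth_noise_sd = depth_noise_sd, temp_mean = temp_mean,
               temp_drift_amp = temp_drift_amp, temp_noise_sd = temp_noise_sd,
               current_phi = current_phi, current_sd = current_sd,
               current_resolution = current_resolution, lags = lags,
               weights = weights, bias = bias, seed = as.integer(seed))
  class(spec) <- "SensorSpec"
  spec
}

#' Simulate sensor series and the latent activity they drive
#'
#' @param spec a [sensorSpec()].
#' @return list with `raw` (long-format data.frame: timestamp, variable,
#'   value at native resolutions), `hourly` (a [SensorSeries-class] built
#'   with the package's two-step median aggregation) and `latent` (an
#'   [ActivitySeries-class] holding a*(t)).
#' @export
simulateSensors <- function(spec) {
  .with_seed(spec$seed, {
    hours <- .hour_seq(spec$start, spec$end - 3600)
    nh <- length(hours)
    th <- as.numeric(hours - hours[1]) / 3600

    temp <- spec$temp_mean +
      spec$temp_drift_amp * sin(2 * pi * th / (24 * 30) + runif(1, 0, 2 * pi)) +
      rnorm(nh, 0, spec$temp_noise_sd)
    depth <- spec$depth_mean +
      spec$tidal_amp * sin(2 * pi * th / spec$tidal_period_h + runif(1, 0, 2 * pi)) +
      rnorm(nh, 0, spec$depth_noise_sd)

    # currents: AR(1) at 10-min native resolution spanning the full window
    # used by the hour-centred aggregation ([t - 30 min, t + 30 min))
    step <- 600
    tmin <- spec$start - 1800
    tmax <- spec$end + 1800
    tcur <- seq(tmin, tmax, by = step)
    phi <- spec$current_phi
    innov_sd <- spec$current_sd * sqrt(1 - phi^2)
    ar1 <- function(n) {
      x <- numeric(n)
      x[1] <- rnorm(1, 0, spec$current_sd)
      eps <- rnorm(n - 1, 0, innov_sd)
      for (i in 2:n) x[i] <- phi * x[i - 1] + eps[i - 1]
      x
    }
    v <- sapply(1:3, function(i) ar1(length(tcur)))

    raw <- rbind(
      data.frame(timestamp = hours, variable = "T", value = temp),
      data.frame(timestamp = hours, variable = "d", value = depth),
      do.call(rbind, lapply(1:3, function(i)
        data.frame(timestamp = tcur, variable = paste0("v", i), value = v[, i]))))

    if (spec$current_resolution == "1s") {
      # interpolate the 10-min process to 1 s (piecewise linear + noise);
      # only sensible for spans of a few hours
      tsec <- seq(tmin, tmax, by = 1)
      vsec <- sapply(1:3, function(i)
        approx(as.numeric(tcur), v[, i], as.numeric(tsec))$y +
          rnorm(length(tsec), 0, 0.25 * innov_sd))
      raw <- rbind(raw[raw$variable %in% c("T", "d"), ],
                   do.call(rbind, lapply(1:3, function(i)
                     data.frame(timestamp = tsec, variable = paste0("v", i),
                                value = vsec[, i]))))
    }

    hourly <- hourlySensorSeries(raw, hours)

    # latent activity: logistic link over lagged standardized drivers
    feats <- sensorFeatures(hourly)
    vmag <- sqrt(rowSums(feats[, c("v1", "v2", "v3")]^2))
    drivers <- cbind(feats, vmag = vmag)
    drv_std <- scale(drivers)
    lin <- rep(spec$bias, nh)
    for (nm in names(spec$weights)) {
      wv <- spec$weights[[nm]]
      for (j in seq_along(spec$lags)) {
        lag <- spec$lags[j]
        if (wv[j] == 0) next
        shifted <- if (lag >= nh) rep(NA_real_, nh)
        else c(rep(NA_real_, lag), drv_std[seq_len(nh - lag), nm])
        lin <- lin + wv[j] * shifted
      }
    }
    astar <- .logistic(lin)  # NA during the first max(lags) hours
    list(raw = raw, hourly = hourly,
         latent = ActivitySeries(hours, astar, "C_r", "G1"))
  })
}

#' Campaign specification for the synthetic generator
#'
#' @param start,end campaign bounds.
#' @param images_per_hour images per camera sensor per hour (1, 2 or 3).
#' @param sensors camera sensors in use (subset of `"K0"`, `"K1"`).
#' @param angles viewing-angle rotation order, cycled over image slots.
#' @param scene base [sceneSpec()] (geometry, noise, cell size).
#' @param sensor_spec a [sensorSpec()]; its span must cover the campaign.
#'   `NULL` derives one from `start`/`end`/`seed`.
#' @param biofouling_growth list with `n_spots`, `radius_range` (px, start
#'   to end of campaign), `opacity_range` (start to end; occlusions grow
#'   monotonically over campaign time).
#' @param fish_probability per-scene transient occluder probability.
#' @param campaign campaign tag for the rendered records.
#' @param seed RNG seed.
#' @return a validated `CampaignSpec` list.
#' @export
campaignSpec <- function(start = "2018-01-01 00:00:00",
                         end = "2018-01-03 00:00:00",
                         images_per_hour = 1L, sensors = "K0",
                         angles = c("theta0", "theta1", "theta2"),
                         scene = sceneSpec(),
                         sensor_spec = NULL,
                         biofouling_growth = list(n_spots = 3L,
                                                  radius_range = c(3, 12),
                                                  opacity_range = c(0.55, 0.95)),
                         fish_probability = 0.05, campaign = "G1",
                         seed = 1L) {
  start <- .as_utc(start); end <- .as_utc(end)
  if (end <= start) stop("end must be after start")
  if (!images_per_hour %in% 1:3) stop("images_per_hour must be 1, 2 or 3")
  if (!all(sensors %in% .SENSORS)) stop("unknown camera sensor")
  if (is.null(sensor_spec))
    sensor_spec <- sensorSpec(start = start, end = end, seed = seed)
  spec <- list(start = start, end = end,
               images_per_hour = as.integer(images_per_hour),
               sensors = sensors, angles = angles, scene = scene,
               sensor_spec = sensor_spec,
               biofouling_growth = biofouling_growth,
               fish_probability = fish_probability, campaign = campaign,
               seed = as.integer(seed))
  class(spec) <- "CampaignSpec"
  spec
}

#' Simulate a full synthetic campaign
#'
#' Simulates the sensor series and latent activity, then renders one scene
#' per scheduled (hour, camera sensor, slot) with the latent signal driving
#' the per-cell extended-polyp probability, angle presets cycling through
#' the configured rotation, and biofouling occlusions growing monotonically
#' over campaign time.
#'
#' @param spec a [campaignSpec()].
#' @return list with `scenes` (list of renderScene outputs), `manifest`
#'   (data.frame: image_id, timestamp, sensor, angle), `truth` (per-coral
#'   [ActivitySeries-class] of rendered extended-cell fractions, hourly),
#'   `latent` (the driving a* series), `sensors_raw` and `sensors_hourly`.
#' @export
simulateCampaign <- function(spec) {
  sim <- simulateSensors(spec$sensor_spec)
  hours <- seriesHours(sim$latent)
  keep <- hours >= spec$start & hours < spec$end
  hours <- hours[keep]
  astar <- seriesValues(sim$latent)[keep]
  nh <- length(hours)

  H <- spec$scene$image_size[1]; W <- spec$scene$image_size[2]
  geom <- .scene_geometry(spec$scene)
  bg <- spec$biofouling_growth
  centers <- .with_seed(spec$seed + 7L, {
    # anchored on/near the near colony so growth shows in its region size
    n <- bg$n_spots
    ang <- runif(n, 0, 2 * pi); rad <- runif(n, 0.2, 0.8)
    cbind(round(geom$red$cx + rad * geom$red$rx * cos(ang)),
          round(geom$red$cy + rad * geom$red$ry * sin(ang)))
  })

  offsets <- switch(spec$images_per_hour, `1` = 0L, `2` = c(-15L, 15L),
                    `3` = c(-20L, 0L, 20L))
  scenes <- list(); mrows <- list(); slot <- 0L; n <- 0L
  for (hi in seq_len(nh)) {
    frac <- if (nh > 1) (hi - 1) / (nh - 1) else 0
    bf <- list(centers = centers,
               radius = bg$radius_range[1] + frac * diff(bg$radius_range),
               opacity = bg$opacity_range[1] + frac * diff(bg$opacity_range))
    a_t <- astar[hi]
    for (cam in spec$sensors) {
      for (off in offsets) {
        slot <- slot + 1L
        sc <- spec$scene
        sc$angle <- spec$angles[((slot - 1L) %% length(spec$angles)) + 1L]
        sc$extended_fraction_red <- if (is.na(a_t)) 0 else a_t
        sc$extended_fraction_blue <- if (is.na(a_t)) 0 else a_t
        sc$biofouling <- bf
        sc$fish_probability <- spec$fish_probability
        sc$seed <- spec$seed * 10000L + slot
        ts <- hours[hi] + 60 * off
        id <- sprintf("img_%05d_%s", slot, cam)
        n <- n + 1L
        scenes[[n]] <- renderScene(sc, id, ts, cam, spec$campaign)
        mrows[[n]] <- data.frame(image_id = id, timestamp = ts, sensor = cam,
                                 angle = sc$angle)
      }
    }
  }
  manifest <- do.call(rbind, mrows)

  # realized ground truth: per-hour mean rendered extended-cell fraction
  truth_for <- function(coral) {
    vals <- rep(NA_real_, nh)
    for (hi in seq_len(nh)) {
      w <- which(manifest$timestamp >= hours[hi] - 1800 &
                 manifest$timestamp < hours[hi] + 1800)
      fr <- unlist(lapply(w, function(i) {
        st <- scenes[[i]]$states
        st <- st[st$coral == coral, , drop = FALSE]
        if (nrow(st)) mean(st$extended) else NULL
      }))
      if (length(fr)) vals[hi] <- mean(fr)
    }
    ActivitySeries(hours, vals, coral, spec$campaign)
  }

  list(scenes = scenes, manifest = manifest,
       truth = list(C_r = truth_for("C_r"), C_b = truth_for("C_b")),
       latent = ActivitySeries(hours, astar, "C_r", spec$campaign),
       sensors_raw = sim$raw, sensors_hourly = sim$hourly)
}

#' Write a simulated campaign to a directory
#'
#' Lays out the on-disk campaign format consumed by the pipeline driver:
#' `images/` and `masks/` PNGs, `manifest.csv`, `truth_activity_<coral>.csv`,
#' `sensors_raw.csv` and `spec.yaml`.
#'
#' @param campaign output of [simulateCampaign()].
#' @param dir output directory (created if needed).
#' @param spec the [campaignSpec()] used (serialized for provenance).
#' @return `dir`, invisibly.
#' @export
writeCampaignDir <- function(campaign, dir, spec = NULL) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  man <- campaign$manifest
  man$path <- file.path("images", paste0(man$image_id, ".png"))
  for (i in seq_along(campaign$scenes)) {
    sc <- campaign$scenes[[i]]
    writeImageArray(sc$image@pixels, file.path(dir, man$path[i]))
    writeMaskPNG(sc$mask, file.path(dir, "masks",
                                    paste0(man$image_id[i], ".png")))
  }
  out <- data.frame(image_id = man$image_id, path = man$path,
                    timestamp = format(man$timestamp, "%Y-%m-%d %H:%M:%S"),
                    sensor = man$sensor, angle = man$angle)
  write.csv(out, file.path(dir, "manifest.csv"), row.names = FALSE,
            quote = FALSE)
  for (coral in names(campaign$truth))
    writeActivityCSV(campaign$truth[[coral]],
                     file.path(dir, paste0("truth_activity_", coral, ".csv")))
  states <- do.call(rbind, lapply(seq_along(campaign$scenes), function(i) {
    st <- campaign$scenes[[i]]$states
    if (is.null(st) || !nrow(st)) return(NULL)
    cbind(image_id = man$image_id[i], st)
  }))
  if (!is.null(states))
    write.csv(states, file.path(dir, "states.csv"), row.names = FALSE,
              quote = FALSE)
  raw <- campaign$sensors_raw
  raw$timestamp <- format(raw$timestamp, "%Y-%m-%d %H:%M:%S")
  write.csv(raw, file.path(dir, "sensors_raw.csv"), row.names = FALSE,
            quote = FALSE)
  if (!is.null(spec)) {
    ser <- spec
    ser$start <- format(ser$start); ser$end <- format(ser$end)
    ser$scene$image_size <- as.integer(ser$scene$image_size)
    ser$sensor_spec$start <- format(ser$sensor_spec$start)
    ser$sensor_spec$end <- format(ser$sensor_spec$end)
    yaml::write_yaml(ser, file.path(dir, "spec.yaml"))
  }
  invisible(dir)
}
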