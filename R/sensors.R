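# Hourly sensor features s(t) = (T, d, v1, v2, v3): temperature and depth
# arrive hourly; current components arrive at 1 s or 10 min native
# resolution and are reduced to hourly values by a two-step median inside
# the hour-centred half-open window [t - 30 min, t + 30 min).

.window_bounds <- function(hour) {
  c(as.numeric(hour) - 1800, as.numeric(hour) + 1800)
}

#' Two-step median aggregation of current data to hourly resolution
#'
#' For each whole hour t, records with timestamps in `[t - 30 min,
#' t + 30 min)` are first reduced to 10-minute medians over the six
#' 10-minute subdivisions of the window (records already at 10-minute
#' resolution pass through unchanged, being alone in their subdivision),
#' then the hourly value is the median of the available 10-minute values.
#' Windows with no records yield `NA` (missing, never zero). The median of
#' an even count is the mean of the two central values.
#'
#' @param records data.frame with `timestamp` (POSIXct) and `value`, one
#'   current component at native resolution.
#' @param hours POSIXct vector of whole hours to aggregate onto.
#' @param variable variable name, for the error message; must be a current
#'   component (temperature and depth are already hourly and bypass this).
#' @return numeric vector parallel to `hours`.
#' @export
aggregateCurrent <- function(records, hours, variable = "v1") {
  if (!variable %in% c("v1", "v2", "v3"))
    stop("aggregateCurrent applies to current components only, not '",
         variable, "'")
  if (any(!.is_whole_hour(hours))) stop("hours must be whole hours")
  ts <- as.numeric(records$timestamp)
  vapply(as.numeric(hours), function(h) {
    lo <- h - 1800
    w <- which(ts >= lo & ts < h + 1800)
    if (!length(w)) return(NA_real_)
    sub <- (ts[w] - lo) %/% 600
    tenmin <- vapply(split(records$value[w], sub), median, 0)
    median(tenmin)
  }, 0)
}

#' Assemble the hourly feature series from per-variable hourly values
#'
#' @param hours POSIXct whole hours (strictly increasing, no duplicates).
#' @param T,d,v1,v2,v3 numeric vectors parallel to `hours` (`NA` = missing).
#' @return a [SensorSeries-class]; hours with any missing component are
#'   flagged gappy (see [isGappy()]).
#' @export
buildFeatureSeries <- function(hours, T, d, v1, v2, v3) {
  if (anyDuplicated(as.numeric(hours))) stop("duplicated hours in feature series")
  SensorSeries(hours, cbind(T = T, d = d, v1 = v1, v2 = v2, v3 = v3))
}

#' Build the hourly feature series from a raw long-format sensor table
#'
#' Temperature and depth records are taken directly (the single record in
#' each hour-centred window; the median if several); current components go
#' through the two-step median of [aggregateCurrent()].
#'
#' @param raw data.frame with columns timestamp, variable, value.
#' @param hours target whole hours; defaults to the span of the raw data.
#' @return a [SensorSeries-class].
#' @export
hourlySensorSeries <- function(raw, hours = NULL) {
  if (is.null(hours)) {
    rng <- range(as.numeric(raw$timestamp))
    first <- .as_utc(round(rng[1] / 3600) * 3600)
    last <- .as_utc(round(rng[2] / 3600) * 3600)
    hours <- .hour_seq(first, last)
  }
  ts <- as.numeric(raw$timestamp)
  direct <- function(variable) {
    rec <- raw[raw$variable == variable, ]
    rts <- as.numeric(rec$timestamp)
    vapply(as.numeric(hours), function(h) {
      w <- which(rts >= h - 1800 & rts < h + 1800)
      if (!length(w)) NA_real_ else median(rec$value[w])
    }, 0)
  }
  feats <- cbind(
    T = direct("T"), d = direct("d"),
    v1 = aggregateCurrent(raw[raw$variable == "v1", ], hours, "v1"),
    v2 = aggregateCurrent(raw[raw$variable == "v2", ], hours, "v2"),
    v3 = aggregateCurrent(raw[raw$variable == "v3", ], hours, "v3"))
  SensorSeries(hours, feats)
}

#' Standardize sensor features to zero mean and unit variance
#'
#' Statistics are computed on the fitting window only (population standard
#' deviation) and can be reused on later data, so that rolling-window
#' training never leaks statistics from its prediction span. Restandardizing
#' an already-standardized series with its own parameters is the identity.
#'
#' @param series a [SensorSeries-class].
#' @param params optional precomputed parameters (from an earlier call);
#'   when given, `fit_hours` is ignored.
#' @param fit_hours POSIXct subset of hours to fit on (default: all hours of
#'   `series`). At least 2 fully observed hours per variable are required.
#' @return list with `series` (standardized [SensorSeries-class]) and
#'   `params` (list with `mean`, `sd`, `window`).
#' @export
standardizeSensors <- function(series, params = NULL, fit_hours = NULL) {
  feats <- series@features
  if (is.null(params)) {
    fit <- if (is.null(fit_hours)) seq_along(series@hours)
           else which(as.numeric(series@hours) %in% as.numeric(fit_hours))
    mu <- sdv <- setNames(numeric(5), .SENSOR_VARS)
    for (v in .SENSOR_VARS) {
      x <- feats[fit, v]
      x <- x[!is.na(x)]
      if (length(x) < 2L)
        stop("fitting window has fewer than 2 observed hours for '", v, "'")
      mu[v] <- mean(x)
      sdv[v] <- sqrt(mean((x - mu[v])^2))  # population sd
      if (sdv[v] == 0) stop("variable '", v, "' has zero variance in the fitting window")
    }
    params <- list(mean = mu, sd = sdv,
                   window = range(series@hours[fit]))
  }
  out <- sweep(sweep(feats, 2, params$mean[.SENSOR_VARS]), 2,
               params$sd[.SENSOR_VARS], "/")
  list(series = SensorSeries(series@hours, out, standardized = TRUE),
       params = params)
}

#' Undo standardization
#'
#' @param series a standardized [SensorSeries-class].
#' @param params parameters from [standardizeSensors()].
#' @return a raw-unit [SensorSeries-class].
#' @export
unstandardizeSensors <- function(series, params) {
  out <- sweep(sweep(series@features, 2, params$sd[.SENSOR_VARS], "*"), 2,
               params$mean[.SENSOR_VARS], "+")
  SensorSeries(series@hours, out, standardized = FALSE)
}

#' Handle gaps in an hourly sensor series
#'
#' The series is first expanded onto the full hourly grid between its first
#' and last hour (absent rows become missing). Under `"drop_windows"` (the
#' conservative default) nothing is filled: gappy hours are reported and any
#' forecasting window covering one is later excluded by [makeWindows()].
#' Under `"ffill_limit"`, per-component gaps of at most `limit` consecutive
#' hours are forward-filled from the last observed value; longer gaps remain
#' missing and are reported.
#'
#' @param series a [SensorSeries-class].
#' @param policy `"drop_windows"` or `"ffill_limit"`.
#' @param limit maximum gap length in hours filled under `"ffill_limit"`.
#' @return list with `series` and `report` (data.frame of still-gappy hours
#'   and, for ffill, the hours that were filled).
#' @export
fillGaps <- function(series, policy = "drop_windows", limit = 3L) {
  if (!policy %in% c("drop_windows", "ffill_limit"))
    stop("unknown gap policy '", policy, "'")
  hours <- series@hours
  grid <- .hour_seq(hours[1], hours[length(hours)])
  feats <- matrix(NA_real_, length(grid), 5,
                  dimnames = list(NULL, .SENSOR_VARS))
  feats[match(as.numeric(hours), as.numeric(grid)), ] <- series@features
  filled <- .as_utc(numeric(0))
  if (policy == "ffill_limit") {
    for (v in .SENSOR_VARS) {
      x <- feats[, v]
      isna <- is.na(x)
      if (!any(isna)) next
      r <- rle(isna)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(r$values)) {
        if (starts[j] == 1L || r$lengths[j] > limit) next
        x[starts[j]:ends[j]] <- x[starts[j] - 1L]
        filled <- c(filled, grid[starts[j]:ends[j]])
      }
      feats[, v] <- x
    }
  }
  out <- SensorSeries(grid, feats, series@standardized)
  gappy <- grid[isGappy(out)]
  list(series = out,
       report = data.frame(hour = c(gappy, unique(filled)),
                           status = c(rep("missing", length(gappy)),
                                      rep("filled", length(unique(filled))))))
}
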