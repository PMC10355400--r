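#' Construct an ImageRecord
#'
#' @param image_id unique identifier.
#' @param timestamp POSIXct (or parseable string), UTC.
#' @param pixels H x W x 3 numeric array, intensities in `[0, 1]`.
#' @param camera_sensor `"K0"` or `"K1"`.
#' @param camera_angle viewing-angle preset; `"unknown"` if unrecorded.
#' @param campaign campaign tag; inferred from the timestamp against
#'   `campaigns` when `NA`.
#' @param source_path originating file, if any.
#' @param campaigns campaign date ranges as returned by [campaignRanges()],
#'   used to check (or infer) the campaign tag.
#' @return an [ImageRecord-class].
#' @export
ImageRecord <- function(image_id, timestamp, pixels, camera_sensor = "K0",
                        camera_angle = "unknown", campaign = NA,
                        source_path = "", campaigns = campaignRanges()) {
  timestamp <- .as_utc(timestamp)
  inferred <- campaignOf(timestamp, campaigns)
  if (is.na(campaign)) {
    campaign <- inferred
    if (is.na(campaign))
      stop("timestamp ", format(timestamp), " falls outside all configured campaigns")
  } else if (!is.na(inferred) && !identical(campaign, inferred) &&
             !(campaign %in% c("G1", "G1prime") && inferred %in% c("G1", "G1prime"))) {
    stop("campaign tag '", campaign, "' inconsistent with timestamp ",
         format(timestamp), " (configured ranges say '", inferred, "')")
  }
  new("ImageRecord", image_id = as.character(image_id), timestamp = timestamp,
      camera_sensor = camera_sensor, camera_angle = camera_angle,
      campaign = campaign, pixels = pixels, source_path = source_path)
}

#' Campaign date ranges
#'
#' The default monitoring-campaign intervals: G1 (winter 2017 to summer
#' 2018) with its configuration sub-interval G1prime starting 13 June 2018
#' 13:00 UTC after a camera-setup change, and G2 (winter 2018 to spring
#' 2019). All values are configuration, not constants.
#'
#' @param g1_start,g1_end,g1prime_start,g2_start,g2_end POSIXct bounds.
#' @return a data.frame with columns campaign, start, end.
#' @export
campaignRanges <- function(g1_start = .as_utc("2017-11-01 00:00:00"),
                           g1prime_start = .as_utc("2018-06-13 13:00:00"),
                           g1_end = .as_utc("2018-08-01 00:00:00"),
                           g2_start = .as_utc("2018-12-01 00:00:00"),
                           g2_end = .as_utc("2019-05-01 00:00:00")) {
  data.frame(campaign = c("G1", "G1prime", "G2"),
             start = c(g1_start, g1prime_start, g2_start),
             end = c(g1prime_start, g1_end, g2_end))
}

#' Map a timestamp to its campaign tag
#'
#' @param timestamp POSIXct.
#' @param campaigns ranges from [campaignRanges()].
#' @return campaign tag, or `NA` if outside all ranges.
#' @export
campaignOf <- function(timestamp, campaigns = campaignRanges()) {
  timestamp <- .as_utc(timestamp)
  hit <- which(timestamp >= campaigns$start & timestamp < campaigns$end)
  if (length(hit)) campaigns$campaign[hit[1]] else NA_character_
}

#' Construct a LabelMask
#'
#' @param labels integer matrix with values in \{0, 1, 2\}.
#' @param resolution_tag `"native"` or `"downscaled"`.
#' @param origin `"ground_truth"` or `"predicted"`.
#' @return a [LabelMask-class].
#' @export
LabelMask <- function(labels, resolution_tag = "native",
                      origin = "ground_truth") {
  storage.mode(labels) <- "integer"
  new("LabelMask", labels = labels, resolution_tag = resolution_tag,
      origin = origin)
}

#' Construct a PolygonAnnotation
#'
#' @param target `"C_r"`, `"C_b"` or `"background_override"`.
#' @param vertices n x 2 matrix of 0-based (x, y) pixel coordinates.
#' @param image_id annotated image id.
#' @return a [PolygonAnnotation-class].
#' @export
PolygonAnnotation <- function(target, vertices, image_id = "") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  colnames(vertices) <- c("x", "y")
  new("PolygonAnnotation", target = target, vertices = vertices,
      image_id = as.character(image_id))
}

#' Construct an ActivitySeries
#'
#' @param hours POSIXct vector of whole hours (strictly increasing).
#' @param values numeric in `[0, 1]`, `NA` for missing hours.
#' @param coral `"C_r"` or `"C_b"`.
#' @param campaign campaign tag.
#' @return an [ActivitySeries-class].
#' @export
ActivitySeries <- function(hours, values, coral = "C_r", campaign = "G1") {
  new("ActivitySeries", coral = coral, campaign = campaign,
      hours = .as_utc(hours), values = as.numeric(values))
}

#' Construct a SensorSeries
#'
#' @param hours POSIXct vector of whole hours.
#' @param features n x 5 numeric matrix (columns T, d, v1, v2, v3) or a
#'   data.frame with those columns.
#' @param standardized whether the series is already standardized.
#' @return a [SensorSeries-class].
#' @export
SensorSeries <- function(hours, features, standardized = FALSE) {
  features <- as.matrix(as.data.frame(features)[, .SENSOR_VARS])
  colnames(features) <- .SENSOR_VARS
  new("SensorSeries", hours = .as_utc(hours), features = features,
      standardized = standardized)
}

#' Construct a ForecastConfig
#'
#' Defaults follow the rolling-retrain scheme: an 8-week (1344 h) trailing
#' training span, a 1-week (168 h) prediction block, and a 24-hour input
#' window.
#'
#' @param window_length input window length in hours.
#' @param train_span training span in hours.
#' @param predict_span prediction block in hours.
#' @param hidden_size recurrent hidden width.
#' @param epochs epochs per weekly model.
#' @param learning_rate optimizer step size.
#' @param batch_size minibatch size.
#' @param gap_policy `"drop_windows"` (default) or `"ffill_limit"`.
#' @param ffill_limit max gap hours filled under `"ffill_limit"`.
#' @param seed base seed.
#' @return a [ForecastConfig-class].
#' @export
ForecastConfig <- function(window_length = 24L, train_span = 1344L,
                           predict_span = 168L, hidden_size = 16L,
                           epochs = 40L, learning_rate = 0.01,
                           batch_size = 128L, gap_policy = "drop_windows",
                           ffill_limit = 3L, seed = 1L) {
  new("ForecastConfig", window_length = as.integer(window_length),
      train_span = as.integer(train_span),
      predict_span = as.integer(predict_span),
      hidden_size = as.integer(hidden_size), epochs = as.integer(epochs),
      learning_rate = learning_rate, batch_size = as.integer(batch_size),
      gap_policy = gap_policy, ffill_limit = as.integer(ffill_limit),
      seed = as.integer(seed))
}
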