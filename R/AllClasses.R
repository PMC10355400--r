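setOldClass("POSIXct")

#' ImageRecord: one time-stamped observatory image
#'
#' Holds one RGB still image together with the acquisition metadata the
#' pipeline needs: which of the two stereo camera sensors recorded it, the
#' pan/tilt viewing angle preset, and the monitoring campaign it belongs to.
#' Pixel intensities are stored in `[0, 1]` as an H x W x 3 array.
#'
#' @slot image_id unique identifier string.
#' @slot timestamp acquisition time, UTC, minute precision.
#' @slot camera_sensor `"K0"` or `"K1"`.
#' @slot camera_angle one of `"theta0"`, `"theta1"`, `"theta2"`, `"unknown"`.
#' @slot campaign one of `"G1"`, `"G1prime"`, `"G2"`.
#' @slot pixels numeric H x W x 3 array with values in `[0, 1]`.
#' @slot source_path originating file path ("" if in-memory).
#' @exportClass ImageRecord
setClass("ImageRecord", representation(
  image_id = "character", timestamp = "POSIXct", camera_sensor = "character",
  camera_angle = "character", campaign = "character", pixels = "array",
  source_path = "character"))

setValidity("ImageRecord", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L) msg <- c(msg, "pixels must be an H x W x 3 array")
  else if (d[1] < 1L || d[2] < 1L) msg <- c(msg, "image must have H >= 1, W >= 1")
  else {
    rng <- range(object@pixels)
    if (rng[1] < 0 || rng[2] > 1) msg <- c(msg, "pixel intensities must lie in [0, 1]")
  }
  if (!object@camera_sensor %in% .SENSORS) msg <- c(msg, "unknown camera_sensor")
  if (!object@camera_angle %in% .ANGLES) msg <- c(msg, "unknown camera_angle")
  if (!object@campaign %in% .CAMPAIGNS) msg <- c(msg, "unknown campaign")
  if (length(msg)) msg else TRUE
})

#' LabelMask: per-pixel colony class map
#'
#' Integer matrix with the pipeline's three semantic classes: 0 background,
#' 1 the near "red" colony, 2 the distant "blue" colony. Masks exist either
#' at the native image resolution or at the segmenter's working resolution,
#' and are tagged with their origin (human annotation vs. network output).
#'
#' @slot labels integer H x W matrix with values in \{0, 1, 2\}.
#' @slot resolution_tag `"native"` or `"downscaled"`.
#' @slot origin `"ground_truth"` or `"predicted"`.
#' @exportClass LabelMask
setClass("LabelMask", representation(
  labels = "matrix", resolution_tag = "character", origin = "character"))

setValidity("LabelMask", function(object) {
  msg <- character()
  if (!all(object@labels %in% c(0L, 1L, 2L))) msg <- c(msg, "labels must be in {0, 1, 2}")
  if (!object@resolution_tag %in% c("native", "downscaled"))
    msg <- c(msg, "resolution_tag must be 'native' or 'downscaled'")
  if (!object@origin %in% c("ground_truth", "predicted"))
    msg <- c(msg, "origin must be 'ground_truth' or 'predicted'")
  if (length(msg)) msg else TRUE
})

#' PolygonAnnotation: a free-hand colony outline
#'
#' One closed polygon annotated on one image, outlining either colony or a
#' background override (occluders such as biofouling or fish that must be
#' forced back to background after the colony polygons are rasterized).
#'
#' @slot target `"C_r"`, `"C_b"` or `"background_override"`.
#' @slot vertices n x 2 numeric matrix of (x, y) pixel coordinates, 0-based,
#'   x rightward and y downward.
#' @slot image_id id of the annotated image.
#' @exportClass PolygonAnnotation
setClass("PolygonAnnotation", representation(
  target = "character", vertices = "matrix", image_id = "character"))

setValidity("PolygonAnnotation", function(object) {
  msg <- character()
  if (!object@target %in% c("C_r", "C_b", "background_override"))
    msg <- c(msg, "unknown annotation target")
  if (ncol(object@vertices) != 2L || nrow(object@vertices) < 3L)
    msg <- c(msg, "polygon needs an n x 2 vertex matrix with n >= 3")
  if (length(msg)) msg else TRUE
})

#' ActivitySeries: hourly colony activity
#'
#' Hourly polyp-activity values in `[0, 1]` for one colony, with explicit
#' missing hours stored as `NA`. Timestamps are strictly increasing whole
#' hours (UTC).
#'
#' @slot coral `"C_r"` or `"C_b"`.
#' @slot campaign campaign tag.
#' @slot hours POSIXct vector of whole hours.
#' @slot values numeric vector, same length, in `[0, 1]` or `NA`.
#' @exportClass ActivitySeries
setClass("ActivitySeries", representation(
  coral = "character", campaign = "character", hours = "POSIXct",
  values = "numeric"))

setValidity("ActivitySeries", function(object) {
  msg <- character()
  if (!object@coral %in% .CORALS) msg <- c(msg, "unknown coral")
  if (length(object@hours) != length(object@values))
    msg <- c(msg, "hours and values differ in length")
  if (length(object@hours)) {
    if (any(!.is_whole_hour(object@hours)))
      msg <- c(msg, "timestamps must be aligned to whole hours")
    if (any(diff(as.numeric(object@hours)) <= 0))
      msg <- c(msg, "timestamps must be strictly increasing")
  }
  v <- object@values[!is.na(object@values)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    msg <- c(msg, "activity values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' SensorSeries: hourly environmental feature vectors
#'
#' The five-variable hourly feature series fed to the forecaster:
#' temperature T (deg C), depth d (m) and the three current-velocity
#' components v1, v2, v3 (m/s). Components may be missing (`NA`); an hour
#' with any missing component is flagged gappy.
#'
#' @slot hours POSIXct vector of whole hours, strictly increasing.
#' @slot features numeric n x 5 matrix, columns T, d, v1, v2, v3.
#' @slot standardized logical: TRUE once scaled to zero mean / unit variance.
#' @exportClass SensorSeries
setClass("SensorSeries", representation(
  hours = "POSIXct", features = "matrix", standardized = "logical"))

setValidity("SensorSeries", function(object) {
  msg <- character()
  if (ncol(object@features) != 5L ||
      !identical(colnames(object@features), .SENSOR_VARS))
    msg <- c(msg, "features must have columns T, d, v1, v2, v3")
  if (nrow(object@features) != length(object@hours))
    msg <- c(msg, "features rows and hours differ in length")
  if (length(object@hours)) {
    if (any(!.is_whole_hour(object@hours)))
      msg <- c(msg, "timestamps must be aligned to whole hours")
    if (any(diff(as.numeric(object@hours)) <= 0))
      msg <- c(msg, "timestamps must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' PatchSet: grid patches cut from one or more images
#'
#' Container for 128 x 128 (configurable) image tiles cut on a cartesian grid
#' over a colony's segmentation mask. Tile pixels at mask-background
#' positions are zeroed; each tile carries its coral-portion weight p (the
#' fraction of tile pixels covered by the colony's mask label). Only tiles
#' with p >= the eligibility threshold (0.1) are retained.
#'
#' @slot info data.frame with columns patch_id, image_id, coral, x, y
#'   (grid origin, native 0-based pixels), p, k (true class, NA if unset),
#'   k_hat (predicted class, NA if unset), mask_origin.
#' @slot pixels list of size x size x 3 arrays, parallel to `info` rows.
#' @slot patch_size tile side length in native pixels.
#' @exportClass PatchSet
setClass("PatchSet", representation(
  info = "data.frame", pixels = "list", patch_size = "integer"))

setValidity("PatchSet", function(object) {
  msg <- character()
  need <- c("patch_id", "image_id", "coral", "x", "y", "p", "k", "k_hat",
            "mask_origin")
  if (!all(need %in% names(object@info)))
    msg <- c(msg, paste("info must have columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(object@info) != length(object@pixels))
      msg <- c(msg, "info rows and pixels list differ in length")
    if (nrow(object@info)) {
      if (any(object@info$p < 0 | object@info$p > 1)) msg <- c(msg, "p must lie in [0, 1]")
      k <- object@info$k
      if (!all(is.na(k) | k %in% 0:1)) msg <- c(msg, "k must be 0, 1 or NA")
    }
  }
  if (length(msg)) msg else TRUE
})

#' SegModel: trained colony segmentation network
#'
#' Bundle holding the encoder-decoder weights, its configuration (working
#' input size, class count, optimizer settings) and the per-epoch validation
#' log from which the best checkpoint was selected.
#'
#' @slot weights list of layer weight arrays (best validation checkpoint).
#' @slot config list of hyperparameters, including `input_size` and
#'   `n_classes` (3).
#' @slot interval training interval tag: `"t1"`, `"t2"` or `"star"`.
#' @slot training_log data.frame with epoch and validation macro-Jaccard.
#' @exportClass SegModel
setClass("SegModel", representation(
  weights = "list", config = "list", interval = "character",
  training_log = "data.frame"))

setValidity("SegModel", function(object) {
  msg <- character()
  if (!object@interval %in% c("t1", "t2", "star")) msg <- c(msg, "unknown interval tag")
  if (!identical(object@config$n_classes, 3L)) msg <- c(msg, "n_classes must be 3")
  if (length(msg)) msg else TRUE
})

#' ClfModel: trained patch activity classifier
#'
#' Bundle for one patch-level extended/retracted classifier, keyed by the
#' training interval and the coral it was trained for.
#'
#' @slot weights list of layer weight arrays (best validation checkpoint).
#' @slot config list of hyperparameters.
#' @slot interval `"t1"`, `"t2"` or `"star"`.
#' @slot coral `"C_r"` or `"C_b"`.
#' @slot init `"random"` (desk-scale training from scratch) or `"pretrained"`.
#' @slot training_log data.frame with epoch and validation macro-F1.
#' @exportClass ClfModel
setClass("ClfModel", representation(
  weights = "list", config = "list", interval = "character",
  coral = "character", init = "character", training_log = "data.frame"))

setValidity("ClfModel", function(object) {
  msg <- character()
  if (!object@interval %in% c("t1", "t2", "star")) msg <- c(msg, "unknown interval tag")
  if (!object@coral %in% .CORALS) msg <- c(msg, "unknown coral")
  if (!object@init %in% c("random", "pretrained")) msg <- c(msg, "unknown init mode")
  if (length(msg)) msg else TRUE
})

#' ForecastConfig: rolling-retrain forecaster settings
#'
#' @slot window_length sliding input window length eta in hours.
#' @slot train_span trailing training span in hours (default 1344 = 8 weeks).
#' @slot predict_span prediction block length in hours (default 168 = 1 week).
#' @slot hidden_size recurrent hidden state width.
#' @slot epochs training epochs per weekly model.
#' @slot learning_rate optimizer step size.
#' @slot batch_size minibatch size.
#' @slot gap_policy `"drop_windows"` or `"ffill_limit"`.
#' @slot ffill_limit maximum gap length (hours) filled under `"ffill_limit"`.
#' @slot seed base random seed; weekly model seed = seed + week index.
#' @exportClass ForecastConfig
setClass("ForecastConfig", representation(
  window_length = "integer", train_span = "integer", predict_span = "integer",
  hidden_size = "integer", epochs = "integer", learning_rate = "numeric",
  batch_size = "integer", gap_policy = "character", ffill_limit = "integer",
  seed = "integer"))

setValidity("ForecastConfig", function(object) {
  msg <- character()
  if (object@window_length < 1L) msg <- c(msg, "window_length must be >= 1")
  if (object@train_span < object@window_length)
    msg <- c(msg, "train_span must be >= window_length")
  if (object@predict_span < 1L) msg <- c(msg, "predict_span must be >= 1")
  if (!object@gap_policy %in% c("drop_windows", "ffill_limit"))
    msg <- c(msg, "unknown gap_policy")
  if (length(msg)) msg else TRUE
})

#' ForecastResult: rolling forecast output
#'
#' @slot predicted [ActivitySeries-class] of clipped hourly predictions.
#' @slot weekly_log data.frame: one row per weekly model (train/predict
#'   window bounds, seed, final training loss, hours predicted).
#' @slot mae mean absolute error against supplied truth (NA if none).
#' @exportClass ForecastResult
setClass("ForecastResult", representation(
  predicted = "ActivitySeries", weekly_log = "data.frame", mae = "numeric"))
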