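#' @name polypact-accessors
#' @title Accessors for polypact data classes
#' @description Slot accessors for the package's S4 containers.
#' @param object,x a polypact object.
#' @param ... unused.
NULL

#' @rdname polypact-accessors
#' @export
setGeneric("imageId", function(object) standardGeneric("imageId"))
#' @rdname polypact-accessors
#' @export
setGeneric("maskLabels", function(object) standardGeneric("maskLabels"))
#' @rdname polypact-accessors
#' @export
setGeneric("seriesHours", function(object) standardGeneric("seriesHours"))
#' @rdname polypact-accessors
#' @export
setGeneric("seriesValues", function(object) standardGeneric("seriesValues"))
#' @rdname polypact-accessors
#' @export
setGeneric("sensorFeatures", function(object) standardGeneric("sensorFeatures"))
#' @rdname polypact-accessors
#' @export
setGeneric("coralOf", function(object) standardGeneric("coralOf"))
#' @rdname polypact-accessors
#' @export
setGeneric("patchInfo", function(object) standardGeneric("patchInfo"))
#' @rdname polypact-accessors
#' @export
setGeneric("patchPixels", function(object) standardGeneric("patchPixels"))
#' @rdname polypact-accessors
#' @export
setGeneric("trainingLog", function(object) standardGeneric("trainingLog"))
#' @rdname polypact-accessors
#' @export
setGeneric("isGappy", function(object) standardGeneric("isGappy"))

setMethod("imageId", "ImageRecord", function(object) object@image_id)
setMethod("maskLabels", "LabelMask", function(object) object@labels)
setMethod("seriesHours", "ActivitySeries", function(object) object@hours)
setMethod("seriesHours", "SensorSeries", function(object) object@hours)
setMethod("seriesValues", "ActivitySeries", function(object) object@values)
setMethod("sensorFeatures", "SensorSeries", function(object) object@features)
setMethod("coralOf", "ActivitySeries", function(object) object@coral)
setMethod("coralOf", "ClfModel", function(object) object@coral)
setMethod("patchInfo", "PatchSet", function(object) object@info)
setMethod("patchPixels", "PatchSet", function(object) object@pixels)
setMethod("trainingLog", "SegModel", function(object) object@training_log)
setMethod("trainingLog", "ClfModel", function(object) object@training_log)

# hours whose feature vector has any missing component
setMethod("isGappy", "SensorSeries", function(object) {
  apply(is.na(object@features), 1L, any)
})

setMethod("show", "ImageRecord", function(object) {
  d <- dim(object@pixels)
  cat("ImageRecord", object@image_id, "\n",
      " ", format(object@timestamp, "%Y-%m-%d %H:%M UTC"),
      " sensor:", object@camera_sensor, " angle:", object@camera_angle,
      " campaign:", object@campaign, "\n",
      "  size:", d[1], "x", d[2], "\n")
})

setMethod("show", "LabelMask", function(object) {
  tab <- tabulate(object@labels + 1L, 3L)
  cat("LabelMask", paste(dim(object@labels), collapse = " x "),
      sprintf("(%s, %s)\n", object@resolution_tag, object@origin),
      sprintf("  background: %d  C_r: %d  C_b: %d\n", tab[1], tab[2], tab[3]))
})

setMethod("show", "ActivitySeries", function(object) {
  n <- length(object@values)
  cat("ActivitySeries for", object@coral, "campaign", object@campaign, "\n",
      sprintf(" %d hours (%d present, %d missing)\n", n,
              sum(!is.na(object@values)), sum(is.na(object@values))))
  if (n) cat("  span:", format(object@hours[1]), "to",
             format(object@hours[n]), "UTC\n")
})

setMethod("show", "SensorSeries", function(object) {
  cat("SensorSeries:", nrow(object@features), "hours,",
      sum(isGappy(object)), "gappy;",
      if (object@standardized) "standardized" else "raw units", "\n")
})

setMethod("show", "PatchSet", function(object) {
  cat("PatchSet:", nrow(object@info), "patches of",
      object@patch_size, "x", object@patch_size, "px\n")
  if (nrow(object@info)) {
    cat("  corals:", paste(unique(object@info$coral), collapse = ", "),
        " labeled:", sum(!is.na(object@info$k)),
        " classified:", sum(!is.na(object@info$k_hat)), "\n")
  }
})

setMethod("show", "SegModel", function(object) {
  cat("SegModel f_", sub("^t", "", object@interval),
      ": input ", paste(object@config$input_size, collapse = " x "),
      ", best val macro-Jaccard ",
      if (nrow(object@training_log)) round(max(object@training_log$val_macro_jaccard), 3)
      else NA, "\n", sep = "")
})

setMethod("show", "ClfModel", function(object) {
  cat("ClfModel g_", sub("^t", "", object@interval), ",",
      object@coral, " (", object@init, " init), best val macro-F1 ",
      if (nrow(object@training_log)) round(max(object@training_log$val_macro_f1), 3)
      else NA, "\n", sep = "")
})

setMethod("show", "ForecastResult", function(object) {
  cat("ForecastResult:", sum(!is.na(object@predicted@values)),
      "predicted hours over", nrow(object@weekly_log), "weekly models")
  if (!is.na(object@mae)) cat("; MAE", round(object@mae, 4))
  cat("\n")
})
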