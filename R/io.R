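#' Gamma correction
#'
#' Nonlinear intensity transform `out = in^gamma` applied elementwise.
#' With gamma < 1 (the observatory default 0.3) dark regions are brightened,
#' which makes the dim distant colony visually assessable. The transform is
#' strictly monotone and maps `[0, 1]` onto itself.
#'
#' @param pixels numeric array/matrix/vector with intensities in `[0, 1]`.
#' @param gamma positive exponent (default 0.3).
#' @return transformed intensities, same shape.
#' @export
gammaCorrect <- function(pixels, gamma = 0.3) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("gamma must be a single positive number")
  rng <- range(pixels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 1)
    stop("intensities must lie in [0, 1]")
  pixels^gamma
}

#' Rasterize polygon annotations into a label mask
#'
#' Pixels inside a `C_r` polygon get label 1, inside a `C_b` polygon label 2,
#' everything else 0. `background_override` polygons (biofouling, fish,
#' shadowed branches) are applied last and force label 0. Interior membership
#' uses the even-odd rule evaluated at pixel centers ((x, y) 0-based integer
#' coordinates); pixels exactly on a polygon edge count as inside. Overlap
#' between a `C_r` and a `C_b` polygon is an error (ambiguous label).
#'
#' @param polygons list of [PolygonAnnotation-class] for one image.
#' @param height,width mask dimensions in pixels.
#' @return a [LabelMask-class] with origin `"ground_truth"`.
#' @export
rasterizeAnnotations <- function(polygons, height, width) {
  if (length(polygons)) {
    ids <- unique(vapply(polygons, function(p) p@image_id, ""))
    if (length(ids) > 1L)
      stop("polygons reference multiple images: ", paste(ids, collapse = ", "))
  }
  red <- matrix(FALSE, height, width)
  blue <- matrix(FALSE, height, width)
  override <- matrix(FALSE, height, width)
  for (p in polygons) {
    inside <- pa_polygon_mask(p@vertices, height, width)
    if (p@target == "C_r") red <- red | inside
    else if (p@target == "C_b") blue <- blue | inside
    else override <- override | inside
  }
  if (any(red & blue))
    stop("ambiguous label: C_r and C_b polygons overlap")
  labels <- matrix(0L, height, width)
  labels[red] <- 1L
  labels[blue] <- 2L
  labels[override] <- 0L
  LabelMask(labels, "native", "ground_truth")
}

# ---- annotation JSON ------------------------------------------------------

#' Read polygon annotations from JSON
#'
#' The file format is a minimal free-hand-outline export: a JSON array of
#' objects with fields `image_id`, `label` (one of `"C_r"`, `"C_b"`,
#' `"background_override"`) and `points`, a flat `[x1, y1, x2, y2, ...]`
#' vertex list in 0-based pixel coordinates.
#'
#' @param path JSON file.
#' @return list of [PolygonAnnotation-class].
#' @export
readAnnotations <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(a) {
    pts <- unlist(a$points)
    if (length(pts) %% 2L != 0L || length(pts) < 6L)
      stop("annotation for image '", a$image_id,
           "' needs an even-length point list with >= 3 vertices")
    PolygonAnnotation(a$label, matrix(pts, ncol = 2, byrow = TRUE), a$image_id)
  })
}

#' Write polygon annotations to JSON
#'
#' @param polygons list of [PolygonAnnotation-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAnnotations <- function(polygons, path) {
  out <- lapply(polygons, function(p) list(
    image_id = p@image_id, label = p@target,
    points = as.numeric(t(p@vertices))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- images and masks -----------------------------------------------------

#' Read an RGB image file
#'
#' @param path PNG file.
#' @return H x W x 3 numeric array with intensities in `[0, 1]`.
#' @export
readImageArray <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  px[, , 1:3, drop = FALSE]
}

#' Write an RGB image file
#'
#' @param pixels H x W x 3 array in `[0, 1]`.
#' @param path output PNG.
#' @return `path`, invisibly.
#' @export
writeImageArray <- function(pixels, path) {
  png::writePNG(pixels, path)
  invisible(path)
}

#' Read / write a label mask as single-channel PNG
#'
#' Masks are stored as 8-bit grayscale PNG with the raw class indices
#' \{0, 1, 2\} in the low bits (value / 255 on disk).
#'
#' @param mask a [LabelMask-class].
#' @param path PNG file.
#' @param resolution_tag,origin tags for the mask read back.
#' @return `writeMaskPNG`: `path` invisibly; `readMaskPNG`: a
#'   [LabelMask-class].
#' @export
writeMaskPNG <- function(mask, path) {
  png::writePNG(mask@labels / 255, path)
  invisible(path)
}

#' @rdname writeMaskPNG
#' @export
readMaskPNG <- function(path, resolution_tag = "native",
                        origin = "ground_truth") {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  LabelMask(matrix(as.integer(round(m * 255)), nrow(m), ncol(m)),
            resolution_tag, origin)
}

# ---- manifest and series CSV ---------------------------------------------

#' Read an image manifest
#'
#' Manifest CSV schema: `image_id, path, timestamp, sensor, angle`. An empty
#' angle field maps to `"unknown"`. Timestamps must parse as
#' `YYYY-mm-dd HH:MM[:SS]` UTC.
#'
#' @param path manifest CSV.
#' @return data.frame with parsed columns.
#' @export
readImageManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(image_id = "character", path = "character",
                                timestamp = "character", sensor = "character",
                                angle = "character"))
  ts <- .parse_ts(df$timestamp)
  if (any(is.na(ts)))
    stop("malformed timestamp in manifest row(s): ",
         paste(which(is.na(ts)), collapse = ", "))
  df$angle[is.na(df$angle) | df$angle == ""] <- "unknown"
  bad <- which(!df$angle %in% .ANGLES)
  if (length(bad))
    stop("unknown camera angle in manifest row(s): ", paste(bad, collapse = ", "))
  bad <- which(!df$sensor %in% .SENSORS)
  if (length(bad))
    stop("unknown camera sensor in manifest row(s): ", paste(bad, collapse = ", "))
  df$timestamp <- ts
  df
}

#' Write / read an hourly activity series as CSV
#'
#' Schema: `timestamp, value`; missing hours serialize as empty value
#' fields. Round-trips are lossless (timestamps exactly, values to full
#' double precision).
#'
#' @param series an [ActivitySeries-class].
#' @param path CSV file.
#' @param coral,campaign tags attached on read.
#' @return `writeActivityCSV`: `path` invisibly; `readActivityCSV`: an
#'   [ActivitySeries-class].
#' @export
writeActivityCSV <- function(series, path) {
  df <- data.frame(
    timestamp = format(series@hours, "%Y-%m-%d %H:%M:%S"),
    value = ifelse(is.na(series@values), "",
                   trimws(formatC(series@values, digits = 17, format = "g"))))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeActivityCSV
#' @export
readActivityCSV <- function(path, coral = "C_r", campaign = "G1") {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(timestamp = "character", value = "character"))
  ts <- .parse_ts(df$timestamp)
  if (any(is.na(ts)))
    stop("malformed timestamp in row(s): ",
         paste(which(is.na(ts)), collapse = ", "))
  if (any(!.is_whole_hour(ts)))
    stop("non-hourly timestamp in row(s): ",
         paste(which(!.is_whole_hour(ts)), collapse = ", "))
  vals <- suppressWarnings(as.numeric(df$value))
  vals[df$value == ""] <- NA_real_
  ActivitySeries(ts, vals, coral, campaign)
}

#' Write / read an hourly sensor feature series as CSV
#'
#' Schema: `timestamp, T, d, v1, v2, v3`; missing components serialize as
#' empty fields.
#'
#' @param series a [SensorSeries-class].
#' @param path CSV file.
#' @param standardized flag attached on read.
#' @return `writeSensorCSV`: `path` invisibly; `readSensorCSV`: a
#'   [SensorSeries-class].
#' @export
writeSensorCSV <- function(series, path) {
  fmt <- function(v)
    ifelse(is.na(v), "", trimws(formatC(v, digits = 17, format = "g")))
  df <- data.frame(timestamp = format(series@hours, "%Y-%m-%d %H:%M:%S"))
  for (v in .SENSOR_VARS) df[[v]] <- fmt(series@features[, v])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSensorCSV
#' @export
readSensorCSV <- function(path, standardized = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 colClasses = "character")
  if (!all(c("timestamp", .SENSOR_VARS) %in% names(df)))
    stop("sensor CSV must have columns timestamp, T, d, v1, v2, v3")
  ts <- .parse_ts(df$timestamp)
  if (any(is.na(ts)))
    stop("malformed timestamp in row(s): ",
         paste(which(is.na(ts)), collapse = ", "))
  feats <- sapply(.SENSOR_VARS, function(v) {
    x <- suppressWarnings(as.numeric(df[[v]]))
    x[df[[v]] == ""] <- NA_real_
    x
  })
  if (length(ts) == 1L) feats <- matrix(feats, 1L, dimnames = list(NULL, .SENSOR_VARS))
  SensorSeries(ts, feats, standardized)
}

#' Read a raw (native-resolution) sensor table
#'
#' Long-format CSV with columns `timestamp, variable, value`, where variable
#' is one of T, d, v1, v2, v3 and records may be at 1-second, 10-minute or
#' hourly native resolution.
#'
#' @param path CSV file.
#' @return data.frame with parsed timestamp, variable, value.
#' @export
readRawSensorCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  ts <- .parse_ts(df$timestamp)
  if (any(is.na(ts)))
    stop("malformed timestamp in row(s): ",
         paste(which(is.na(ts)), collapse = ", "))
  bad <- which(!df$variable %in% .SENSOR_VARS)
  if (length(bad))
    stop("unknown variable in row(s): ", paste(bad, collapse = ", "))
  data.frame(timestamp = ts, variable = df$variable,
             value = as.numeric(df$value))
}
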