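# Colony activity scores: per image, the coral-portion-weighted mean of the
# binary patch classes over eligible patches (p >= 0.1); per hour, the
# unweighted mean of the per-image scores recorded in the half-open window
# [t - 30 min, t + 30 min), pooling both camera sensors and all angles.

#' Per-image colony activity
#'
#' `a = sum(p_j * k_j * [p_j >= p_min]) / sum(p_j * [p_j >= p_min])` over
#' the patches of one (image, coral): each eligible patch contributes its
#' class weighted by its coral portion, normalized by the total eligible
#' weight. Undefined (NA) when no eligible patch exists.
#'
#' @param patches a [PatchSet-class] with patches from a single image and
#'   coral.
#' @param use which class column to aggregate: `"k_hat"` (predictions, the
#'   estimation path) or `"k"` (true labels, the ground-truth path).
#' @param p_min eligibility threshold (0.1).
#' @return one-row data.frame: image_id, coral, a, n_patches, weight_sum.
#' @export
imageActivity <- function(patches, use = c("k_hat", "k"), p_min = 0.1) {
  use <- match.arg(use)
  info <- patches@info
  if (nrow(info)) {
    if (length(unique(info$image_id)) > 1L)
      stop("patches from multiple images: ",
           paste(unique(info$image_id), collapse = ", "))
    if (length(unique(info$coral)) > 1L)
      stop("patches from multiple corals")
  }
  k <- info[[use]]
  elig <- !is.na(k) & info$p >= p_min
  den <- sum(info$p[elig])
  a <- if (den > 0) sum(info$p[elig] * k[elig]) / den else NA_real_
  data.frame(
    image_id = if (nrow(info)) info$image_id[1] else NA_character_,
    coral = if (nrow(info)) info$coral[1] else NA_character_,
    a = a, n_patches = sum(elig), weight_sum = den)
}

#' Hourly activity series from per-image activities
#'
#' `a(t)` is the unweighted mean of all per-image activities whose
#' timestamps fall in the half-open window `[t - 30 min, t + 30 min)` —
#' a timestamp exactly at t + 30 min belongs to the next hour. Images from
#' both camera sensors and all angles pool into one mean. Hours with no
#' images are missing (never zero). Images at or after `cutoff` are
#' excluded (imagery is only sparsely available after it).
#'
#' @param activities data.frame with columns timestamp (POSIXct) and a
#'   (per-image activity, NA rows are dropped).
#' @param coral,campaign tags for the output series.
#' @param hours optional POSIXct grid of whole hours; defaults to the span
#'   of the data (window-rounded).
#' @param cutoff timestamp at/after which images are excluded
#'   (default 7 April 2019).
#' @return an [ActivitySeries-class].
#' @export
hourlySeries <- function(activities, coral = "C_r", campaign = "G1",
                         hours = NULL,
                         cutoff = .as_utc("2019-04-07 00:00:00")) {
  act <- activities[!is.na(activities$a), , drop = FALSE]
  if (!is.null(cutoff))
    act <- act[act$timestamp < .as_utc(cutoff), , drop = FALSE]
  if (is.null(hours)) {
    if (!nrow(act)) stop("no activities to aggregate and no hour grid given")
    rng <- range(as.numeric(act$timestamp))
    hours <- .hour_seq(.as_utc(floor((rng[1] + 1800) / 3600) * 3600),
                       .as_utc(floor((rng[2] + 1800) / 3600) * 3600))
  }
  ts <- as.numeric(act$timestamp)
  vals <- vapply(as.numeric(hours), function(h) {
    w <- which(ts >= h - 1800 & ts < h + 1800)
    if (length(w)) mean(act$a[w]) else NA_real_
  }, 0)
  ActivitySeries(hours, vals, coral, campaign)
}

#' Visibility filter for the distant colony
#'
#' The distant colony is out of frame at some camera angles; images whose
#' predicted colony region size falls strictly below `threshold` pixels are
#' excluded from that colony's activity computation (sizes exactly at the
#' threshold are kept). The default threshold is derived with
#' [blueVisibilityThreshold()].
#'
#' @param region_sizes data.frame from [regionSizeSeries()] for label 2.
#' @param threshold pixel-count threshold.
#' @return character vector of kept image ids.
#' @export
blueVisibilityFilter <- function(region_sizes, threshold) {
  region_sizes$image_id[region_sizes$pixels >= threshold]
}

#' Default region-size threshold for the visibility filter
#'
#' A quarter of the median predicted region size over images where the
#' colony is known (annotated or rendered) visible.
#'
#' @param region_sizes data.frame from [regionSizeSeries()].
#' @param visible_ids image ids with the colony known visible.
#' @return threshold in pixels.
#' @export
blueVisibilityThreshold <- function(region_sizes, visible_ids) {
  vis <- region_sizes$pixels[region_sizes$image_id %in% visible_ids]
  if (!length(vis)) stop("no visible reference images supplied")
  0.25 * median(vis)
}

#' Mean absolute error with presence penalty
#'
#' Compares estimated per-image activities with ground truth. Where both
#' are defined the image contributes `|a_hat - a|`; where the coral is
#' present in the ground truth but the pipeline produced no estimate (not
#' found by segmentation), or an estimate exists although the coral is
#' absent from the ground truth, the absolute error for that image is set
#' to 1. Images where both agree the coral is absent contribute 0.
#'
#' @param pred,truth data.frames with columns image_id, coral, a (NA = no
#'   value / coral absent).
#' @return the mean absolute error over the union of (image, coral) keys.
#' @export
maeWithPenalty <- function(pred, truth) {
  key <- function(df) paste(df$image_id, df$coral)
  keys <- union(key(pred), key(truth))
  pa <- pred$a[match(keys, key(pred))]
  ta <- truth$a[match(keys, key(truth))]
  err <- ifelse(!is.na(pa) & !is.na(ta), abs(pa - ta),
                ifelse(is.na(pa) & is.na(ta), 0, 1))
  mean(err)
}

#' Select the model pair with the lowest evaluation MAE
#'
#' @param maes named numeric vector of MAEs, one per candidate
#'   (segmenter, classifier) pair.
#' @return the name (or index) of the minimizer.
#' @export
selectModelPair <- function(maes) {
  i <- which.min(maes)
  if (!is.null(names(maes))) names(maes)[i] else i
}

#' Stitch per-interval activity series into one campaign series
#'
#' The final time series combines activity estimated by separate model
#' pairs for consecutive sub-intervals (each pair chosen by lowest MAE on
#' its interval). Output hours partition exactly at the boundary
#' timestamps: hour t is taken from the interval with
#' `boundaries[i] <= t < boundaries[i + 1]`.
#'
#' @param series_list list of [ActivitySeries-class], one per interval, in
#'   time order; `NULL` entries (unassigned intervals) are an error.
#' @param boundaries POSIXct vector of length `length(series_list) + 1`.
#' @param coral,campaign tags for the stitched series.
#' @return an [ActivitySeries-class] with interval boundaries recorded in
#'   the `"boundaries"` attribute.
#' @export
assembleFinalSeries <- function(series_list, boundaries, coral = "C_r",
                                campaign = "G1") {
  if (any(vapply(series_list, is.null, NA)))
    stop("unassigned interval: every interval needs a series")
  if (length(boundaries) != length(series_list) + 1L)
    stop("need length(series_list) + 1 boundaries")
  boundaries <- .as_utc(boundaries)
  hours <- .hour_seq(boundaries[1],
                     boundaries[length(boundaries)] - 3600)
  vals <- rep(NA_real_, length(hours))
  for (i in seq_along(series_list)) {
    s <- series_list[[i]]
    inwin <- hours >= boundaries[i] & hours < boundaries[i + 1]
    m <- match(as.numeric(hours[inwin]), as.numeric(s@hours))
    vals[inwin] <- s@values[m]
  }
  out <- ActivitySeries(hours, vals, coral, campaign)
  attr(out, "boundaries") <- boundaries
  out
}
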