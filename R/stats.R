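# Correlation and time-series statistics for hourly activity series:
# Spearman rank correlation with a t-distributed significance test,
# Gaussian smoothing that never bridges data gaps, and detection of
# multi-day low-activity ("sleeping") periods.

#' Align two hourly series on their common present hours
#'
#' Keeps exactly the hours at which both series have a present value, in
#' time order. This is the pairing rule used for all correlations: only
#' hours for which an activity value is available enter.
#'
#' @param x,y [ActivitySeries-class] or [SensorSeries-class] objects
#'   (a sensor series contributes the hours at which it is not gappy).
#' @return list with `hours`, `x`, `y` (paired value vectors; for a sensor
#'   series, a 5-column matrix) and `N` (pair count).
#' @export
alignSeries <- function(x, y) {
  hv <- function(s) {
    if (is(s, "ActivitySeries"))
      list(h = as.numeric(s@hours), present = !is.na(s@values),
           val = function(i) s@values[i])
    else if (is(s, "SensorSeries"))
      list(h = as.numeric(s@hours), present = !isGappy(s),
           val = function(i) s@features[i, , drop = FALSE])
    else stop("unsupported series type")
  }
  a <- hv(x); b <- hv(y)
  common <- intersect(a$h[a$present], b$h[b$present])
  if (!length(common)) stop("series have no overlapping present hours")
  common <- sort(common)
  ia <- match(common, a$h); ib <- match(common, b$h)
  list(hours = .as_utc(common), x = a$val(ia), y = b$val(ib),
       N = length(common))
}

#' Spearman rank correlation coefficient
#'
#' Pearson correlation of the average-ranked values (ties receive average
#' ranks). Defined for vectors of length >= 2 with nonzero rank variance.
#'
#' @param x,y equal-length numeric vectors.
#' @return the correlation in `[-1, 1]`.
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 2L) stop("need at least 2 paired values")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("constant vector: Spearman correlation undefined")
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

#' Significance test for a Spearman correlation
#'
#' Two-sided t-test with statistic `t = r_S * sqrt(N - 2) / sqrt(1 - r_S^2)`
#' on N - 2 degrees of freedom, appropriate for larger samples (N > 30).
#' For `|r_S| = 1` the statistic diverges; p = 0 is returned with a warning.
#'
#' @param r_s Spearman correlation.
#' @param N number of pairs (>= 3).
#' @return list with `t` and two-sided `p`.
#' @export
spearmanTest <- function(r_s, N) {
  if (N < 3L) stop("need N >= 3 for the t-test")
  if (abs(r_s) > 1) stop("|r_s| must be <= 1")
  if (abs(r_s) == 1) {
    warning("|r_s| = 1: test statistic diverges, p = 0 by convention")
    return(list(t = sign(r_s) * Inf, p = 0))
  }
  t <- r_s * sqrt(N - 2) / sqrt(1 - r_s^2)
  list(t = t, p = 2 * pt(-abs(t), df = N - 2))
}

#' Correlate an activity series with another series
#'
#' Convenience wrapper: aligns on common present hours, then computes the
#' Spearman correlation and its t-test. For a sensor series, one result row
#' per feature column.
#'
#' @param x an [ActivitySeries-class].
#' @param y an [ActivitySeries-class] or [SensorSeries-class].
#' @return data.frame with columns variable, r_s, t, p, N.
#' @export
correlateSeries <- function(x, y) {
  al <- alignSeries(x, y)
  one <- function(name, yv) {
    r <- spearmanRho(al$x, yv)
    tst <- suppressWarnings(spearmanTest(r, al$N))
    data.frame(variable = name, r_s = r, t = tst$t, p = tst$p, N = al$N)
  }
  if (is.matrix(al$y))
    do.call(rbind, lapply(colnames(al$y), function(v) one(v, al$y[, v])))
  else one("series", al$y)
}

#' Gaussian smoothing of an hourly activity series
#'
#' Convolution with a discrete Gaussian kernel (truncated at 4 sigma,
#' renormalized wherever the window is cut short) applied independently
#' within each maximal contiguous run of present hours: the filter never
#' smooths across a gap. Values whose previous or next hour is missing are
#' flagged, mirroring the "x" markers used when plotting such series.
#'
#' @param series an [ActivitySeries-class].
#' @param sigma kernel standard deviation in hours (default 10).
#' @return list with `series` (smoothed, on the full hourly grid between
#'   the first and last hour) and `flagged` (logical vector: present value
#'   adjacent to a gap).
#' @export
gaussianSmooth <- function(series, sigma = 10) {
  if (sigma <= 0) stop("sigma must be positive")
  hours <- series@hours
  grid <- .hour_seq(hours[1], hours[length(hours)])
  v <- rep(NA_real_, length(grid))
  v[match(as.numeric(hours), as.numeric(grid))] <- series@values
  K <- ceiling(4 * sigma)
  kern <- dnorm(-K:K, 0, sigma)
  out <- rep(NA_real_, length(v))
  present <- !is.na(v)
  r <- rle(present)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    run <- v[starts[j]:ends[j]]
    L <- length(run)
    sm <- numeric(L)
    for (i in seq_len(L)) {
      lo <- max(1L, i - K); hi <- min(L, i + K)
      w <- kern[(lo - i + K + 1L):(hi - i + K + 1L)]
      sm[i] <- sum(w * run[lo:hi]) / sum(w)
    }
    out[starts[j]:ends[j]] <- sm
  }
  flagged <- logical(length(grid))
  prev_missing <- c(TRUE, !present[-length(present)])
  next_missing <- c(!present[-1], TRUE)
  flagged[present] <- (prev_missing | next_missing)[present]
  list(series = ActivitySeries(grid, out, series@coral, series@campaign),
       flagged = flagged)
}

# strict local maxima above a threshold within one run of present values;
# plateaus collapse to one peak, run boundaries compare one-sided
.count_peaks <- function(v, threshold) {
  keep <- c(TRUE, diff(v) != 0)
  u <- v[keep]
  m <- length(u)
  if (m == 1L) return(as.integer(u > threshold))
  up_left <- c(TRUE, diff(u) > 0)
  down_right <- c(diff(u) < 0, TRUE)
  sum(up_left & down_right & u > threshold)
}

#' Detect multi-day low-activity periods
#'
#' Finds maximal time intervals in which the smoothed activity curve shows
#' at most one single peak greater than `peak_threshold`. Peaks are strict
#' local maxima of the smoothed curve; missing hours neither host peaks nor
#' break a period. Intervals shorter than `min_days` are dropped. Where two
#' single-peak excursions share a below-threshold stretch, the two maximal
#' intervals overlap on that stretch (no single period ever spans both
#' peaks).
#'
#' @param smoothed a smoothed [ActivitySeries-class] (see
#'   [gaussianSmooth()]).
#' @param peak_threshold activity level a peak must exceed (default 0.1).
#' @param min_days minimum period length in whole days (default 5).
#' @param max_above_fraction upper bound on the fraction of a period's
#'   present hours that may lie above the threshold (default 0.25):
#'   a sustained high plateau is high activity, not a low-activity period
#'   with one broad peak.
#' @return data.frame with columns coral, campaign, start, end (exclusive
#'   bound), duration_days (floor of full days between start and end) and
#'   peaks.
#' @export
detectLowActivity <- function(smoothed, peak_threshold = 0.1, min_days = 5,
                              max_above_fraction = 0.25) {
  hours <- smoothed@hours
  vals <- smoothed@values
  pres <- which(!is.na(vals))
  empty <- data.frame(coral = character(), campaign = character(),
                      start = .as_utc(numeric(0)), end = .as_utc(numeric(0)),
                      duration_days = integer(), peaks = integer())
  if (!length(pres)) return(empty)
  h <- hours[pres]; v <- vals[pres]
  above <- v > peak_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nseg <- length(r$values)
  seg_peaks <- vapply(seq_len(nseg), function(j) {
    if (!r$values[j]) 0L
    else as.integer(.count_peaks(v[starts[j]:ends[j]], peak_threshold))
  }, 0L)
  # maximal interval of consecutive segments with total peak count <= 1:
  # for each start segment, extend right while the budget holds; keep
  # non-dominated intervals
  cand <- list(); n <- 0L
  j <- 1L
  while (j <= nseg) {
    total <- 0L; k <- j
    while (k <= nseg && total + seg_peaks[k] <= 1L) {
      total <- total + seg_peaks[k]
      k <- k + 1L
    }
    if (k == j) { j <- j + 1L; next }  # segment alone exceeds the budget
    n <- n + 1L
    cand[[n]] <- c(j, k - 1L, total)
    # next maximal interval starts after the first peak-bearing segment
    nxt <- which(seg_peaks[j:(k - 1L)] > 0L)
    j <- if (length(nxt)) j + nxt[1] else k
  }
  if (!n) return(empty)
  rows <- lapply(cand, function(ck) {
    i0 <- starts[ck[1]]; i1 <- ends[ck[2]]
    if (mean(above[i0:i1]) > max_above_fraction) return(NULL)
    start <- h[i0]
    end <- h[i1] + 3600  # exclusive bound
    data.frame(coral = smoothed@coral, campaign = smoothed@campaign,
               start = start, end = end,
               duration_days = as.integer(floor(as.numeric(end - start,
                                                           units = "days"))),
               peaks = ck[3])
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("start", "end")]), , drop = FALSE]
  # drop intervals nested inside another candidate (keep maximal ones only)
  keep <- vapply(seq_len(nrow(out)), function(i) {
    !any(out$start <= out$start[i] & out$end >= out$end[i] &
           (out$start < out$start[i] | out$end > out$end[i]))
  }, NA)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out[out$duration_days >= min_days, , drop = FALSE]
}
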