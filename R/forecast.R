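# Activity prediction from sensor data: an LSTM reads sliding eta-hour
# windows of the standardized hourly feature series and outputs the
# activity at the window's last hour. A fresh model is trained for every
# week to predict, on the eight weeks before it; the window pair then
# shifts by one week (rolling retraining, no cross-week state). Outputs
# are clipped to [0, 1] at test time only.

.sigm <- function(x) 1 / (1 + exp(-x))

.lstm_init <- function(n_in, H) {
  s <- 1 / sqrt(H)
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1  # forget-gate bias starts open
  list(Wx = matrix(runif(n_in * 4 * H, -s, s), n_in, 4 * H),
       Wh = matrix(runif(H * 4 * H, -s, s), H, 4 * H),
       b = b,
       Wo = matrix(runif(H, -s, s), H, 1),
       bo = 0)
}

# forward over an X (B x eta x n_in) batch; returns prediction and caches
.lstm_forward <- function(X, p, H, keep_cache = TRUE) {
  B <- dim(X)[1]; eta <- dim(X)[2]
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  cache <- if (keep_cache) vector("list", eta) else NULL
  for (t in seq_len(eta)) {
    xt <- X[, t, , drop = TRUE]
    if (is.null(dim(xt))) xt <- matrix(xt, B)
    z <- xt %*% p$Wx + h %*% p$Wh
    z <- sweep(z, 2, p$b, "+")
    ii <- .sigm(z[, 1:H, drop = FALSE])
    ff <- .sigm(z[, (H + 1):(2 * H), drop = FALSE])
    gg <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    oo <- .sigm(z[, (3 * H + 1):(4 * H), drop = FALSE])
    cnew <- ff * cc + ii * gg
    tc <- tanh(cnew)
    hnew <- oo * tc
    if (keep_cache)
      cache[[t]] <- list(x = xt, hprev = h, cprev = cc, i = ii, f = ff,
                         g = gg, o = oo, tc = tc)
    h <- hnew; cc <- cnew
  }
  yhat <- as.numeric(h %*% p$Wo + p$bo)
  list(yhat = yhat, h = h, cache = cache)
}

.lstm_backward <- function(fw, p, dy, H) {
  cache <- fw$cache
  eta <- length(cache)
  B <- length(dy)
  g <- list(Wx = p$Wx * 0, Wh = p$Wh * 0, b = p$b * 0, Wo = p$Wo * 0, bo = 0)
  g$Wo <- crossprod(fw$h, matrix(dy))
  g$bo <- sum(dy)
  dh <- tcrossprod(matrix(dy), p$Wo)
  dc <- matrix(0, B, H)
  for (t in rev(seq_len(eta))) {
    cs <- cache[[t]]
    do_ <- dh * cs$tc
    dc <- dc + dh * cs$o * (1 - cs$tc^2)
    di <- dc * cs$g
    dfr <- dc * cs$cprev
    dg <- dc * cs$i
    dzi <- di * cs$i * (1 - cs$i)
    dzf <- dfr * cs$f * (1 - cs$f)
    dzg <- dg * (1 - cs$g^2)
    dzo <- do_ * cs$o * (1 - cs$o)
    dz <- cbind(dzi, dzf, dzg, dzo)
    g$Wx <- g$Wx + crossprod(cs$x, dz)
    g$Wh <- g$Wh + crossprod(cs$hprev, dz)
    g$b <- g$b + colSums(dz)
    dh <- tcrossprod(dz, p$Wh)
    dc <- dc * cs$f
  }
  g
}

.lstm_train <- function(X, y, cfg, seed) {
  H <- cfg@hidden_size
  .with_seed(seed, {
    p <- .lstm_init(dim(X)[3], H)
    opt <- .adam_new(p)
    n <- dim(X)[1]
    final_loss <- NA_real_
    for (ep in seq_len(cfg@epochs)) {
      ord <- sample(n)
      tot <- 0
      for (start in seq(1, n, by = cfg@batch_size)) {
        idx <- ord[start:min(start + cfg@batch_size - 1, n)]
        Xb <- X[idx, , , drop = FALSE]
        fw <- .lstm_forward(Xb, p, H)
        err <- fw$yhat - y[idx]         # squared-error loss on raw outputs
        tot <- tot + sum(err^2)
        dy <- 2 * err / length(idx)
        grads <- .lstm_backward(fw, p, dy, H)
        st <- .adam_step(p, grads, opt, cfg@learning_rate)
        p <- st$params; opt <- st$state
      }
      final_loss <- tot / n
    }
    list(params = p, final_loss = final_loss)
  })
}

#' Build sliding input windows from a standardized sensor series
#'
#' One window per hour t whose `eta` consecutive hourly feature vectors
#' (t - eta + 1, ..., t) are all present and gap-free after the gap policy;
#' the window's output target hour is its last hour. A window length
#' exceeding the series length yields an empty result, not an error.
#'
#' @param sensor a standardized [SensorSeries-class] (on a contiguous
#'   hourly grid, e.g. from [fillGaps()]).
#' @param eta window length in hours.
#' @return list with `hours` (POSIXct targets) and `X`
#'   (n x eta x 5 array), in time order.
#' @export
makeWindows <- function(sensor, eta) {
  if (!sensor@standardized)
    stop("makeWindows expects a standardized sensor series")
  eta <- as.integer(eta)
  hours <- sensor@hours
  n <- length(hours)
  empty <- list(hours = .as_utc(numeric(0)), X = array(0, c(0, eta, 5)))
  if (eta > n) return(empty)
  contiguous <- c(rep(TRUE, 1), diff(as.numeric(hours)) == 3600)
  ok_hour <- !isGappy(sensor) & contiguous
  ok_hour[1] <- !isGappy(sensor)[1]
  # window at i valid iff hours i-eta+1 .. i all gap-free and consecutive
  run <- cumsum(ok_hour)
  valid <- vapply(seq_len(n), function(i) {
    if (i < eta) return(FALSE)
    all(ok_hour[(i - eta + 1):i]) &&
      all(diff(as.numeric(hours[(i - eta + 1):i])) == 3600)
  }, NA)
  idx <- which(valid)
  if (!length(idx)) return(empty)
  X <- array(0, c(length(idx), eta, 5))
  for (j in seq_along(idx))
    X[j, , ] <- sensor@features[(idx[j] - eta + 1):idx[j], ]
  list(hours = hours[idx], X = X)
}

#' Rolling-retrain activity forecast from sensor data
#'
#' For each week starting at t': a fresh recurrent model is trained on
#' (window, target) pairs whose windows lie entirely within the eight
#' weeks before t' (sensor standardization is fitted on that training
#' window only), then predicts the activity for t in [t', t' + 1 week),
#' clipped to [0, 1]; the window pair shifts by one week and the process
#' repeats until every predictable hour is covered. Hours whose input
#' window is unavailable (gaps) stay missing. Weeks whose training targets
#' are more than half missing are skipped with a warning. Evaluation can
#' only start once a full training span of prior data exists; earlier
#' hours are excluded.
#'
#' @param sensor an hourly [SensorSeries-class] in raw units.
#' @param truth an [ActivitySeries-class] used as training target (and for
#'   the evaluation MAE over predicted hours).
#' @param config a [ForecastConfig()].
#' @return a [ForecastResult-class].
#' @export
rollingForecast <- function(sensor, truth, config = ForecastConfig()) {
  cfg <- config
  gp <- fillGaps(sensor, cfg@gap_policy, cfg@ffill_limit)
  sens <- gp$series
  eta <- cfg@window_length
  t_first <- max(as.numeric(sens@hours[1]), as.numeric(truth@hours[1]))
  t_last <- min(as.numeric(sens@hours[length(sens@hours)]),
                as.numeric(truth@hours[length(truth@hours)]))
  eval_start <- t_first + cfg@train_span * 3600
  if (eval_start > t_last)
    stop("series too short for one training span")
  week_starts <- seq(eval_start, t_last, by = cfg@predict_span * 3600)

  pred_hours <- .as_utc(numeric(0)); pred_vals <- numeric(0)
  logs <- list()
  for (wi in seq_along(week_starts)) {
    t0 <- week_starts[wi]
    train_lo <- t0 - cfg@train_span * 3600
    train_idx <- which(as.numeric(sens@hours) >= train_lo &
                       as.numeric(sens@hours) < t0)
    swk <- SensorSeries(sens@hours[train_idx],
                        sens@features[train_idx, , drop = FALSE])
    std <- standardizeSensors(swk)
    win <- makeWindows(std$series, eta)
    tv <- truth@values[match(as.numeric(win$hours), as.numeric(truth@hours))]
    have <- !is.na(tv)
    seed_w <- cfg@seed + wi
    if (!length(tv) || mean(have) < 0.5) {
      warning("week ", wi, ": training targets more than half missing; skipped")
      logs[[wi]] <- data.frame(week = wi, train_start = .as_utc(train_lo),
                               predict_start = .as_utc(t0), seed = seed_w,
                               n_train = sum(have), final_loss = NA_real_,
                               n_predicted = 0L)
      next
    }
    fit <- .lstm_train(win$X[have, , , drop = FALSE], tv[have], cfg, seed_w)

    # prediction block: standardize with the training-window parameters
    blk_idx <- which(as.numeric(sens@hours) >= train_lo &
                     as.numeric(sens@hours) < t0 + cfg@predict_span * 3600)
    sblk <- SensorSeries(sens@hours[blk_idx],
                         sens@features[blk_idx, , drop = FALSE])
    stdb <- standardizeSensors(sblk, params = std$params)
    winb <- makeWindows(stdb$series, eta)
    sel <- which(as.numeric(winb$hours) >= t0 &
                 as.numeric(winb$hours) < t0 + cfg@predict_span * 3600)
    n_pred <- length(sel)
    if (n_pred) {
      fw <- .lstm_forward(winb$X[sel, , , drop = FALSE], fit$params,
                          cfg@hidden_size, keep_cache = FALSE)
      pred_hours <- c(pred_hours, winb$hours[sel])
      pred_vals <- c(pred_vals, pmin(pmax(fw$yhat, 0), 1))  # clip at test time
    }
    logs[[wi]] <- data.frame(week = wi, train_start = .as_utc(train_lo),
                             predict_start = .as_utc(t0), seed = seed_w,
                             n_train = sum(have), final_loss = fit$final_loss,
                             n_predicted = n_pred)
  }
  ord <- order(pred_hours)
  grid <- if (length(pred_hours))
    .hour_seq(min(pred_hours), max(pred_hours)) else .as_utc(numeric(0))
  vals <- rep(NA_real_, length(grid))
  vals[match(as.numeric(pred_hours[ord]), as.numeric(grid))] <- pred_vals[ord]
  predicted <- ActivitySeries(grid, vals, truth@coral, truth@campaign)
  mae <- tryCatch(forecastMae(predicted, truth), error = function(e) NA_real_)
  new("ForecastResult", predicted = predicted,
      weekly_log = do.call(rbind, logs), mae = mae)
}

#' Forecast mean absolute error
#'
#' Mean of `|a_hat(t) - a(t)|` over the hours where both series have a
#' present value.
#'
#' @param predicted,truth [ActivitySeries-class] objects.
#' @return the MAE.
#' @export
forecastMae <- function(predicted, truth) {
  al <- alignSeries(predicted, truth)
  mean(abs(al$x - al$y))
}

#' MAE of the best constant predictor
#'
#' The constant minimizing the mean absolute error against a series is its
#' median; used as the baseline a forecaster must beat to demonstrate
#' signal recovery.
#'
#' @param truth an [ActivitySeries-class].
#' @param hours optional hours to restrict to.
#' @return list with `constant` and `mae`.
#' @export
bestConstantMae <- function(truth, hours = NULL) {
  v <- truth@values
  if (!is.null(hours))
    v <- v[as.numeric(truth@hours) %in% as.numeric(hours)]
  v <- v[!is.na(v)]
  if (!length(v)) stop("no present values")
  m <- median(v)
  list(constant = m, mae = mean(abs(v - m)))
}
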