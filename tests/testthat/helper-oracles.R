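# Independent brute-force oracles used to check the package's
# implementations. These deliberately share no code with the package
# internals.

# even-odd point-in-polygon with boundary-inclusive pixels, one pixel at a
# time (the rasterizer oracle)
bf_point_in_polygon <- function(px, py, verts) {
  n <- nrow(verts)
  inside <- FALSE
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- verts[i, 1]; y1 <- verts[i, 2]
    x2 <- verts[j, 1]; y2 <- verts[j, 2]
    # boundary check
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    if (abs(cross) < 1e-9 &&
        px >= min(x1, x2) - 1e-9 && px <= max(x1, x2) + 1e-9 &&
        py >= min(y1, y2) - 1e-9 && py <= max(y1, y2) + 1e-9)
      return(TRUE)
    if ((y1 > py) != (y2 > py)) {
      xi <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      if (px < xi) inside <- !inside
    }
  }
  inside
}

bf_rasterize <- function(verts, H, W) {
  m <- matrix(FALSE, H, W)
  for (iy in 0:(H - 1))
    for (ix in 0:(W - 1))
      m[iy + 1, ix + 1] <- bf_point_in_polygon(ix, iy, verts)
  m
}

# Jaccard from explicit pixel index sets
bf_jaccard <- function(pred, truth, label) {
  a <- which(pred == label)
  b <- which(truth == label)
  u <- union(a, b)
  if (!length(u)) return(1)
  length(intersect(a, b)) / length(u)
}

# precision/recall/F1 from an explicitly tabulated confusion matrix
bf_prf <- function(truth, pred, cl) {
  cm <- table(factor(truth, levels = 0:1), factor(pred, levels = 0:1))
  tp <- cm[as.character(cl), as.character(cl)]
  fp <- sum(cm[, as.character(cl)]) - tp
  fn <- sum(cm[as.character(cl), ]) - tp
  P <- if (tp + fp > 0) tp / (tp + fp) else 0
  R <- if (tp + fn > 0) tp / (tp + fn) else 0
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  c(P = P, R = R, F1 = F1)
}

# Spearman via explicit average ranks and the definitional sum formula
bf_spearman <- function(x, y) {
  rk <- function(v) {
    o <- order(v)
    r <- numeric(length(v))
    i <- 1L
    while (i <= length(v)) {
      j <- i
      while (j < length(v) && v[o[j + 1]] == v[o[i]]) j <- j + 1L
      r[o[i:j]] <- mean(i:j)
      i <- j + 1L
    }
    r
  }
  rx <- rk(x); ry <- rk(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# weighted activity score by direct filtering and summation
bf_activity <- function(p, k, p_min = 0.1) {
  keep <- p >= p_min
  if (!any(keep) || sum(p[keep]) == 0) return(NA_real_)
  sum(p[keep] * k[keep]) / sum(p[keep])
}

# two-step median by explicit subdivision of one hour-centred window
bf_two_step_median <- function(ts, vals, hour) {
  lo <- as.numeric(hour) - 1800
  w <- ts >= lo & ts < as.numeric(hour) + 1800
  if (!any(w)) return(NA_real_)
  sub <- floor((ts[w] - lo) / 600)
  tenmin <- sapply(split(vals[w], sub), median)
  median(tenmin)
}

# small scene helpers -------------------------------------------------------

tiny_scene <- function(seed = 1L, angle = "theta1", frac = 0.5, ...) {
  renderScene(sceneSpec(image_size = c(128L, 160L), angle = angle,
                        extended_fraction_red = frac,
                        extended_fraction_blue = frac, seed = seed, ...),
              image_id = paste0("tiny", seed))
}

# a minimal PatchSet carrying given weights and labels (pixel content is
# irrelevant for the aggregation operations)
mk_patchset <- function(p, k = NA_integer_, k_hat = NA_integer_,
                        image_id = "im1", coral = "C_r") {
  n <- length(p)
  info <- data.frame(
    patch_id = sprintf("%s_%s_%d", image_id, coral, seq_len(n)),
    image_id = rep(image_id, n), coral = rep(coral, n),
    x = as.integer(seq_len(n) * 8L), y = rep(0L, n), p = p,
    k = rep_len(as.integer(k), n), k_hat = rep_len(as.integer(k_hat), n),
    mask_origin = "ground_truth")
  new("PatchSet", info = info,
      pixels = replicate(n, array(0, c(8, 8, 3)), simplify = FALSE),
      patch_size = 8L)
}

mk_patchset_raw <- mk_patchset   # same builder; name marks sets that keep
                                 # sub-threshold patches for the indicator

hours_from <- function(start, n) {
  seq(as.POSIXct(start, tz = "UTC"), by = 3600, length.out = n)
}
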