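# Minimal CNN machinery: stride-1 "same" convolutions lowered to GEMMs via
# the compiled im2col/col2im kernels, 2x2 max pooling, nearest-neighbour
# up/down-sampling, ReLU, softmax cross-entropy and Adam. Feature maps are
# H x W x C arrays; the (H*W) x C matrix view shares their memory layout.

.as_map <- function(m, H, W, C) { dim(m) <- c(H, W, C); m }
.as_mat <- function(a) { d <- dim(a); dim(a) <- c(d[1] * d[2], d[3]); a }

.he_init <- function(nin, nout) {
  matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

.conv_fwd <- function(x, W, b, k) {
  d <- dim(x)
  cols <- pa_im2col(x, d[1], d[2], d[3], k)
  out <- cols %*% W
  out <- sweep(out, 2, b, "+")
  list(out = .as_map(out, d[1], d[2], ncol(W)), cols = cols, in_dim = d)
}

.conv_bwd <- function(dout, cache, W, k) {
  dmat <- .as_mat(dout)
  dW <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dcols <- tcrossprod(dmat, W)
  d <- cache$in_dim
  dx <- pa_col2im(dcols, d[1], d[2], d[3], k)
  list(dW = dW, db = db, dx = .as_map(dx, d[1], d[2], d[3]))
}

.relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}

.pool_fwd <- function(x) {
  d <- dim(x)
  r <- pa_maxpool2(x, d[1], d[2], d[3])
  list(out = .as_map(r$out, d[1] / 2, d[2] / 2, d[3]), idx = r$idx, in_dim = d)
}

.pool_bwd <- function(dout, cache) {
  d <- cache$in_dim
  .as_map(pa_maxpool2_bwd(dout, cache$idx, d[1], d[2], d[3]), d[1], d[2], d[3])
}

.up_fwd <- function(x) {
  d <- dim(x)
  .as_map(pa_upsample2(x, d[1], d[2], d[3]), 2 * d[1], 2 * d[2], d[3])
}

.up_bwd <- function(dout, in_dim) {
  .as_map(pa_upsample2_bwd(dout, in_dim[1], in_dim[2], in_dim[3]),
          in_dim[1], in_dim[2], in_dim[3])
}

# softmax cross-entropy over rows of an n x K logit matrix;
# returns loss and dlogits already divided by the total weight
.softmax_ce <- function(logits, target, wpix = NULL) {
  n <- nrow(logits)
  m <- logits - apply(logits, 1, max)
  e <- exp(m)
  p <- e / rowSums(e)
  if (is.null(wpix)) wpix <- rep(1, n)
  idx <- cbind(seq_len(n), target + 1L)
  loss <- -sum(wpix * log(pmax(p[idx], 1e-12))) / sum(wpix)
  d <- p
  d[idx] <- d[idx] - 1
  d <- d * (wpix / sum(wpix))
  list(loss = loss, dlogits = d, probs = p)
}

.adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# bilinear resampling of an H x W x C array (used for images); masks use
# .resize_nearest to keep labels crisp
.resize_bilinear <- function(x, Ho, Wo) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]
  sy <- pmin(pmax((seq_len(Ho) - 0.5) * H / Ho - 0.5, 0), H - 1)
  sx <- pmin(pmax((seq_len(Wo) - 0.5) * W / Wo - 0.5, 0), W - 1)
  y0 <- pmin(floor(sy), H - 1); y1 <- pmin(y0 + 1, H - 1)
  x0 <- pmin(floor(sx), W - 1); x1 <- pmin(x0 + 1, W - 1)
  fy <- sy - y0; fx <- sx - x0
  out <- array(0, c(Ho, Wo, C))
  for (ch in seq_len(C)) {
    m <- x[, , ch]
    a <- m[y0 + 1, x0 + 1, drop = FALSE]; b <- m[y0 + 1, x1 + 1, drop = FALSE]
    cc <- m[y1 + 1, x0 + 1, drop = FALSE]; dd <- m[y1 + 1, x1 + 1, drop = FALSE]
    top <- a * (1 - fx)[col(a)] + b * fx[col(b)]
    bot <- cc * (1 - fx)[col(cc)] + dd * fx[col(dd)]
    out[, , ch] <- top * (1 - fy)[row(top)] + bot * fy[row(bot)]
  }
  out
}

.resize_nearest <- function(m, Ho, Wo) {
  H <- nrow(m); W <- ncol(m)
  yi <- pmin(pmax(floor((seq_len(Ho) - 0.5) * H / Ho) + 1, 1), H)
  xi <- pmin(pmax(floor((seq_len(Wo) - 0.5) * W / Wo) + 1, 1), W)
  m[yi, xi, drop = FALSE]
}

#' Seeded train/validation/test split of image ids
#'
#' Random split of images into train/val/test (default 60/20/20) with a
#' fixed seed, mirroring the per-image splitting used for both the
#' segmentation and the patch-classification datasets (patches always
#' inherit their source image's split).
#'
#' @param image_ids character vector.
#' @param fractions length-3 numeric summing to 1 (train, val, test).
#' @param seed RNG seed.
#' @return list with character vectors `train`, `val`, `test`.
#' @export
seededSplit <- function(image_ids, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-9)
  n <- length(image_ids)
  .with_seed(seed, {
    perm <- sample(image_ids)
    n_train <- round(fractions[1] * n)
    n_val <- round(fractions[2] * n)
    list(train = perm[seq_len(n_train)],
         val = perm[n_train + seq_len(n_val)],
         test = perm[seq(n_train + n_val + 1, length.out = n - n_train - n_val)])
  })
}
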