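# Colony segmentation: a compact encoder-decoder ("U"-shaped) network with
# two pooling levels, skip connections, and zero-padded stride-1
# convolutions throughout, so the predicted label map always matches its
# input size. Images are downscaled to the configured working size for the
# network and predicted masks are upscaled back to native resolution by
# nearest neighbour so patches can be cut from original-resolution images.

#' Segmentation configuration
#'
#' @param input_size working `(H, W)` of the network; both divisible by 4.
#'   The full-scale setting is `(551, 688)` rounded to `(552, 688)`; the
#'   desk-scale default is `(128, 160)`.
#' @param channels widths of (enc1, enc2, bottleneck, dec2, dec1).
#' @param n_classes number of semantic classes (3: background, C_r, C_b).
#' @param learning_rate Adam step size.
#' @param epochs training epochs; the best-on-validation checkpoint is kept.
#' @param apply_gamma whether inputs are gamma-corrected before the network
#'   (both for training and inference).
#' @param gamma gamma-correction exponent.
#' @param class_weight_cap cap on inverse-frequency class weights.
#' @param seed RNG seed for weight init and epoch shuffling.
#' @return config list.
#' @export
segConfig <- function(input_size = c(128L, 160L),
                      channels = c(8L, 16L, 24L, 16L, 12L),
                      n_classes = 3L, learning_rate = 3e-3, epochs = 12L,
                      apply_gamma = TRUE, gamma = 0.3,
                      class_weight_cap = 8, seed = 1L) {
  if (any(input_size %% 4L != 0L))
    stop("input_size must be divisible by 4 (two pooling levels)")
  list(input_size = as.integer(input_size), channels = as.integer(channels),
       n_classes = 3L, learning_rate = learning_rate,
       epochs = as.integer(epochs), apply_gamma = apply_gamma, gamma = gamma,
       class_weight_cap = class_weight_cap, seed = as.integer(seed))
}

.seg_init <- function(cfg) {
  ch <- cfg$channels
  list(W1 = .he_init(9 * 3, ch[1]), b1 = numeric(ch[1]),
       W2 = .he_init(9 * ch[1], ch[2]), b2 = numeric(ch[2]),
       W3 = .he_init(9 * ch[2], ch[3]), b3 = numeric(ch[3]),
       W4 = .he_init(9 * (ch[3] + ch[2]), ch[4]), b4 = numeric(ch[4]),
       W5 = .he_init(9 * (ch[4] + ch[1]), ch[5]), b5 = numeric(ch[5]),
       W6 = .he_init(ch[5], cfg$n_classes), b6 = numeric(cfg$n_classes))
}

.cat3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- c(a, b)
  dim(out) <- c(da[1], da[2], da[3] + db[3])
  out
}

.seg_forward <- function(x, p, keep_cache = TRUE) {
  f1 <- .conv_fwd(x, p$W1, p$b1, 3); r1 <- .relu_fwd(f1$out)
  p1 <- .pool_fwd(r1$out)
  f2 <- .conv_fwd(p1$out, p$W2, p$b2, 3); r2 <- .relu_fwd(f2$out)
  p2 <- .pool_fwd(r2$out)
  f3 <- .conv_fwd(p2$out, p$W3, p$b3, 3); r3 <- .relu_fwd(f3$out)
  u2 <- .up_fwd(r3$out)
  cat2 <- .cat3(u2, r2$out)
  f4 <- .conv_fwd(cat2, p$W4, p$b4, 3); r4 <- .relu_fwd(f4$out)
  u1 <- .up_fwd(r4$out)
  cat1 <- .cat3(u1, r1$out)
  f5 <- .conv_fwd(cat1, p$W5, p$b5, 3); r5 <- .relu_fwd(f5$out)
  logits <- sweep(.as_mat(r5$out) %*% p$W6, 2, p$b6, "+")
  if (!keep_cache) return(list(logits = logits))
  list(logits = logits, f1 = f1, r1 = r1, p1 = p1, f2 = f2, r2 = r2,
       p2 = p2, f3 = f3, r3 = r3, f4 = f4, r4 = r4, f5 = f5, r5 = r5)
}

.seg_backward <- function(cache, p, dlogits, cfg) {
  ch <- cfg$channels
  g <- list()
  r5m <- .as_mat(cache$r5$out)
  g$W6 <- crossprod(r5m, dlogits); g$b6 <- colSums(dlogits)
  dr5 <- tcrossprod(dlogits, p$W6)
  d5 <- dim(cache$r5$out); dim(dr5) <- d5
  dr5 <- dr5 * cache$r5$mask
  bw5 <- .conv_bwd(dr5, cache$f5, p$W5, 3)
  g$W5 <- bw5$dW; g$b5 <- bw5$db
  dcat1 <- bw5$dx
  du1 <- dcat1[, , seq_len(ch[4]), drop = FALSE]
  da1_skip <- dcat1[, , ch[4] + seq_len(ch[1]), drop = FALSE]
  dr4 <- .up_bwd(du1, dim(cache$r4$out)) * cache$r4$mask
  bw4 <- .conv_bwd(dr4, cache$f4, p$W4, 3)
  g$W4 <- bw4$dW; g$b4 <- bw4$db
  dcat2 <- bw4$dx
  du2 <- dcat2[, , seq_len(ch[3]), drop = FALSE]
  da2_skip <- dcat2[, , ch[3] + seq_len(ch[2]), drop = FALSE]
  dr3 <- .up_bwd(du2, dim(cache$r3$out)) * cache$r3$mask
  bw3 <- .conv_bwd(dr3, cache$f3, p$W3, 3)
  g$W3 <- bw3$dW; g$b3 <- bw3$db
  dp2 <- .pool_bwd(bw3$dx, cache$p2)
  dr2 <- (dp2 + da2_skip) * cache$r2$mask
  bw2 <- .conv_bwd(dr2, cache$f2, p$W2, 3)
  g$W2 <- bw2$dW; g$b2 <- bw2$db
  dp1 <- .pool_bwd(bw2$dx, cache$p1)
  dr1 <- (dp1 + da1_skip) * cache$r1$mask
  bw1 <- .conv_bwd(dr1, cache$f1, p$W1, 3)
  g$W1 <- bw1$dW; g$b1 <- bw1$db
  g
}

.seg_preprocess <- function(image, cfg) {
  px <- image@pixels
  if (cfg$apply_gamma) px <- gammaCorrect(px, cfg$gamma)
  .resize_bilinear(px, cfg$input_size[1], cfg$input_size[2])
}

#' Train the colony segmentation network
#'
#' Trains the encoder-decoder on (image, mask) pairs, evaluating the model
#' on the validation set after every epoch and keeping the weights of the
#' best validation macro-Jaccard epoch (not the last). Masks are supplied
#' at native resolution and downscaled internally together with the images.
#' Pixel losses are weighted by capped inverse class frequency.
#'
#' @param train,val lists whose elements carry `$image`
#'   ([ImageRecord-class]) and `$mask` ([LabelMask-class], native
#'   resolution), e.g. the `scenes` of [simulateCampaign()].
#' @param config a [segConfig()].
#' @param interval training interval tag (`"t1"`, `"t2"` or `"star"`).
#' @param verbose print per-epoch validation scores.
#' @return a [SegModel-class].
#' @export
trainSegmenter <- function(train, val, config = segConfig(),
                           interval = "t1", verbose = FALSE) {
  if (!length(train) || !length(val)) stop("empty train or validation set")
  chans <- unique(vapply(train, function(s) dim(s$image@pixels)[3], 0))
  if (length(chans) != 1L) stop("images have inconsistent channel counts")
  cfg <- config
  Hw <- cfg$input_size[1]; Ww <- cfg$input_size[2]
  prep <- function(set) lapply(set, function(s) {
    list(x = .seg_preprocess(s$image, cfg),
         y = as.integer(.resize_nearest(s$mask@labels, Hw, Ww)))
  })
  tr <- prep(train); va <- prep(val)
  freq <- tabulate(unlist(lapply(tr, `[[`, "y")) + 1L, cfg$n_classes)
  wcls <- pmin(sum(freq) / (cfg$n_classes * pmax(freq, 1)),
               cfg$class_weight_cap)

  .with_seed(cfg$seed, {
    params <- .seg_init(cfg)
    opt <- .adam_new(params)
    best <- list(score = -Inf, params = params)
    log <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_macro_jaccard = numeric())
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(seq_along(tr))
      tot <- 0
      for (i in ord) {
        fw <- .seg_forward(tr[[i]]$x, params)
        ce <- .softmax_ce(fw$logits, tr[[i]]$y, wcls[tr[[i]]$y + 1L])
        tot <- tot + ce$loss
        grads <- .seg_backward(fw, params, ce$dlogits, cfg)
        st <- .adam_step(params, grads, opt, cfg$learning_rate)
        params <- st$params; opt <- st$state
      }
      vj <- mean(vapply(va, function(s) {
        pred <- max.col(.seg_forward(s$x, params, keep_cache = FALSE)$logits) - 1L
        macroJaccard(matrix(pred, Hw, Ww), matrix(s$y, Hw, Ww))
      }, 0))
      log <- rbind(log, data.frame(epoch = ep, train_loss = tot / length(tr),
                                   val_macro_jaccard = vj))
      if (verbose)
        message(sprintf("epoch %d: loss %.4f, val macro-Jaccard %.4f",
                        ep, tot / length(tr), vj))
      if (vj > best$score) best <- list(score = vj, params = params)
    }
    new("SegModel", weights = best$params, config = cfg,
        interval = interval, training_log = log)
  })
}

#' Apply a trained segmenter to an image
#'
#' Downscales the image to the network's working size, predicts the
#' per-pixel argmax label map, and upscales it back to the native image
#' size by nearest neighbour, so that patches can be cut from the
#' original-resolution image.
#'
#' @param model a [SegModel-class].
#' @param image an [ImageRecord-class].
#' @return a [LabelMask-class] with origin `"predicted"`, native resolution.
#' @export
applySegmenter <- function(model, image) {
  if (!length(model@weights)) stop("untrained segmentation model")
  cfg <- model@config
  x <- .seg_preprocess(image, cfg)
  pred <- max.col(.seg_forward(x, model@weights, keep_cache = FALSE)$logits) - 1L
  work <- matrix(pred, cfg$input_size[1], cfg$input_size[2])
  d <- dim(image@pixels)
  LabelMask(.resize_nearest(work, d[1], d[2]), "native", "predicted")
}

#' Jaccard score of one class
#'
#' `|intersection| / |union|` of the pixel sets carrying `label` in the two
#' masks. If the class is absent from both masks the score is 1 (perfect
#' agreement); absent from exactly one, 0.
#'
#' @param pred,truth [LabelMask-class] objects or integer matrices of equal
#'   shape.
#' @param label class label (0, 1 or 2).
#' @return score in `[0, 1]`.
#' @export
jaccard <- function(pred, truth, label) {
  p <- if (is(pred, "LabelMask")) pred@labels else pred
  t <- if (is(truth, "LabelMask")) truth@labels else truth
  if (!identical(dim(p), dim(t))) stop("mask shapes differ")
  a <- p == label; b <- t == label
  uni <- sum(a | b)
  if (uni == 0L) return(1)
  sum(a & b) / uni
}

#' Macro-averaged Jaccard score
#'
#' Unweighted mean of the per-class Jaccard scores over `labels`.
#'
#' @param pred,truth masks as in [jaccard()].
#' @param labels class labels to average over (default all three).
#' @return score in `[0, 1]`.
#' @export
macroJaccard <- function(pred, truth, labels = 0:2) {
  mean(vapply(labels, function(l) jaccard(pred, truth, l), 0))
}

#' Dataset-pooled Jaccard scores
#'
#' Aggregates intersections and unions over a whole test set before the
#' division, the usual way semantic-segmentation models are scored on a
#' dataset (robust to images where a class is absent).
#'
#' @param preds,truths parallel lists of masks ([LabelMask-class] or
#'   integer matrices).
#' @param labels class labels to score.
#' @return list with `per_class` (named scores) and `macro` (their
#'   unweighted mean).
#' @export
datasetJaccard <- function(preds, truths, labels = 0:2) {
  stopifnot(length(preds) == length(truths))
  lab_mat <- function(m) if (is(m, "LabelMask")) m@labels else m
  per <- vapply(labels, function(l) {
    inter <- 0; uni <- 0
    for (i in seq_along(preds)) {
      a <- lab_mat(preds[[i]]) == l
      b <- lab_mat(truths[[i]]) == l
      inter <- inter + sum(a & b)
      uni <- uni + sum(a | b)
    }
    if (uni == 0) 1 else inter / uni
  }, 0)
  names(per) <- paste0("class_", labels)
  list(per_class = per, macro = mean(per))
}

#' Per-image region size of one class
#'
#' Counts the pixels carrying `label` in each mask, keyed by timestamp and
#' camera angle. Feeds the distant-colony visibility filter and the
#' biofouling growth diagnostics (under growing occlusion the counts
#' decrease over campaign time).
#'
#' @param records list of [ImageRecord-class].
#' @param masks parallel list of [LabelMask-class].
#' @param label class label to count.
#' @return data.frame with image_id, timestamp, angle, pixels.
#' @export
regionSizeSeries <- function(records, masks, label = 2L) {
  stopifnot(length(records) == length(masks))
  do.call(rbind, lapply(seq_along(records), function(i) data.frame(
    image_id = records[[i]]@image_id, timestamp = records[[i]]@timestamp,
    angle = records[[i]]@camera_angle,
    pixels = sum(masks[[i]]@labels == label))))
}
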