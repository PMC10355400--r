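# Patch-level activity classification: extended (1) vs. retracted (0)
# polyps. The full-scale method fine-tunes a deep residual network on
# 128 x 128 patches; the desk-scale default trains a compact 4-conv-block
# CNN from scratch on internally downscaled tiles, which is what synthetic
# textures need and what a single CPU can train in minutes.

#' Classifier configuration
#'
#' @param working_size side length the (square) patch is downscaled to
#'   before entering the network.
#' @param channels widths of the four conv blocks.
#' @param learning_rate Adam step size.
#' @param epochs training epochs; best-on-validation checkpoint kept.
#' @param init `"random"` (train all layers from scratch). `"pretrained"`
#'   mirrors the full-scale fine-tuning setup and requires an external
#'   ImageNet checkpoint; without one it raises an error.
#' @param threshold decision threshold on the positive-class score.
#' @param apply_gamma,gamma gamma-correction preprocessing toggle.
#' @param seed RNG seed.
#' @return config list.
#' @export
clfConfig <- function(working_size = 32L, channels = c(8L, 16L, 24L, 32L),
                      learning_rate = 1.5e-3, epochs = 40L, init = "random",
                      threshold = 0.5, apply_gamma = TRUE, gamma = 0.3,
                      seed = 1L) {
  if (working_size %% 16L != 0L)
    stop("working_size must be divisible by 16 (four pooling levels)")
  list(working_size = as.integer(working_size),
       channels = as.integer(channels), learning_rate = learning_rate,
       epochs = as.integer(epochs), init = init, threshold = threshold,
       apply_gamma = apply_gamma, gamma = gamma, seed = as.integer(seed))
}

.clf_init <- function(cfg) {
  ch <- cfg$channels
  list(W1 = .he_init(9 * 3, ch[1]), b1 = numeric(ch[1]),
       W2 = .he_init(9 * ch[1], ch[2]), b2 = numeric(ch[2]),
       W3 = .he_init(9 * ch[2], ch[3]), b3 = numeric(ch[3]),
       W4 = .he_init(9 * ch[3], ch[4]), b4 = numeric(ch[4]),
       W5 = .he_init(ch[4], 2L), b5 = numeric(2L))
}

.clf_forward <- function(x, p, keep_cache = TRUE) {
  f1 <- .conv_fwd(x, p$W1, p$b1, 3); r1 <- .relu_fwd(f1$out); p1 <- .pool_fwd(r1$out)
  f2 <- .conv_fwd(p1$out, p$W2, p$b2, 3); r2 <- .relu_fwd(f2$out); p2 <- .pool_fwd(r2$out)
  f3 <- .conv_fwd(p2$out, p$W3, p$b3, 3); r3 <- .relu_fwd(f3$out); p3 <- .pool_fwd(r3$out)
  f4 <- .conv_fwd(p3$out, p$W4, p$b4, 3); r4 <- .relu_fwd(f4$out); p4 <- .pool_fwd(r4$out)
  feat <- colMeans(.as_mat(p4$out))                     # global average pool
  logits <- as.numeric(feat %*% p$W5 + p$b5)
  if (!keep_cache) return(list(logits = logits))
  list(logits = logits, feat = feat, f1 = f1, r1 = r1, p1 = p1, f2 = f2,
       r2 = r2, p2 = p2, f3 = f3, r3 = r3, p3 = p3, f4 = f4, r4 = r4,
       p4 = p4)
}

.clf_backward <- function(cache, p, dlogits) {
  g <- list()
  g$W5 <- outer(cache$feat, dlogits); g$b5 <- dlogits
  dfeat <- as.numeric(p$W5 %*% dlogits)
  d4 <- dim(cache$p4$out)
  npix <- d4[1] * d4[2]
  dp4 <- .as_map(matrix(rep(dfeat / npix, each = npix), npix), d4[1], d4[2], d4[3])
  dr4 <- .pool_bwd(dp4, cache$p4) * cache$r4$mask
  bw4 <- .conv_bwd(dr4, cache$f4, p$W4, 3); g$W4 <- bw4$dW; g$b4 <- bw4$db
  dr3 <- .pool_bwd(bw4$dx, cache$p3) * cache$r3$mask
  bw3 <- .conv_bwd(dr3, cache$f3, p$W3, 3); g$W3 <- bw3$dW; g$b3 <- bw3$db
  dr2 <- .pool_bwd(bw3$dx, cache$p2) * cache$r2$mask
  bw2 <- .conv_bwd(dr2, cache$f2, p$W2, 3); g$W2 <- bw2$dW; g$b2 <- bw2$db
  dr1 <- .pool_bwd(bw2$dx, cache$p1) * cache$r1$mask
  bw1 <- .conv_bwd(dr1, cache$f1, p$W1, 3); g$W1 <- bw1$dW; g$b1 <- bw1$db
  g
}

.clf_preprocess <- function(tile, cfg) {
  if (cfg$apply_gamma) tile <- gammaCorrect(tile, cfg$gamma)
  .resize_bilinear(tile, cfg$working_size, cfg$working_size)
}

#' Train the patch activity classifier
#'
#' All layers are trainable; the checkpoint with the best validation
#' macro-F1 across epochs is returned. Training requires both classes in
#' the training set.
#'
#' @param train,val labeled [PatchSet-class] objects (true class `k` set).
#' @param config a [clfConfig()].
#' @param interval training interval tag (`"t1"`, `"t2"`, `"star"`).
#' @param coral the coral the model is trained for.
#' @param verbose print per-epoch validation scores.
#' @return a [ClfModel-class].
#' @export
trainClassifier <- function(train, val, config = clfConfig(),
                            interval = "t1", coral = "C_r",
                            verbose = FALSE) {
  cfg <- config
  if (cfg$init == "pretrained")
    stop("pretrained initialization needs an external ImageNet checkpoint; ",
         "use init = 'random' for the from-scratch configuration")
  ytr <- train@info$k
  if (any(is.na(ytr))) {
    keep <- !is.na(ytr)
    train <- patchSubset(train, keep); ytr <- train@info$k
  }
  if (length(unique(ytr)) < 2L)
    stop("training set must contain both classes")
  yva <- val@info$k
  if (any(is.na(yva))) { val <- patchSubset(val, !is.na(yva)); yva <- val@info$k }
  xtr <- lapply(train@pixels, .clf_preprocess, cfg = cfg)
  xva <- lapply(val@pixels, .clf_preprocess, cfg = cfg)
  # inverse-frequency sample weights so the rarer class is not drowned out
  cls_n <- table(factor(ytr, levels = 0:1))
  wts <- as.numeric(length(ytr) / (2 * pmax(cls_n, 1)))[ytr + 1L]

  .with_seed(cfg$seed, {
    params <- .clf_init(cfg)
    opt <- .adam_new(params)
    best <- list(score = -Inf, params = params)
    log <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_macro_f1 = numeric())
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(seq_along(xtr))
      tot <- 0
      for (i in ord) {
        fw <- .clf_forward(xtr[[i]], params)
        ce <- .softmax_ce(matrix(fw$logits, 1), ytr[i])
        tot <- tot + ce$loss
        grads <- .clf_backward(fw, params, wts[i] * as.numeric(ce$dlogits))
        st <- .adam_step(params, grads, opt, cfg$learning_rate)
        params <- st$params; opt <- st$state
      }
      pred <- vapply(xva, function(x) {
        lg <- .clf_forward(x, params, keep_cache = FALSE)$logits
        as.integer(.logistic(lg[2] - lg[1]) > cfg$threshold)
      }, 0L)
      vf <- classificationMetrics(yva, pred)$macro_f1
      log <- rbind(log, data.frame(epoch = ep, train_loss = tot / length(xtr),
                                   val_macro_f1 = vf))
      if (verbose)
        message(sprintf("epoch %d: loss %.4f, val macro-F1 %.4f",
                        ep, tot / length(xtr), vf))
      if (vf > best$score) best <- list(score = vf, params = params)
    }
    new("ClfModel", weights = best$params, config = cfg, interval = interval,
        coral = coral, init = cfg$init, training_log = log)
  })
}

#' Classify patches as extended or retracted
#'
#' Every input patch receives a binary predicted class. Patches with coral
#' portion below 0.1 are rejected with an error: the eligibility filter
#' must happen upstream, never silently here.
#'
#' @param model a [ClfModel-class].
#' @param patches a [PatchSet-class].
#' @param p_min eligibility threshold (0.1).
#' @return the [PatchSet-class] with `k_hat` filled in.
#' @export
classifyPatches <- function(model, patches, p_min = 0.1) {
  if (!length(model@weights)) stop("untrained classification model")
  if (!nrow(patches@info)) return(patches)
  if (any(patches@info$p < p_min))
    stop("patch(es) with coral portion p < ", p_min,
         " must be filtered out before classification")
  cfg <- model@config
  patches@info$k_hat <- vapply(patches@pixels, function(tile) {
    lg <- .clf_forward(.clf_preprocess(tile, cfg), model@weights,
                       keep_cache = FALSE)$logits
    as.integer(.logistic(lg[2] - lg[1]) > cfg$threshold)
  }, 0L)
  patches
}

#' Precision, recall and F1 per class with macro averages
#'
#' Per class: `P = TP / (TP + FP)`, `R = TP / (TP + FN)`,
#' `F1 = 2PR / (P + R)`; cells with an empty denominator yield 0 (declared
#' convention). Macro scores are unweighted means over the two classes.
#'
#' @param truth,pred equal-length binary label vectors.
#' @return list with `per_class` (data.frame class, P, R, F1),
#'   `macro_precision`, `macro_recall`, `macro_f1`.
#' @export
classificationMetrics <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("label vectors differ in length")
  per <- lapply(0:1, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    P <- if (tp + fp > 0) tp / (tp + fp) else 0
    R <- if (tp + fn > 0) tp / (tp + fn) else 0
    F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
    data.frame(class = cl, P = P, R = R, F1 = F1)
  })
  per <- do.call(rbind, per)
  list(per_class = per, macro_precision = mean(per$P),
       macro_recall = mean(per$R), macro_f1 = mean(per$F1))
}
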