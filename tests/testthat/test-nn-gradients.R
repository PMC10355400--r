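# Finite-difference checks of the hand-derived gradients behind the
# segmentation/classification networks and the recurrent forecaster.

num_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

test_that("convolution backward matches finite differences", {
  set.seed(1)
  H <- 5L; W <- 6L; Cin <- 2L; Cout <- 3L; k <- 3L
  x <- array(rnorm(H * W * Cin), c(H, W, Cin))
  Wm <- matrix(rnorm(k * k * Cin * Cout), k * k * Cin, Cout)
  b <- rnorm(Cout)
  tgt <- array(rnorm(H * W * Cout), c(H, W, Cout))
  loss_of <- function(Wm, b, x) {
    out <- polypact:::.conv_fwd(x, Wm, b, k)$out
    sum((out - tgt)^2)
  }
  fw <- polypact:::.conv_fwd(x, Wm, b, k)
  dout <- 2 * (fw$out - tgt)
  bw <- polypact:::.conv_bwd(dout, fw, Wm, k)
  expect_equal(bw$dW, num_grad(function(w) loss_of(matrix(w, nrow(Wm)), b, x),
                               as.numeric(Wm)) |> matrix(nrow(Wm)),
               tolerance = 1e-5)
  expect_equal(bw$db, num_grad(function(bb) loss_of(Wm, bb, x), b),
               tolerance = 1e-5)
  expect_equal(as.numeric(bw$dx),
               num_grad(function(xx) loss_of(Wm, b, array(xx, dim(x))),
                        as.numeric(x)),
               tolerance = 1e-5)
})

test_that("max-pool and upsampling adjoints match finite differences", {
  set.seed(2)
  x <- array(rnorm(4 * 6 * 2), c(4, 6, 2))
  tgt <- array(rnorm(2 * 3 * 2), c(2, 3, 2))
  loss_pool <- function(xx) {
    p <- polypact:::.pool_fwd(array(xx, dim(x)))
    sum((p$out - tgt)^2)
  }
  p <- polypact:::.pool_fwd(x)
  dx <- polypact:::.pool_bwd(2 * (p$out - tgt), p)
  expect_equal(as.numeric(dx), num_grad(loss_pool, as.numeric(x)),
               tolerance = 1e-5)

  u <- array(rnorm(2 * 3 * 2), c(2, 3, 2))
  tgt2 <- array(rnorm(4 * 6 * 2), c(4, 6, 2))
  loss_up <- function(uu) sum((polypact:::.up_fwd(array(uu, dim(u))) - tgt2)^2)
  du <- polypact:::.up_bwd(2 * (polypact:::.up_fwd(u) - tgt2), dim(u))
  expect_equal(as.numeric(du), num_grad(loss_up, as.numeric(u)),
               tolerance = 1e-5)
})

test_that("LSTM backward matches finite differences on all parameters", {
  set.seed(3)
  B <- 4L; eta <- 5L; n_in <- 3L; H <- 4L
  X <- array(rnorm(B * eta * n_in), c(B, eta, n_in))
  y <- runif(B)
  p <- polypact:::.lstm_init(n_in, H)
  loss_of <- function(p) {
    fw <- polypact:::.lstm_forward(X, p, H, keep_cache = FALSE)
    sum((fw$yhat - y)^2)
  }
  fw <- polypact:::.lstm_forward(X, p, H)
  g <- polypact:::.lstm_backward(fw, p, 2 * (fw$yhat - y), H)
  for (nm in names(p)) {
    gn <- num_grad(function(v) {
      pp <- p; pp[[nm]] <- if (is.matrix(p[[nm]])) matrix(v, nrow(p[[nm]]))
      else v
      loss_of(pp)
    }, as.numeric(p[[nm]]))
    expect_equal(as.numeric(g[[nm]]), gn, tolerance = 1e-4,
                 ignore_attr = TRUE)
  }
})

test_that("softmax cross-entropy gradient matches finite differences", {
  set.seed(4)
  logits <- matrix(rnorm(12), 4, 3)
  target <- c(0L, 2L, 1L, 0L)
  w <- runif(4, 0.5, 2)
  f <- function(l) polypact:::.softmax_ce(matrix(l, 4), target, w)$loss
  ce <- polypact:::.softmax_ce(logits, target, w)
  expect_equal(as.numeric(ce$dlogits), num_grad(f, as.numeric(logits)),
               tolerance = 1e-6)
})
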