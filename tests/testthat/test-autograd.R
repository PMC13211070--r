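# The autodiff engine is the foundation under every network module; each op
# is checked against central finite differences on small random instances.

test_that("elementwise, matmul and reduction gradients match finite differences", {
  set.seed(42)
  X <- matrix(rnorm(24), 6, 4)
  W <- matrix(rnorm(12), 4, 3)
  s <- matrix(rnorm(4), 1)
  b <- matrix(rnorm(4), 1)
  ag <- asNamespace("slecg")

  cases <- list(
    matmul_relu = function(p) ag$ag_mean_all(ag$ag_relu(ag$ag_matmul(p, W))),
    softmax_log = function(p) ag$ag_mean_all(ag$ag_log(ag$ag_softmax_rows(p))),
    sigmoid_abs = function(p) ag$ag_sum_all(ag$ag_mul(ag$ag_sigmoid(p), ag$ag_abs(p))),
    colscale = function(p) ag$ag_sum_all(ag$ag_colscale(p, s)),
    addbias = function(p) ag$ag_mean_all(ag$ag_sigmoid(ag$ag_addbias(p, b))),
    pools = function(p) ag$ag_sum_all(ag$ag_cbind(list(ag$ag_colmeans(p),
                                                       ag$ag_colmax(p)))),
    maxpool2 = function(p) ag$ag_sum_all(ag$ag_mul(ag$ag_maxpool2(p),
                                                   ag$ag_maxpool2(p))),
    slice = function(p) ag$ag_sum_all(ag$ag_mul(ag$ag_cols(p, 2:3),
                                                ag$ag_cols(p, c(1, 4)))),
    pow = function(p) ag$ag_sum_all(ag$ag_pow(ag$ag_sigmoid(p), -0.5)),
    transpose = function(p) ag$ag_mean_all(ag$ag_abs(ag$ag_scale(
      ag$ag_sub(ag$ag_transpose(p), t(X) * 0.5), 2)))
  )
  for (nm in names(cases)) {
    expect_lt(grad_err(cases[[nm]], X + 0.3), 1e-5, label = nm)
  }
})

test_that("convolution gradients (input and weights) match finite differences", {
  set.seed(7)
  ag <- asNamespace("slecg")
  X <- matrix(rnorm(24), 6, 4)
  Wc <- matrix(rnorm(5 * 4 * 2), 20)
  bc <- matrix(rnorm(2), 1)
  wd <- matrix(rnorm(12), 3)
  bd <- matrix(rnorm(4), 1)
  expect_lt(grad_err(function(p)
    ag$ag_mean_all(ag$ag_relu(ag$ag_conv1d(p, Wc, bc, 5L))), X), 1e-5)
  expect_lt(grad_err(function(p)
    ag$ag_mean_all(ag$ag_relu(ag$ag_conv1d(X, p, bc, 5L))), Wc), 1e-5)
  expect_lt(grad_err(function(p)
    ag$ag_sum_all(ag$ag_relu(ag$ag_dwconv3s2(p, wd, bd))), X), 1e-5)
  expect_lt(grad_err(function(p)
    ag$ag_sum_all(ag$ag_relu(ag$ag_dwconv3s2(X, p, bd))), wd), 1e-5)
})

test_that("normalization gradients match finite differences", {
  set.seed(11)
  ag <- asNamespace("slecg")
  X <- matrix(rnorm(24), 6, 4)
  gm <- matrix(runif(4) + 0.5, 1)
  bt <- matrix(rnorm(4), 1)
  mkbn <- function() {
    e <- new.env()
    e$running_mean <- rep(0, 4); e$running_var <- rep(1, 4)
    e$momentum <- 0.1; e$bn <- TRUE
    e
  }
  expect_lt(grad_err(function(p)
    ag$ag_sum_all(ag$ag_abs(ag$ag_layernorm(p, gm, bt))), X), 1e-5)
  expect_lt(grad_err(function(p)
    ag$ag_sum_all(ag$ag_abs(ag$ag_layernorm(X, p, bt))), gm), 1e-5)
  expect_lt(grad_err(function(p)
    ag$ag_sum_all(ag$ag_abs(ag$ag_batchnorm(p, gm, bt, mkbn(), TRUE))), X), 1e-5)
  expect_lt(grad_err(function(p)
    ag$ag_sum_all(ag$ag_abs(ag$ag_batchnorm(X, p, bt, mkbn(), TRUE))), gm), 1e-5)
  expect_lt(grad_err(function(p)
    ag$ag_sum_all(ag$ag_abs(ag$ag_batchnorm(p, gm, bt, mkbn(), FALSE,
                                            use_running = TRUE))), X), 1e-5)
})

test_that("fused dense and squeeze-and-excitation gradients match finite differences", {
  set.seed(13)
  ag <- asNamespace("slecg")
  X <- matrix(rnorm(24), 6, 4)
  W <- matrix(rnorm(12), 4, 3)
  b <- matrix(rnorm(3), 1)
  expect_lt(grad_err(function(p)
    ag$ag_mean_all(ag$ag_sigmoid(ag$ag_dense(p, W, b))), X), 1e-5)
  expect_lt(grad_err(function(p)
    ag$ag_mean_all(ag$ag_sigmoid(ag$ag_dense(X, p, b))), W), 1e-5)
  expect_lt(grad_err(function(p)
    ag$ag_mean_all(ag$ag_sigmoid(ag$ag_dense(X, W, p))), b), 1e-5)

  w1 <- matrix(rnorm(8), 4, 2); b1 <- matrix(rnorm(2), 1)
  w2 <- matrix(rnorm(8), 2, 4); b2 <- matrix(rnorm(4), 1)
  se_loss <- function(x, a1 = w1, a2 = b1, a3 = w2, a4 = b2)
    ag$ag_sum_all(ag$ag_abs(ag$ag_se(x, a1, a2, a3, a4)))
  expect_lt(grad_err(function(p) se_loss(p), X), 1e-5)
  expect_lt(grad_err(function(p) se_loss(X, a1 = p), w1), 1e-5)
  expect_lt(grad_err(function(p) se_loss(X, a2 = p), b1), 1e-5)
  expect_lt(grad_err(function(p) se_loss(X, a3 = p), w2), 1e-5)
  expect_lt(grad_err(function(p) se_loss(X, a4 = p), b2), 1e-5)
})

test_that("a composite network gradient matches finite differences end to end", {
  set.seed(5)
  ag <- asNamespace("slecg")
  X <- matrix(rnorm(16), 4, 4)
  W1 <- matrix(rnorm(16), 4, 4)
  W2 <- matrix(rnorm(8), 4, 2)
  loss <- function(p) {
    h <- ag$ag_relu(ag$ag_matmul(p, W1))
    a <- ag$ag_softmax_rows(ag$ag_matmul(h, ag$ag_transpose(h)))
    z <- ag$ag_matmul(ag$ag_matmul(a, h), W2)
    ag$ag_mean_all(ag$ag_abs(z))
  }
  expect_lt(grad_err(loss, X), 1e-5)
})

test_that("Adam descends on a quadratic and no_grad records nothing", {
  ag <- asNamespace("slecg")
  target <- matrix(c(1, -2, 3, 0.5), 2)
  p <- ag$ag_param(matrix(0, 2, 2))
  opt <- new.env(); opt$t <- 0L
  for (i in 1:300) {
    ag$ag_reset()
    d <- ag$ag_sub(p, target)
    l <- ag$ag_mean_all(ag$ag_mul(d, d))
    ag$ag_backward(l)
    ag$adam_step(list(p), 0.05, opt)
    ag$zero_grads(list(p))
  }
  expect_lt(max(abs(p$value - target)), 1e-2)

  ag$ag_reset()
  res <- ag$ag_no_grad(ag$ag_relu(ag$ag_matmul(ag$as_node(target), target)))
  expect_identical(ag$.ag$n, 0L)
  expect_true(is.matrix(res$value))
})
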