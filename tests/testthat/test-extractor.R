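# Extractor stages: SE gating against hand evaluation, stage shape
# contracts, transformer properties, and end-to-end shape/NaN/gradient-flow
# invariants of the full extractor.

test_that("SE recalibration matches a hand-computed two-layer gate", {
  se <- list(fc1 = list(w = slecg:::ag_param(matrix(c(0.5, -0.2, 0.3, 0.1), 2)),
                        b = slecg:::ag_param(matrix(c(0.1, -0.1), 1))),
             fc2 = list(w = slecg:::ag_param(matrix(c(0.7, 0.2, -0.4, 0.6), 2)),
                        b = slecg:::ag_param(matrix(c(0.05, -0.05), 1))))
  x <- matrix(c(1, 3, 2, 4), 2)  # 2 time steps x 2 channels
  z <- colMeans(x)
  h <- pmax(z %*% se$fc1$w$value + as.vector(se$fc1$b$value), 0)
  g <- 1 / (1 + exp(-(h %*% se$fc2$w$value + as.vector(se$fc2$b$value))))
  expected <- x * rep(as.vector(g), each = 2)
  got <- se_recalibrate(x, se)
  expect_equal(got, expected, tolerance = 1e-12, ignore_attr = TRUE)

  ratio <- got / x
  expect_lt(max(abs(ratio[1, ] - ratio[2, ])), 1e-12)  # constant along time
  expect_true(all(ratio > 0 & ratio < 1))              # sigmoid gate
  expect_identical(se_recalibrate(matrix(0, 2, 2), se), matrix(0, 2, 2))
  expect_error(se_recalibrate(matrix(0, 2, 3), se), "channels")
})

test_that("OS-CNN stage halves time and emits the configured channel count", {
  set.seed(1)
  spec <- tiny_spec(1L)
  m <- extractor_init(spec)
  x <- matrix(rnorm(640), 1)
  out <- oscnn_forward(x, m)
  expect_equal(dim(out), c(320L, 6L))

  spec12 <- tiny_spec(12L)
  m12 <- extractor_init(spec12)
  out12 <- oscnn_forward(matrix(rnorm(12 * 640), 12), m12)
  expect_equal(dim(out12), c(320L, 6L))  # lead count absorbed at the first conv
  expect_error(oscnn_forward(matrix(rnorm(641), 1), m), "even")
})

test_that("zero input gives zero pre-pool OS-CNN activations when biases are zero", {
  set.seed(2)
  m <- extractor_init(tiny_spec(1L))
  x0 <- slecg:::as_node(matrix(0, 640, 1))
  branches <- lapply(m$oscnn$branches, function(br)
    if (br$k == 1L) slecg:::dense(x0, br) else slecg:::ag_conv1d(x0, br$w, br$b, br$k))
  pre <- slecg:::ag_value(slecg:::ag_cbind(branches))
  expect_true(all(pre == 0))
})

test_that("CNN blocks halve time and follow the channel schedule; five blocks give x1/64", {
  set.seed(3)
  m <- extractor_init(tiny_spec(1L))
  f0 <- oscnn_forward(matrix(rnorm(640), 1), m)  # 320 x 6
  f1 <- cnn_block_forward(f0, m, 1L)
  expect_equal(dim(f1), c(160L, 8L))
  f <- f0
  for (b in 1:5) f <- cnn_block_forward(f, m, b)
  expect_equal(dim(f), c(10L, 16L))              # 640 / 64 tokens, d_model
  expect_error(cnn_block_forward(matrix(0, 4, 5), m, 1L), "channels")
})

test_that("evaluation-mode forward is deterministic across repeated calls", {
  set.seed(4)
  m <- extractor_init(tiny_spec(1L))
  x <- matrix(rnorm(320), 1)
  expect_identical(extract(x, m), extract(x, m))
})

test_that("transformer stage preserves shape, normalizes attention and is equivariant without positions", {
  set.seed(5)
  spec <- tiny_spec(1L)
  m <- extractor_init(spec)
  f <- matrix(rnorm(10 * 16), 10)
  out <- transformer_encode(f, m)
  expect_equal(dim(out), dim(f))

  # attention rows are probability distributions
  ag <- asNamespace("slecg")
  res <- ag$ag_no_grad(ag$mha(ag$as_node(f), ag$as_node(f), m$layers[[1]]$attn))
  for (a in res$attn) expect_lt(max(abs(rowSums(a) - 1)), 1e-6)

  # permuting tokens without positional encoding permutes the output; with
  # positional encoding it does not
  perm <- sample(10L)
  no_pe <- transformer_encode(f, m, positional = FALSE)
  no_pe_perm <- transformer_encode(f[perm, ], m, positional = FALSE)
  expect_equal(no_pe_perm, no_pe[perm, ], tolerance = 1e-10)
  with_pe <- transformer_encode(f, m, positional = TRUE)
  with_pe_perm <- transformer_encode(f[perm, ], m, positional = TRUE)
  expect_gt(max(abs(with_pe_perm - with_pe[perm, ])), 1e-4)
})

test_that("extract honours the (N/64, d_model) shape contract over random lengths", {
  set.seed(6)
  m <- extractor_init(tiny_spec(1L))
  for (n in c(128L, 320L, 64L * sample(2:8, 2L))) {
    f <- extract(matrix(rnorm(n), 1), m)
    expect_equal(dim(f), c(n %/% 64L, 16L))
  }
  expect_error(extract(matrix(rnorm(100), 1), m), "divisible by 64")
  expect_error(extract(matrix(rnorm(128), 2), m), "lead")
})

test_that("random initializations produce finite features", {
  x <- matrix(rnorm(128), 1)
  for (i in 1:100) {
    set.seed(i)
    m <- extractor_init(tiny_spec(1L))
    expect_true(all(is.finite(extract(x, m))), label = paste("init", i))
  }
})

test_that("every trainable parameter receives gradient from a scalar loss", {
  set.seed(7)
  ag <- asNamespace("slecg")
  m <- extractor_init(tiny_spec(1L))
  ag$ag_reset()
  f <- ag$fwd_extract(ag$as_node(matrix(rnorm(128), 128, 1)), m, training = TRUE)
  loss <- ag$ag_mean_all(ag$ag_mul(f, f))
  ag$ag_backward(loss)
  params <- ag$collect_params(m)
  dead <- vapply(params, function(p)
    is.null(p$grad) || all(p$grad == 0), TRUE)
  expect_false(any(dead))
})

test_that("spec validation enforces the architectural invariants", {
  expect_error(extractor_spec(in_leads = 2L), "1, 3 or 12")
  expect_error(extractor_spec(oscnn_kernels = c(1L, 4L)), "odd")
  expect_error(extractor_spec(oscnn_out_channels = 100L), "divisible")
  expect_error(extractor_spec(d_model = 512L), "last block_channels")
  expect_error(extractor_spec(block_channels = c(256L, 512L, 1536L),
                              d_model = 1536L), "stride")
  sp <- extractor_spec(small_profile = TRUE)
  expect_equal(sp$d_model, utils::tail(sp$block_channels, 1L))
})
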