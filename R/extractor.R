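# Multi-scale CNN-transformer feature extractor. The same architecture serves
# the 12-lead teacher and the single-lead student; only the number of input
# channels differs. Stages and their time/channel contract:
#
#   input          (N, leads)
#   OS-CNN         -> (N/2,  oscnn_out_channels)   parallel kernels + SE + pool
#   5 CNN blocks   -> (N/64, d_model)              each halves time
#   transformer    -> (N/64, d_model)              4 pre-norm encoder layers
#
# so the total time downsampling factor is 2 * 2^5 = 64.

#' Feature-extractor architecture specification
#'
#' Describes the multi-scale CNN-transformer extractor: parallel ("omni-scale")
#' 1-D convolutions with squeeze-and-excitation gating, a stack of inverted
#' bottleneck CNN blocks (1x1 expansion, stride-2 depthwise 3-tap, 1x1
#' compression, each followed by batch norm / ReLU / SE), and a pre-norm
#' transformer encoder. The default widths realize the full-size tensor
#' contract (192 channels after the OS-CNN stage at half time resolution,
#' 1536 channels at 1/64 resolution after the CNN blocks, preserved by the
#' transformer); `small_profile = TRUE` scales all widths down for desk-size
#' experiments while keeping the stride arithmetic (and so the shape
#' contract) identical.
#'
#' @param in_leads Number of input leads (1, 3 or 12).
#' @param oscnn_kernels Odd kernel sizes of the parallel convolution branches.
#' @param oscnn_out_channels Total channels after branch concatenation; must
#'   be divisible by the number of branches.
#' @param block_channels Output channels of each CNN block; the last entry
#'   must equal `d_model`. The number of blocks is `length(block_channels)`
#'   and must keep the total stride at 64 (i.e. 5 blocks).
#' @param block_expansion Channel expansion factor inside each block.
#' @param d_model Transformer width (= feature-map channels).
#' @param n_transformer_layers,n_heads Transformer depth and head count.
#' @param se_reduction Squeeze-and-excitation bottleneck reduction.
#' @param ffn_mult Transformer feed-forward width multiplier.
#' @param dropout Dropout rate applied inside transformer layers in training.
#' @param small_profile If `TRUE`, overrides the width arguments with a
#'   desk-size profile (48-channel OS-CNN stage, blocks 32-48-64-128-192,
#'   d_model 192, 2 heads).
#' @return An object of class `extractor_spec`.
#' @examples
#' spec <- extractor_spec(in_leads = 1, small_profile = TRUE)
#' spec$d_model
#' @export
extractor_spec <- function(in_leads = 1L,
                           oscnn_kernels = c(1L, 3L, 5L, 7L, 11L, 13L),
                           oscnn_out_channels = 192L,
                           block_channels = c(256L, 384L, 512L, 1024L, 1536L),
                           block_expansion = 4L,
                           d_model = 1536L,
                           n_transformer_layers = 4L,
                           n_heads = 8L,
                           se_reduction = 16L,
                           ffn_mult = 4L,
                           dropout = 0.1,
                           small_profile = FALSE) {
  if (small_profile) {
    oscnn_out_channels <- 48L
    block_channels <- c(32L, 48L, 64L, 128L, 192L)
    d_model <- 192L
    n_heads <- 2L
    se_reduction <- 8L
  }
  if (!in_leads %in% c(1L, 3L, 12L)) {
    stop("in_leads must be 1, 3 or 12, got ", in_leads)
  }
  if (any(oscnn_kernels %% 2L == 0L)) stop("oscnn_kernels must all be odd")
  if (oscnn_out_channels %% length(oscnn_kernels) != 0L) {
    stop("oscnn_out_channels (", oscnn_out_channels,
         ") must be divisible by the number of kernel branches (",
         length(oscnn_kernels), ")")
  }
  if (utils::tail(block_channels, 1L) != d_model) {
    stop("d_model (", d_model, ") must equal the last block_channels entry (",
         utils::tail(block_channels, 1L), ")")
  }
  stride <- 2L * 2L^length(block_channels)
  if (stride != 64L) {
    stop("total stride must be 64 (OS-CNN pool x one stride-2 per block); ",
         length(block_channels), " blocks give ", stride)
  }
  if (d_model %% n_heads != 0L) stop("d_model must be divisible by n_heads")
  structure(list(in_leads = as.integer(in_leads),
                 oscnn_kernels = as.integer(oscnn_kernels),
                 oscnn_out_channels = as.integer(oscnn_out_channels),
                 block_channels = as.integer(block_channels),
                 block_expansion = as.integer(block_expansion),
                 d_model = as.integer(d_model),
                 n_transformer_layers = as.integer(n_transformer_layers),
                 n_heads = as.integer(n_heads),
                 se_reduction = as.integer(se_reduction),
                 ffn_mult = as.integer(ffn_mult),
                 dropout = dropout,
                 small_profile = small_profile),
            class = "extractor_spec")
}

#' @export
print.extractor_spec <- function(x, ...) {
  cat("Feature extractor spec:", x$in_leads, "lead(s) ->",
      "OS-CNN", x$oscnn_out_channels, "ch ->",
      paste(x$block_channels, collapse = "-"), "->",
      x$n_transformer_layers, "transformer layer(s), d_model", x$d_model, "\n")
  invisible(x)
}

new_bn_state <- function(channels) {
  e <- new.env(parent = emptyenv())
  e$running_mean <- rep(0, channels)
  e$running_var <- rep(1, channels)
  e$momentum <- 0.1
  e$bn <- TRUE
  e
}

init_bn <- function(channels) {
  list(g = ag_param(matrix(1, 1L, channels)), b = ag_param(zeros(1L, channels)),
       state = new_bn_state(channels))
}

#' Initialize extractor weights
#'
#' Draws all trainable parameters from the current RNG stream (seed before
#' calling for reproducibility) and allocates batch-norm running statistics.
#'
#' @param spec An [extractor_spec()].
#' @return A parameter tree of class `extractor_model` carrying `spec`.
#' @export
extractor_init <- function(spec) {
  stopifnot(inherits(spec, "extractor_spec"))
  nb <- length(spec$oscnn_kernels)
  branch_ch <- spec$oscnn_out_channels %/% nb
  oscnn <- list(
    branches = lapply(spec$oscnn_kernels, function(k)
      list(w = ag_param(he_init(k * spec$in_leads, branch_ch, fan_in = k * spec$in_leads)),
           b = ag_param(zeros(1L, branch_ch)), k = k)),
    se = init_se(spec$oscnn_out_channels, spec$se_reduction))
  c_in <- spec$oscnn_out_channels
  blocks <- vector("list", length(spec$block_channels))
  for (i in seq_along(spec$block_channels)) {
    c_out <- spec$block_channels[i]
    e <- c_in * spec$block_expansion
    blocks[[i]] <- list(
      expand = init_dense(c_in, e, he_init),
      bn1 = init_bn(e), se1 = init_se(e, spec$se_reduction),
      dw_w = ag_param(he_init(3L, e, fan_in = 3L)),
      dw_b = ag_param(zeros(1L, e)),
      bn2 = init_bn(e), se2 = init_se(e, spec$se_reduction),
      compress = init_dense(e, c_out, he_init),
      bn3 = init_bn(c_out), se3 = init_se(c_out, spec$se_reduction))
    c_in <- c_out
  }
  layers <- lapply(seq_len(spec$n_transformer_layers), function(i)
    init_transformer_layer(spec$d_model, spec$n_heads, spec$ffn_mult))
  structure(list(oscnn = oscnn, blocks = blocks, layers = layers,
                 final_ln = init_layernorm(spec$d_model), spec = spec),
            class = "extractor_model")
}

# ---- node-level forwards (used in training) ----

fwd_oscnn <- function(x, model, training = FALSE) {
  branches <- lapply(model$oscnn$branches, function(br) {
    if (br$k == 1L) dense(x, br) else ag_conv1d(x, br$w, br$b, br$k)
  })
  y <- se_recalibrate(ag_cbind(branches), model$oscnn$se)
  ag_maxpool2(y)
}

fwd_cnn_block <- function(x, blk, training = FALSE) {
  y <- se_recalibrate(ag_relu(ag_batchnorm(dense(x, blk$expand),
                                           blk$bn1$g, blk$bn1$b, blk$bn1$state, training)),
                      blk$se1)
  y <- ag_dwconv3s2(y, blk$dw_w, blk$dw_b)
  y <- se_recalibrate(ag_relu(ag_batchnorm(y, blk$bn2$g, blk$bn2$b, blk$bn2$state, training)),
                      blk$se2)
  y <- dense(y, blk$compress)
  se_recalibrate(ag_relu(ag_batchnorm(y, blk$bn3$g, blk$bn3$b, blk$bn3$state, training)),
                 blk$se3)
}

fwd_transformer <- function(x, model, training = FALSE) {
  spec <- model$spec
  x <- ag_add_const(x, positional_encoding(nrow(x$value), spec$d_model))
  for (p in model$layers) {
    x <- transformer_layer(x, p, training = training,
                           dropout = if (training) spec$dropout else 0)
  }
  ag_layernorm(x, model$final_ln$g, model$final_ln$b)
}

fwd_extract <- function(x, model, training = FALSE) {
  y <- fwd_oscnn(x, model, training)
  for (blk in model$blocks) y <- fwd_cnn_block(y, blk, training)
  fwd_transformer(y, model, training)
}

# ---- exported matrix-level operations ----

check_signal <- function(signal, model) {
  if (!is.matrix(signal)) stop("signal must be a leads x samples matrix")
  if (nrow(signal) != model$spec$in_leads) {
    stop("signal has ", nrow(signal), " lead(s) but the extractor expects ",
         model$spec$in_leads)
  }
}

#' Omni-scale convolution stage
#'
#' Applies the parallel same-padded 1-D convolutions (one branch per kernel
#' size), concatenates branches channel-wise, recalibrates with a
#' squeeze-and-excitation gate, and halves time with a stride-2 max pool.
#'
#' @param signal A `leads x N` numeric matrix, `N` even.
#' @param model An [extractor_init()] parameter tree.
#' @return An `N/2 x oscnn_out_channels` feature matrix.
#' @export
oscnn_forward <- function(signal, model) {
  check_signal(signal, model)
  if (ncol(signal) %% 2L != 0L) stop("signal length must be even, got ", ncol(signal))
  ag_no_grad(fwd_oscnn(as_node(t(signal)), model))$value
}

#' One CNN block (inverted bottleneck, stride 2)
#'
#' 1x1 expansion, stride-2 depthwise 3-tap convolution, 1x1 compression;
#' each convolution is followed by batch norm, ReLU and an SE gate. Time
#' halves, channels move to the block's configured output width.
#'
#' @param feature_map A `T x C` feature matrix (`T` at least 2 and even).
#' @param model An [extractor_init()] parameter tree.
#' @param block Index of the block to apply.
#' @return A `T/2 x C_out` feature matrix.
#' @export
cnn_block_forward <- function(feature_map, model, block = 1L) {
  if (nrow(feature_map) < 2L) stop("feature map time length must be at least 2")
  blk <- model$blocks[[block]]
  if (ncol(feature_map) != nrow(blk$expand$w$value)) {
    stop("feature map has ", ncol(feature_map), " channels; block ", block,
         " expects ", nrow(blk$expand$w$value))
  }
  ag_no_grad(fwd_cnn_block(as_node(feature_map), blk, training = FALSE))$value
}

#' Transformer encoding stage
#'
#' Adds fixed sinusoidal positional encoding and applies the pre-norm
#' transformer encoder layers (multi-head self-attention + feed-forward,
#' residual connections, final layer norm). Shape is preserved.
#'
#' @param feature_map A `tokens x d_model` feature matrix.
#' @param model An [extractor_init()] parameter tree.
#' @param positional Add positional encoding? (Disable to observe pure
#'   token-permutation equivariance of the attention stack.)
#' @return A `tokens x d_model` feature matrix.
#' @export
transformer_encode <- function(feature_map, model, positional = TRUE) {
  spec <- model$spec
  if (ncol(feature_map) != spec$d_model) {
    stop("feature map has ", ncol(feature_map), " channels; d_model is ", spec$d_model)
  }
  ag_no_grad({
    x <- as_node(feature_map)
    if (positional) x <- ag_add_const(x, positional_encoding(nrow(feature_map), spec$d_model))
    for (p in model$layers) x <- transformer_layer(x, p, training = FALSE, dropout = 0)
    ag_layernorm(x, model$final_ln$g, model$final_ln$b)
  })$value
}

#' Extract a feature map from a preprocessed signal
#'
#' Full extractor forward: OS-CNN stage, CNN blocks, transformer. An input of
#' `N` samples (divisible by 64) yields an `N/64 x d_model` feature map.
#'
#' @param signal A `leads x N` numeric matrix; `N` must be divisible by 64
#'   (use [fix_length()] to pad).
#' @param model An [extractor_init()] parameter tree.
#' @return An `N/64 x d_model` feature matrix.
#' @export
extract <- function(signal, model) {
  check_signal(signal, model)
  if (ncol(signal) %% 64L != 0L) {
    stop("signal length ", ncol(signal),
         " is not divisible by 64; run fix_length() first")
  }
  ag_no_grad(fwd_extract(as_node(t(signal)), model, training = FALSE))$value
}

# snapshot/restore including batch-norm running statistics
collect_bn_states <- function(x) {
  if (is.environment(x)) {
    if (isTRUE(x$bn)) return(list(x))
    return(list())
  }
  if (is.list(x)) return(do.call(c, lapply(x, collect_bn_states)))
  list()
}

model_snapshot <- function(model) {
  list(params = params_snapshot(collect_params(model)),
       bn = lapply(collect_bn_states(model), function(s)
         list(m = s$running_mean, v = s$running_var)))
}

model_restore <- function(model, snap) {
  params_restore(collect_params(model), snap$params)
  states <- collect_bn_states(model)
  stopifnot(length(states) == length(snap$bn))
  for (i in seq_along(states)) {
    states[[i]]$running_mean <- snap$bn[[i]]$m
    states[[i]]$running_var <- snap$bn[[i]]$v
  }
  invisible(NULL)
}
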