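# Cross-attention fusion of reconstructed and original single-lead features,
# followed by one self-attention refinement layer, and the pooled softmax
# classifier shared (in form) by student and teacher.

#' Fusion-module specification
#'
#' @param d_model Feature width; must match the extractor.
#' @param n_heads Attention heads; per-head key dimension is
#'   `d_model / n_heads`.
#' @param ffn_mult Feed-forward multiplier of the self-attention layer.
#' @param dropout Training-time dropout rate.
#' @return An object of class `fusion_spec`.
#' @export
fusion_spec <- function(d_model, n_heads = 2L, ffn_mult = 4L, dropout = 0.1) {
  if (d_model %% n_heads != 0L) stop("d_model must be divisible by n_heads")
  structure(list(d_model = as.integer(d_model), n_heads = as.integer(n_heads),
                 d_k = as.integer(d_model %/% n_heads),
                 ffn_mult = as.integer(ffn_mult), dropout = dropout),
            class = "fusion_spec")
}

#' Initialize fusion-module weights
#' @param spec A [fusion_spec()].
#' @return A parameter tree of class `fusion_model`.
#' @export
fusion_init <- function(spec) {
  stopifnot(inherits(spec, "fusion_spec"))
  structure(list(cross = init_mha(spec$d_model, spec$n_heads),
                 ln_cross = init_layernorm(spec$d_model),
                 self_layer = init_transformer_layer(spec$d_model, spec$n_heads,
                                                     spec$ffn_mult),
                 spec = spec), class = "fusion_model")
}

check_fusion_shapes <- function(f_rec, f_full) {
  if (!all(dim(ag_value(f_rec)) == dim(ag_value(f_full)))) {
    stop("shape mismatch: the two feature maps must share (tokens, d_model)")
  }
}

# node-level cross-attention: Q from f_rec, K/V from f_single, multi-head
# with output projection, residual from f_rec, layer norm
fwd_cross_attention <- function(f_rec, f_single, model, return_attn = FALSE) {
  a <- mha(f_rec, f_single, model$cross)
  out <- ag_layernorm(ag_add(f_rec, a$out), model$ln_cross$g, model$ln_cross$b)
  if (return_attn) list(out = out, attn = a$attn) else out
}

fwd_fuse <- function(f_rec, f_single, model, training = FALSE) {
  y <- fwd_cross_attention(f_rec, f_single, model)
  transformer_layer(y, model$self_layer, training = training,
                    dropout = if (training) model$spec$dropout else 0)
}

#' Cross-attention between reconstructed and single-lead features
#'
#' The reconstructed map provides the queries; the original single-lead map
#' provides keys and values. Attention is `softmax(Q K' / sqrt(d_k)) V`
#' per head, followed by the output projection, a residual connection from
#' the query map, and layer normalization.
#'
#' @param f_rec,f_single Equal-shaped `tokens x d_model` matrices.
#' @param model A [fusion_init()] parameter tree.
#' @param return_attn If `TRUE`, also return the per-head attention weight
#'   matrices (each row a distribution over key tokens).
#' @return A `tokens x d_model` matrix, or a list `(out, attn)` when
#'   `return_attn = TRUE`.
#' @export
cross_attention <- function(f_rec, f_single, model, return_attn = FALSE) {
  check_fusion_shapes(f_rec, f_single)
  res <- ag_no_grad(fwd_cross_attention(as_node(f_rec), as_node(f_single), model,
                                        return_attn = TRUE))
  if (return_attn) list(out = res$out$value, attn = res$attn) else res$out$value
}

#' Fuse reconstructed and single-lead feature maps
#'
#' Cross-attention (queries from the reconstructed map) followed by one
#' self-attention transformer layer. The result is the enhanced feature map
#' passed to the classifier.
#'
#' @inheritParams cross_attention
#' @return A `tokens x d_model` enhanced feature matrix.
#' @export
fuse <- function(f_rec, f_single, model) {
  check_fusion_shapes(f_rec, f_single)
  ag_no_grad(fwd_fuse(as_node(f_rec), as_node(f_single), model,
                      training = FALSE))$value
}

#' Initialize classifier parameters
#'
#' The classifier concatenates global average and global max pooling over
#' time (giving `2 * d_model` features) and applies an affine map + softmax.
#'
#' @param d_model Feature width of the incoming map.
#' @param k Number of classes (at least 2).
#' @return A parameter list with weight `w` (`2 d_model x k`) and bias `b`.
#' @export
classifier_init <- function(d_model, k) {
  if (k < 2L) stop("need at least 2 classes")
  init_dense(2L * d_model, k)
}

fwd_classify <- function(f, params) {
  pooled <- ag_cbind(list(ag_colmeans(f), ag_colmax(f)))
  ag_softmax_rows(dense(pooled, params))
}

#' Classify an enhanced feature map
#'
#' Global average pooling and global max pooling over time are concatenated
#' and mapped through a fully connected layer with softmax activation.
#'
#' @param f_enhance A `tokens x d_model` feature matrix.
#' @param params A [classifier_init()] parameter list.
#' @return A probability vector of length `k` (positive, sums to 1).
#' @export
classify <- function(f_enhance, params) {
  if (2L * ncol(f_enhance) != nrow(params$w$value)) {
    stop("feature width ", ncol(f_enhance), " does not match classifier input ",
         nrow(params$w$value) / 2)
  }
  as.vector(ag_no_grad(fwd_classify(as_node(f_enhance), params))$value)
}

#' Teacher classifier head
#'
#' Identical contract to [classify()], applied to the frozen teacher's
#' 12-lead feature map with the teacher's own weight and bias.
#'
#' @param f_full A `tokens x d_model` teacher feature matrix.
#' @param params The teacher's classifier parameter list.
#' @return A probability vector over classes.
#' @export
teacher_classify <- function(f_full, params) classify(f_full, params)
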