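# Feature reconstruction: a small transformer encoder that maps single-lead
# feature maps towards the feature distribution of the frozen 12-lead
# teacher. Training minimizes a token-wise alignment loss (L1 by default)
# between the reconstructed map and the teacher's map.

#' Reconstruction-module specification
#'
#' @param d_model Feature-map width; must match the extractor's `d_model`.
#' @param n_layers Number of transformer encoder layers (2 balances capacity
#'   against cost and is the default).
#' @param n_heads Attention heads.
#' @param loss_kind Alignment loss: `"L1"` (default), `"L2"`, `"COS"`,
#'   `"KL"` or `"JS"`. See [recon_loss()].
#' @param ffn_mult Feed-forward width multiplier.
#' @param dropout Training-time dropout rate.
#' @return An object of class `recon_spec`.
#' @export
recon_spec <- function(d_model, n_layers = 2L, n_heads = 2L, loss_kind = "L1",
                       ffn_mult = 4L, dropout = 0.1) {
  loss_kind <- match.arg(loss_kind, c("L1", "L2", "COS", "KL", "JS"))
  if (n_layers < 1L) stop("n_layers must be at least 1")
  if (d_model %% n_heads != 0L) stop("d_model must be divisible by n_heads")
  structure(list(d_model = as.integer(d_model), n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads), loss_kind = loss_kind,
                 ffn_mult = as.integer(ffn_mult), dropout = dropout),
            class = "recon_spec")
}

#' Initialize reconstruction-module weights
#' @param spec A [recon_spec()].
#' @return A parameter tree of class `recon_model`.
#' @export
recon_init <- function(spec) {
  stopifnot(inherits(spec, "recon_spec"))
  layers <- lapply(seq_len(spec$n_layers), function(i)
    init_transformer_layer(spec$d_model, spec$n_heads, spec$ffn_mult))
  structure(list(layers = layers, final_ln = init_layernorm(spec$d_model),
                 spec = spec), class = "recon_model")
}

fwd_reconstruct <- function(x, model, training = FALSE) {
  spec <- model$spec
  x <- ag_add_const(x, positional_encoding(nrow(x$value), spec$d_model))
  for (p in model$layers) {
    x <- transformer_layer(x, p, training = training,
                           dropout = if (training) spec$dropout else 0)
  }
  ag_layernorm(x, model$final_ln$g, model$final_ln$b)
}

#' Reconstruct 12-lead-like features from single-lead features
#'
#' Applies positional encoding and the reconstruction transformer encoder.
#' Shape is preserved: the output lives at the same `tokens x d_model`
#' resolution as the input single-lead feature map.
#'
#' @param f_single A `tokens x d_model` feature matrix.
#' @param model A [recon_init()] parameter tree.
#' @return A `tokens x d_model` reconstructed feature matrix.
#' @export
reconstruct <- function(f_single, model) {
  if (ncol(f_single) != model$spec$d_model) {
    stop("feature map has ", ncol(f_single), " channels; reconstruction module expects ",
         model$spec$d_model)
  }
  ag_no_grad(fwd_reconstruct(as_node(f_single), model, training = FALSE))$value
}

# node-level loss (used during training); target is a plain matrix (teacher
# features carry no gradient)
# differentiable alignment loss; f_rec is a node, f_full a plain matrix
# (teacher target, no gradient). Values agree with recon_loss().
fwd_recon_loss <- function(f_rec, f_full, kind) {
  tgt <- ag_value(f_full)
  tokens <- nrow(tgt)
  ones <- matrix(1, ncol(tgt), 1L)
  rowsums <- function(x) ag_matmul(x, ones)  # T x 1
  switch(kind,
    L1 = ag_mean_all(ag_abs(ag_sub(f_rec, tgt))),
    L2 = {
      d <- ag_sub(f_rec, tgt)
      ag_mean_all(ag_mul(d, d))
    },
    COS = {
      tn <- sqrt(rowSums(tgt^2))
      tn[tn == 0] <- 1
      tgt_n <- tgt / tn
      dots <- rowsums(ag_mul(f_rec, tgt_n))                     # T x 1
      inv_norm <- ag_pow(ag_add_const(rowsums(ag_mul(f_rec, f_rec)),
                                      matrix(1e-12, tokens, 1L)), -0.5)
      ag_add_const(ag_scale(ag_mean_all(ag_mul(dots, inv_norm)), -1),
                   matrix(1, 1L, 1L))
    },
    KL = {
      p <- softmax_rows(tgt)
      lq <- ag_log(ag_softmax_rows(f_rec))
      const <- mean(rowSums(p * log(p)))
      ag_add_const(ag_scale(ag_mean_all(ag_scale(rowsums(ag_mul(lq, p)), 1)), -1),
                   matrix(const, 1L, 1L))
    },
    JS = {
      p <- softmax_rows(tgt)
      q <- ag_softmax_rows(f_rec)
      m <- ag_scale(ag_add_const(q, p), 0.5)
      lm <- ag_scale(ag_log(m), 1 / log(2))
      lq <- ag_scale(ag_log(q), 1 / log(2))
      # 0.5 * mean_t [ sum p (log2 p - log2 m) + sum q (log2 q - log2 m) ]
      t1 <- ag_scale(ag_mean_all(rowsums(ag_mul(lm, p))), -1)   # -mean sum p log2 m
      t2 <- ag_mean_all(rowsums(ag_sub(ag_mul(q, lq), ag_mul(q, lm))))
      ag_scale(ag_add(ag_add_const(t1, matrix(mean(rowSums(p * log2(p))), 1L, 1L)), t2),
               0.5)
    })
}

#' Feature-alignment loss between reconstructed and target feature maps
#'
#' Measures how far a reconstructed feature map `f_rec` lies from the frozen
#' teacher's target map `f_full`. All variants are normalized so their value
#' does not scale with token count or width:
#' * `L1` - mean absolute elementwise difference (the training default);
#' * `L2` - mean squared elementwise difference;
#' * `COS` - one minus the mean per-token cosine similarity;
#' * `KL` - Kullback-Leibler divergence `KL(p_full || p_rec)` between
#'   per-token softmax-normalized channel distributions (target as
#'   reference), averaged over tokens, in nats;
#' * `JS` - Jensen-Shannon divergence of the same distributions, base 2, so
#'   symmetric and bounded in \[0, 1\].
#'
#' @param f_rec,f_full Equal-shaped `tokens x d_model` matrices.
#' @param loss_kind One of `"L1"`, `"L2"`, `"COS"`, `"KL"`, `"JS"`.
#' @return A single non-negative number; 0 iff the maps agree (up to the
#'   softmax normalization for `KL`/`JS`).
#' @examples
#' recon_loss(matrix(c(1, 3), 1), matrix(c(2, 5), 1), "L1")  # 1.5
#' @export
recon_loss <- function(f_rec, f_full, loss_kind = "L1") {
  loss_kind <- match.arg(loss_kind, c("L1", "L2", "COS", "KL", "JS"))
  if (!all(dim(f_rec) == dim(f_full))) {
    stop("shape mismatch: f_rec is ", paste(dim(f_rec), collapse = "x"),
         ", f_full is ", paste(dim(f_full), collapse = "x"))
  }
  switch(loss_kind,
    L1 = mean(abs(f_rec - f_full)),
    L2 = mean((f_rec - f_full)^2),
    COS = {
      num <- rowSums(f_rec * f_full)
      den <- sqrt(rowSums(f_rec^2)) * sqrt(rowSums(f_full^2))
      cosv <- ifelse(den == 0, as.numeric(num == 0), num / pmax(den, .Machine$double.eps))
      1 - mean(cosv)
    },
    KL = {
      p <- softmax_rows(f_full)
      q <- softmax_rows(f_rec)
      mean(rowSums(p * (log(p) - log(q))))
    },
    JS = {
      p <- softmax_rows(f_full)
      q <- softmax_rows(f_rec)
      m <- (p + q) / 2
      kl2 <- function(a, b) rowSums(a * (log2(a) - log2(b)))
      mean(0.5 * kl2(p, m) + 0.5 * kl2(q, m))
    })
}

softmax_rows <- function(x) {
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}
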