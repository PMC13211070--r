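# Neural building blocks shared by the extractor, the reconstruction module
# and the fusion head. All forward functions take and return autodiff nodes;
# parameters are nested lists of ag_param() leaves created by the init_*
# constructors (which consume the current RNG stream).

he_init <- function(nr, nc, fan_in = nr) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

glorot_init <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
}

zeros <- function(nr, nc) matrix(0, nr, nc)

init_dense <- function(d_in, d_out, init = glorot_init) {
  list(w = ag_param(init(d_in, d_out)), b = ag_param(zeros(1L, d_out)))
}

dense <- function(x, p) ag_dense(x, p$w, p$b)

# ---- squeeze-and-excitation ----

init_se <- function(channels, reduction) {
  hidden <- max(1L, channels %/% reduction)
  list(fc1 = init_dense(channels, hidden, he_init),
       fc2 = init_dense(hidden, channels))
}

#' Squeeze-and-excitation channel recalibration
#'
#' Computes a per-channel gate `g = sigmoid(W2 relu(W1 avg(x) + b1) + b2)`
#' from the time-averaged channel descriptor and rescales every channel of
#' the feature map by its gate. Gates are strictly inside (0, 1), so a zero
#' input maps to a zero output.
#'
#' @param x Feature map, a `tokens x channels` matrix or autodiff node.
#' @param se SE parameter list from the internal constructor (two dense
#'   layers whose outer width must equal `ncol(x)`).
#' @return Same type as `x` (matrix in, matrix out): the recalibrated map.
#' @examples
#' se <- slecg:::init_se(4L, 2L)
#' x <- matrix(rnorm(20), 5, 4)
#' y <- se_recalibrate(x, se)
#' range(y / x)  # constant per column, inside (0, 1)
#' @export
se_recalibrate <- function(x, se) {
  plain <- !is.environment(x)
  if (plain) x <- as_node(x)
  ch <- ncol(x$value)
  if (nrow(se$fc1$w$value) != ch) {
    stop("se_recalibrate: feature map has ", ch, " channels but SE parameters expect ",
         nrow(se$fc1$w$value))
  }
  out <- ag_se(x, se$fc1$w, se$fc1$b, se$fc2$w, se$fc2$b)
  if (plain) out$value else out
}

# ---- attention ----

init_mha <- function(d_model, n_heads) {
  stopifnot(d_model %% n_heads == 0L)
  list(wq = init_dense(d_model, d_model), wk = init_dense(d_model, d_model),
       wv = init_dense(d_model, d_model), wo = init_dense(d_model, d_model),
       n_heads = n_heads)
}

# multi-head scaled dot-product attention. Queries from xq, keys/values from
# xkv (self-attention when identical). Returns list(out, attn) where attn is
# a plain list of per-head weight matrices (values only, for inspection).
mha <- function(xq, xkv, p) {
  q <- dense(xq, p$wq)
  k <- dense(xkv, p$wk)
  v <- dense(xkv, p$wv)
  d_model <- ncol(q$value)
  h <- p$n_heads
  dk <- d_model %/% h
  heads <- vector("list", h)
  attn <- vector("list", h)
  for (i in seq_len(h)) {
    idx <- ((i - 1L) * dk + 1L):(i * dk)
    qh <- ag_cols(q, idx); kh <- ag_cols(k, idx); vh <- ag_cols(v, idx)
    a <- ag_softmax_rows(ag_scale(ag_matmul(qh, ag_transpose(kh)), 1 / sqrt(dk)))
    attn[[i]] <- a$value
    heads[[i]] <- ag_matmul(a, vh)
  }
  list(out = dense(ag_cbind(heads), p$wo), attn = attn)
}

init_transformer_layer <- function(d_model, n_heads, ffn_mult = 4L) {
  list(ln1 = list(g = ag_param(matrix(1, 1L, d_model)), b = ag_param(zeros(1L, d_model))),
       attn = init_mha(d_model, n_heads),
       ln2 = list(g = ag_param(matrix(1, 1L, d_model)), b = ag_param(zeros(1L, d_model))),
       ffn1 = init_dense(d_model, ffn_mult * d_model, he_init),
       ffn2 = init_dense(ffn_mult * d_model, d_model))
}

# pre-norm transformer encoder layer: x + MHA(LN(x)); then x + FFN(LN(x))
transformer_layer <- function(x, p, training = FALSE, dropout = 0) {
  xn <- ag_layernorm(x, p$ln1$g, p$ln1$b)
  a <- mha(xn, xn, p$attn)
  x <- ag_add(x, ag_dropout(a$out, dropout, training))
  f <- dense(ag_relu(dense(ag_layernorm(x, p$ln2$g, p$ln2$b), p$ffn1)), p$ffn2)
  ag_add(x, ag_dropout(f, dropout, training))
}

init_layernorm <- function(d_model) {
  list(g = ag_param(matrix(1, 1L, d_model)), b = ag_param(zeros(1L, d_model)))
}

#' Fixed sinusoidal positional encoding
#'
#' @param tokens Number of time tokens.
#' @param d_model Embedding width.
#' @return A `tokens x d_model` matrix of interleaved sine/cosine waves with
#'   geometrically spaced wavelengths (10^4 span), as used by standard
#'   transformer encoders.
#' @export
positional_encoding <- function(tokens, d_model) {
  pos <- seq_len(tokens) - 1L
  pe <- matrix(0, tokens, d_model)
  half <- ceiling(d_model / 2)
  for (i in seq_len(half)) {
    freq <- 1 / 10000^(2 * (i - 1) / d_model)
    pe[, 2L * i - 1L] <- sin(pos * freq)
    if (2L * i <= d_model) pe[, 2L * i] <- cos(pos * freq)
  }
  pe
}
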