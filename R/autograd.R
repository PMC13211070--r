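# Reverse-mode automatic differentiation on dense matrices.
#
# Every intermediate quantity is a node: an environment holding `value` (a
# numeric matrix), `grad` (accumulated cotangent, same shape), `parents`
# (list of nodes) and `vjp` (vector-Jacobian product: cotangent of the output
# -> list of cotangents, one per parent). Operation nodes are appended to a
# global tape in creation order, so a single reverse sweep over the tape is
# a valid reverse topological order. Parameters are leaf nodes that live
# outside the tape and keep their gradients across `ag_reset()` calls; the
# optimizer zeroes them.

.ag <- new.env(parent = emptyenv())
.ag$tape <- vector("list", 1024L)
.ag$n <- 0L
.ag$record <- TRUE


# fast column-wise broadcast helpers (compiled; avoid sweep()/aperm overhead):
# v must have length ncol(x)
cmul <- function(x, v) .Call(C_cmul, x, as.double(v))
cadd <- function(x, v) .Call(C_cadd, x, as.double(v))

#' Clear the autodiff tape
#'
#' Discards all recorded operations (and their activations). Parameters and
#' their accumulated gradients are untouched. Call once per training example
#' or batch element, before the forward pass.
#' @return Invisibly, `NULL`.
#' @keywords internal
ag_reset <- function() {
  .ag$tape <- vector("list", 1024L)
  .ag$n <- 0L
  invisible(NULL)
}

#' Evaluate an expression without recording gradients
#'
#' Inside `ag_no_grad()` forward computations build no tape, so memory stays
#' flat and `ag_backward()` cannot reach through them. Used for evaluation
#' passes and for the frozen teacher.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
ag_no_grad <- function(expr) {
  old <- .ag$record
  .ag$record <- FALSE
  on.exit(.ag$record <- old)
  expr
}

new_node <- function(value, parents = NULL, vjp = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  if (.ag$record && !is.null(parents)) {
    nd$parents <- parents
    nd$vjp <- vjp
    n <- .ag$n + 1L
    if (n > length(.ag$tape)) .ag$tape <- c(.ag$tape, vector("list", length(.ag$tape)))
    .ag$tape[[n]] <- nd
    .ag$n <- n
  }
  nd
}

#' Create a trainable parameter node
#' @param value Numeric matrix (or vector, promoted to a 1-row matrix).
#' @return A leaf node with `$param = TRUE`.
#' @keywords internal
ag_param <- function(value) {
  if (!is.matrix(value)) value <- matrix(value, nrow = 1L)
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$param <- TRUE
  p
}

as_node <- function(x) {
  if (is.environment(x)) return(x)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  new_node(x)
}

#' @keywords internal
ag_value <- function(x) if (is.environment(x)) x$value else x

accumulate <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

#' Reverse sweep: accumulate gradients of `loss` into all reachable nodes
#' @param loss A scalar (1 x 1) node produced while recording.
#' @return Invisibly, `NULL`. Gradients land in each node's `$grad`.
#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(is.environment(loss), length(loss$value) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  if (.ag$n == 0L) return(invisible(NULL))
  for (i in seq.int(.ag$n, 1L)) {
    nd <- .ag$tape[[i]]
    if (is.null(nd$grad)) next
    gs <- nd$vjp(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      if (!is.null(gs[[j]])) accumulate(ps[[j]], gs[[j]])
    }
  }
  invisible(NULL)
}

# ---- arithmetic ----

ag_add <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  new_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  new_node(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$value; bv <- b$value
  new_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

# multiply by a fixed scalar
ag_scale <- function(a, k) {
  a <- as_node(a)
  new_node(a$value * k, list(a), function(g) list(g * k))
}

# add a fixed matrix (e.g. positional encoding)
ag_add_const <- function(a, m) {
  a <- as_node(a)
  new_node(a$value + m, list(a), function(g) list(g))
}

ag_matmul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$value; bv <- b$value
  new_node(av %*% bv, list(a, b),
           function(g) list(g %*% t(bv), crossprod(av, g)))
}

ag_transpose <- function(a) {
  a <- as_node(a)
  new_node(t(a$value), list(a), function(g) list(t(g)))
}

# add a 1 x C row vector to every row of a T x C matrix
ag_addbias <- function(x, b) {
  x <- as_node(x); b <- as_node(b)
  bv <- b$value
  new_node(cadd(x$value, as.vector(bv)), list(x, b),
           function(g) list(g, matrix(colSums(g), 1L)))
}

# scale column c of a T x C matrix by s[c] (s a 1 x C node), e.g. SE gating
ag_colscale <- function(x, s) {
  x <- as_node(x); s <- as_node(s)
  xv <- x$value; sv <- as.vector(s$value)
  new_node(cmul(xv, sv), list(x, s),
           function(g) list(cmul(g, sv),
                            matrix(colSums(g * xv), 1L)))
}

# fused affine map: x %*% w + b (one tape node instead of two)
ag_dense <- function(x, w, b) {
  x <- as_node(x); w <- as_node(w); b <- as_node(b)
  xv <- x$value; wv <- w$value
  out <- cadd(xv %*% wv, as.vector(b$value))
  new_node(out, list(x, w, b), function(g) {
    list(g %*% t(wv), crossprod(xv, g),
         matrix(.colSums(g, nrow(g), ncol(g)), 1L))
  })
}

# fused squeeze-and-excitation gate: out = x * sigmoid(relu(mean(x) W1 + b1) W2 + b2)
# Single tape node; the closed-form vector-Jacobian product backs out the
# whole two-layer gating network.
ag_se <- function(x, w1, b1, w2, b2) {
  x <- as_node(x); w1 <- as_node(w1); b1 <- as_node(b1)
  w2 <- as_node(w2); b2 <- as_node(b2)
  xv <- x$value
  tn <- nrow(xv); cn <- ncol(xv)
  z <- matrix(.colMeans(xv, tn, cn), 1L)
  w1v <- w1$value; w2v <- w2$value
  h <- z %*% w1v + b1$value
  hr <- h * (h > 0)
  s <- 1 / (1 + exp(-(hr %*% w2v + b2$value)))
  sv <- as.vector(s)
  new_node(cmul(xv, sv), list(x, w1, b1, w2, b2), function(g) {
    ds <- matrix(.colSums(g * xv, tn, cn), 1L)
    dg2 <- ds * s * (1 - s)
    dhr <- dg2 %*% t(w2v)
    dw2 <- crossprod(hr, dg2)
    dh <- dhr * (h > 0)
    dw1 <- crossprod(z, dh)
    dz <- dh %*% t(w1v)
    dx <- cmul(g, sv) + matrix(as.vector(dz) / tn, tn, cn, byrow = TRUE)
    list(dx, dw1, dh, dw2, dg2)
  })
}

# ---- nonlinearities ----

ag_relu <- function(a) {
  a <- as_node(a)
  av <- a$value
  new_node(.Call(C_relu, av), list(a),
           function(g) list(.Call(C_relu_grad, g, av)))
}

ag_sigmoid <- function(a) {
  a <- as_node(a)
  y <- 1 / (1 + exp(-a$value))
  new_node(y, list(a), function(g) list(g * y * (1 - y)))
}

ag_abs <- function(a) {
  a <- as_node(a)
  s <- sign(a$value)
  new_node(abs(a$value), list(a), function(g) list(g * s))
}

ag_pow <- function(a, p) {
  a <- as_node(a)
  av <- a$value
  new_node(av^p, list(a), function(g) list(g * p * av^(p - 1)))
}

ag_log <- function(a) {
  a <- as_node(a)
  av <- a$value
  new_node(log(av), list(a), function(g) list(g / av))
}

# row-wise softmax of a T x C matrix
ag_softmax_rows <- function(a) {
  a <- as_node(a)
  v <- a$value
  m <- apply(v, 1L, max)
  e <- exp(v - m)
  y <- e / rowSums(e)
  new_node(y, list(a), function(g) {
    gy <- g * y
    list(gy - y * rowSums(gy))
  })
}

# ---- reductions / pooling ----

ag_mean_all <- function(a) {
  a <- as_node(a)
  n <- length(a$value)
  new_node(matrix(mean(a$value), 1L, 1L), list(a),
           function(g) list(matrix(g[1L] / n, nrow(a$value), ncol(a$value))))
}

ag_sum_all <- function(a) {
  a <- as_node(a)
  new_node(matrix(sum(a$value), 1L, 1L), list(a),
           function(g) list(matrix(g[1L], nrow(a$value), ncol(a$value))))
}

# global average pool over time: T x C -> 1 x C
ag_colmeans <- function(a) {
  a <- as_node(a)
  n <- nrow(a$value)
  new_node(matrix(colMeans(a$value), 1L), list(a),
           function(g) matrix(rep(as.vector(g) / n, each = n), nrow = n) |> list())
}

# global max pool over time: T x C -> 1 x C
ag_colmax <- function(a) {
  a <- as_node(a)
  v <- a$value
  idx <- max.col(t(v), ties.method = "first")  # row index of max per column
  new_node(matrix(v[cbind(idx, seq_len(ncol(v)))], 1L), list(a),
           function(g) {
             out <- matrix(0, nrow(v), ncol(v))
             out[cbind(idx, seq_len(ncol(v)))] <- as.vector(g)
             list(out)
           })
}

# non-overlapping stride-2 max pool over time: T x C -> T/2 x C (T even)
ag_maxpool2 <- function(a) {
  a <- as_node(a)
  v <- a$value
  tn <- nrow(v)
  stopifnot(tn %% 2L == 0L)
  odd <- v[seq(1L, tn, 2L), , drop = FALSE]
  even <- v[seq(2L, tn, 2L), , drop = FALSE]
  takeodd <- odd >= even  # ties -> first
  new_node(pmax(odd, even), list(a), function(g) {
    out <- matrix(0, tn, ncol(v))
    out[seq(1L, tn, 2L), ][takeodd] <- g[takeodd]
    out[seq(2L, tn, 2L), ][!takeodd] <- g[!takeodd]
    list(out)
  })
}

# ---- structure ----

# column slice (e.g. one attention head)
ag_cols <- function(a, idx) {
  a <- as_node(a)
  new_node(a$value[, idx, drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(a$value), ncol(a$value))
    out[, idx] <- g
    list(out)
  })
}

# column-concatenate a list of T x C_i nodes
ag_cbind <- function(nodes) {
  nodes <- lapply(nodes, as_node)
  widths <- vapply(nodes, function(n) ncol(n$value), 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  new_node(do.call(cbind, lapply(nodes, function(n) n$value)), nodes,
           function(g) lapply(seq_along(nodes), function(j)
             g[, starts[j]:ends[j], drop = FALSE]))
}

# ---- convolutions ----

# im2col for stride-1 same-padded 1D convolution; x is T x C, returns T x (k*C)
# with tap-major column blocks (tap j occupies columns (j-1)*C + 1 .. j*C).
im2col1d <- function(x, k) {
  tn <- nrow(x); cn <- ncol(x)
  p <- (k - 1L) %/% 2L
  xp <- rbind(matrix(0, p, cn), x, matrix(0, k - 1L - p, cn))
  out <- matrix(0, tn, k * cn)
  for (j in seq_len(k)) out[, ((j - 1L) * cn + 1L):(j * cn)] <- xp[j:(j + tn - 1L), , drop = FALSE]
  out
}

col2im1d <- function(g2, k, tn, cn) {
  p <- (k - 1L) %/% 2L
  gx <- matrix(0, tn + k - 1L, cn)
  for (j in seq_len(k)) {
    rows <- j:(j + tn - 1L)
    gx[rows, ] <- gx[rows, ] + g2[, ((j - 1L) * cn + 1L):(j * cn), drop = FALSE]
  }
  gx[(p + 1L):(p + tn), , drop = FALSE]
}

# stride-1 same-padded 1D convolution: x T x Cin, W (k*Cin) x Cout, b 1 x Cout
ag_conv1d <- function(x, w, b, k) {
  x <- as_node(x); w <- as_node(w); b <- as_node(b)
  xv <- x$value
  x2 <- im2col1d(xv, k)
  wv <- w$value
  out <- cadd(x2 %*% wv, as.vector(b$value))
  new_node(out, list(x, w, b), function(g) {
    list(col2im1d(g %*% t(wv), k, nrow(xv), ncol(xv)),
         crossprod(x2, g),
         matrix(colSums(g), 1L))
  })
}

# depthwise convolution, kernel 3, stride 2, pad 1: x T x C (T even), w 3 x C,
# b 1 x C; output (T/2) x C. Output row t sees input rows 2t-2, 2t-1, 2t.
ag_dwconv3s2 <- function(x, w, b) {
  x <- as_node(x); w <- as_node(w); b <- as_node(b)
  xv <- x$value
  tn <- nrow(xv); cn <- ncol(xv)
  stopifnot(tn %% 2L == 0L)
  wv <- w$value
  xp <- rbind(matrix(0, 1L, cn), xv, matrix(0, 1L, cn))
  i0 <- seq(1L, tn, 2L)  # rows of xp feeding tap 1
  out <- cmul(xp[i0, , drop = FALSE], wv[1L, ]) +
    cmul(xp[i0 + 1L, , drop = FALSE], wv[2L, ]) +
    cmul(xp[i0 + 2L, , drop = FALSE], wv[3L, ])
  out <- cadd(out, as.vector(b$value))
  new_node(out, list(x, w, b), function(g) {
    gxp <- matrix(0, tn + 2L, cn)
    gw <- matrix(0, 3L, cn)
    for (j in 1:3) {
      rows <- i0 + j - 1L
      gxp[rows, ] <- gxp[rows, ] + cmul(g, wv[j, ])
      gw[j, ] <- colSums(g * xp[rows, , drop = FALSE])
    }
    list(gxp[2L:(tn + 1L), , drop = FALSE], gw, matrix(colSums(g), 1L))
  })
}

# ---- normalization ----

# layer norm across channels, per time token; gamma, beta are 1 x C params
ag_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_node(x); gamma <- as_node(gamma); beta <- as_node(beta)
  xv <- x$value
  cn <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowSums(xc * xc) / cn
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  gv <- as.vector(gamma$value)
  out <- cadd(cmul(xhat, gv), as.vector(beta$value))
  new_node(out, list(x, gamma, beta), function(g) {
    dxhat <- cmul(g, gv)
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * istd
    list(dx, matrix(colSums(g * xhat), 1L), matrix(colSums(g), 1L))
  })
}

# batch norm over the time axis, per channel. One record is one "batch":
# statistics are the current record's per-channel time-axis moments in both
# training and evaluation (instance-style normalization), which keeps the
# train/eval activation distributions identical — with record-sized batches,
# global running averages mix class-dependent feature scales and shift the
# eval distribution away from what the network trained on. Running moments
# are still tracked (momentum 0.1) while training and can be requested
# explicitly with use_running = TRUE (that path is a pure per-channel affine
# map, e.g. for frozen-statistics checks).
ag_batchnorm <- function(x, gamma, beta, bn, training, eps = 1e-5,
                         use_running = FALSE) {
  x <- as_node(x); gamma <- as_node(gamma); beta <- as_node(beta)
  xv <- x$value
  tn <- nrow(xv)
  gv <- as.vector(gamma$value)
  if (!use_running) {
    mu <- colMeans(xv)
    xc <- cadd(xv, -mu)
    va <- colSums(xc * xc) / tn
    if (training) {
      bn$running_mean <- (1 - bn$momentum) * bn$running_mean + bn$momentum * mu
      bn$running_var <- (1 - bn$momentum) * bn$running_var + bn$momentum * va
    }
    istd <- 1 / sqrt(va + eps)
    xhat <- cmul(xc, istd)
    out <- cadd(cmul(xhat, gv), as.vector(beta$value))
    new_node(out, list(x, gamma, beta), function(g) {
      dxhat <- cmul(g, gv)
      dx <- cmul(cadd(dxhat - xhat * rep(colMeans(dxhat * xhat), each = tn),
                      -colMeans(dxhat)), istd)
      list(dx, matrix(colSums(g * xhat), 1L), matrix(colSums(g), 1L))
    })
  } else {
    istd <- 1 / sqrt(bn$running_var + eps)
    xhat <- cmul(cadd(xv, -bn$running_mean), istd)
    out <- cadd(cmul(xhat, gv), as.vector(beta$value))
    new_node(out, list(x, gamma, beta), function(g) {
      list(cmul(cmul(g, gv), istd),
           matrix(colSums(g * xhat), 1L), matrix(colSums(g), 1L))
    })
  }
}

# inverted dropout; identity when rate == 0 or not training
ag_dropout <- function(x, rate, training) {
  x <- as_node(x)
  if (!training || rate <= 0) return(x)
  m <- (matrix(stats::runif(length(x$value)), nrow(x$value)) >= rate) / (1 - rate)
  new_node(x$value * m, list(x), function(g) list(g * m))
}

# ---- parameter utilities ----

# recursively collect parameter nodes from a nested list
collect_params <- function(x) {
  if (is.environment(x)) {
    if (isTRUE(x$param)) return(list(x))
    return(list())
  }
  if (is.list(x)) return(do.call(c, lapply(x, collect_params)))
  list()
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Adam update; `st` is a state environment carrying step count t (and slots
# m_i/v_i grown lazily on each param node)
adam_step <- function(params, lr, st, beta1 = 0.9, beta2 = 0.99, eps = 1e-8,
                      grad_scale = 1) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (p in params) {
    if (is.null(p$grad)) next
    g <- p$grad * grad_scale
    if (is.null(p$m)) { p$m <- g * 0; p$v <- g * 0 }
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g * g
    p$value <- p$value - lr * (p$m / bc1) / (sqrt(p$v / bc2) + eps)
  }
  invisible(NULL)
}

# deep copy / restore of parameter values (model checkpointing)
params_snapshot <- function(params) lapply(params, function(p) p$value)

params_restore <- function(params, snap) {
  stopifnot(length(params) == length(snap))
  for (i in seq_along(params)) params[[i]]$value <- snap[[i]]
  invisible(NULL)
}
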