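# Reverse-mode automatic differentiation on a flat tape.
#
# Nodes are environments holding `value`, an accumulated `grad`, and a
# `backward` closure that routes the node's gradient to its parents.
# Operations are deliberately coarse (a whole convolution, a whole
# attention block) so the tape stays short and the heavy lifting runs in
# BLAS / compiled code. Parameters live in a parameter store and are
# wrapped into leaf nodes at each forward pass; frozen parameters simply
# never accumulate gradient.

tape_new <- function(training = TRUE) {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 512L)
  t$n <- 0L
  t$training <- training
  t
}

node_new <- function(tape, value, backward = NULL, param_name = NULL,
                     frozen = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  nd$param_name <- param_name
  nd$frozen <- frozen
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    length(tape$nodes) <- 2L * length(tape$nodes)
  tape$nodes[[tape$n]] <- nd
  nd
}

acc_grad <- function(nd, g) {
  if (is.null(nd)) return(invisible(NULL))
  if (isTRUE(nd$frozen)) return(invisible(NULL))
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

backward_tape <- function(tape, loss_node) {
  loss_value <- loss_node$value
  loss_node$grad <- 1
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$backward)) {
      if (!is.null(nd$grad)) nd$backward(nd$grad)
      # processed in reverse creation order, so this node's buffers can no
      # longer be referenced by any remaining backward: release them early
      nd$grad <- NULL
      nd$value <- NULL
    }
  }
  loss_node$value <- loss_value
  invisible(NULL)
}

# gradients of all parameter nodes on the tape, keyed by parameter name;
# frozen parameters report an explicit zero gradient
collect_grads <- function(tape, param_store) {
  out <- list()
  for (i in seq_len(tape$n)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$param_name)) next
    g <- nd$grad
    if (is.null(g)) {
      g <- array(0, dim = dim(nd$value) %||% length(nd$value))
      if (is.null(dim(nd$value))) g <- as.numeric(g)
    }
    if (is.null(out[[nd$param_name]])) out[[nd$param_name]] <- g
    else out[[nd$param_name]] <- out[[nd$param_name]] + g
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- parameter store -------------------------------------------------------

param_store <- function() {
  ps <- new.env(parent = emptyenv())
  ps$params <- list()
  ps$state <- list()   # batchnorm running statistics, keyed by layer name
  ps$frozen <- character(0)
  ps
}

ps_add <- function(ps, name, value) {
  ps$params[[name]] <- value
  invisible(ps)
}

pnode <- function(tape, ps, name) {
  node_new(tape, ps$params[[name]], param_name = name,
           frozen = any(startsWith(name, ps$frozen)))
}

# ---- elementary ops --------------------------------------------------------

op_input <- function(tape, value) node_new(tape, value)

op_conv2d <- function(tape, x, w, b = NULL, stride = 1, pad = 0,
                      need_gx = TRUE) {
  y <- cpp_conv2d_fw(x$value, dim(x$value), w$value, dim(w$value),
                     if (is.null(b)) numeric(0) else b$value, stride, pad)
  nd <- node_new(tape, y)
  nd$backward <- function(g) {
    need_gw <- !isTRUE(w$frozen)
    bw <- cpp_conv2d_bw(x$value, dim(x$value), w$value, dim(w$value),
                        g, stride, pad, need_gx, need_gw)
    if (need_gx) acc_grad(x, bw$gx)
    acc_grad(w, bw$gw)
    if (!is.null(b)) acc_grad(b, bw$gb)
  }
  nd
}

# fused batchnorm + optional relu (one pass over the activation tensor)
op_bn_act <- function(tape, x, gamma, beta, state, training,
                      relu = TRUE, momentum = 0.1, eps = 1e-5) {
  d <- dim(x$value)
  C <- d[3]
  fw <- cpp_bnact_fw(x$value, d, gamma$value, beta$value,
                     state$rm %||% numeric(C), state$rv %||% rep(1, C),
                     training, eps, relu)
  if (training) {
    if (is.null(state$rm)) { state$rm <- fw$mu; state$rv <- fw$var }
    else {
      state$rm <- (1 - momentum) * state$rm + momentum * fw$mu
      state$rv <- (1 - momentum) * state$rv + momentum * fw$var
    }
  }
  nd <- node_new(tape, fw$y)
  nd$backward <- function(g) {
    bw <- cpp_bnact_bw(x$value, d, gamma$value, fw$mu, fw$var, fw$y, g,
                       training, eps, relu)
    acc_grad(x, bw$gx)
    acc_grad(gamma, bw$ggamma)
    acc_grad(beta, bw$gbeta)
  }
  nd
}

# fused residual add + relu
op_add_relu <- function(tape, a, b) {
  y <- cpp_addrelu_fw(a$value, b$value)
  nd <- node_new(tape, y)
  nd$backward <- function(g) {
    gm <- cpp_addrelu_bw(y, g)
    acc_grad(a, gm)
    acc_grad(b, gm)
  }
  nd
}

op_maxpool <- function(tape, x, ksize, stride, pad) {
  fw <- cpp_maxpool_fw(x$value, dim(x$value), ksize, stride, pad)
  nd <- node_new(tape, fw$y)
  nd$backward <- function(g)
    acc_grad(x, cpp_maxpool_bw(g, fw$arg, dim(x$value)))
  nd
}

op_relu <- function(tape, x) {
  fw <- cpp_relu_fw(x$value)
  nd <- node_new(tape, fw$y)
  nd$backward <- function(g) acc_grad(x, cpp_mask_mul(g, fw$keep))
  nd
}

op_add <- function(tape, a, b) {
  nd <- node_new(tape, a$value + b$value)
  nd$backward <- function(g) { acc_grad(a, g); acc_grad(b, g) }
  nd
}

# batch normalization over (H, W, N) per channel for (H, W, C, N) input
op_batchnorm <- function(tape, x, gamma, beta, state, training,
                         momentum = 0.1, eps = 1e-5) {
  d <- dim(x$value)
  C <- d[3]
  fw <- cpp_bn_fw(x$value, d, gamma$value, beta$value,
                  state$rm %||% numeric(C), state$rv %||% rep(1, C),
                  training, eps)
  if (training) {
    if (is.null(state$rm)) { state$rm <- fw$mu; state$rv <- fw$var }
    else {
      state$rm <- (1 - momentum) * state$rm + momentum * fw$mu
      state$rv <- (1 - momentum) * state$rv + momentum * fw$var
    }
  }
  nd <- node_new(tape, fw$y)
  nd$backward <- function(g) {
    bw <- cpp_bn_bw(x$value, d, gamma$value, fw$mu, fw$var, g, training, eps)
    acc_grad(x, bw$gx)
    acc_grad(gamma, bw$ggamma)
    acc_grad(beta, bw$gbeta)
  }
  nd
}

# subset images along the 4th axis
op_index_images <- function(tape, x, idx) {
  nd <- node_new(tape, x$value[, , , idx, drop = FALSE])
  nd$backward <- function(g) {
    gx <- array(0, dim(x$value))
    gx[, , , idx] <- g
    acc_grad(x, gx)
  }
  nd
}

# channel concatenation of feature maps sharing (h, w, ., N)
op_concat_channel <- function(tape, maps) {
  dims <- lapply(maps, function(m) dim(m$value))
  chans <- vapply(dims, `[`, numeric(1), 3)
  d1 <- dims[[1]]
  out <- array(0, c(d1[1], d1[2], sum(chans), d1[4]))
  off <- 0
  for (m in maps) {
    cm <- dim(m$value)[3]
    out[, , off + seq_len(cm), ] <- m$value
    off <- off + cm
  }
  nd <- node_new(tape, out)
  nd$backward <- function(g) {
    off <- 0
    for (m in maps) {
      cm <- dim(m$value)[3]
      acc_grad(m, g[, , off + seq_len(cm), , drop = FALSE])
      off <- off + cm
    }
  }
  nd
}

# add the per-position axial embedding plane, broadcast over channels
op_axial_add <- function(tape, x, table, axial_idx) {
  d <- dim(x$value)
  y <- x$value
  for (sl in seq_len(d[4])) {
    pl <- table$value[axial_idx[sl], , ]
    y[, , , sl] <- y[, , , sl] + as.vector(pl)  # recycles over channels
  }
  nd <- node_new(tape, y)
  nd$backward <- function(g) {
    acc_grad(x, g)
    if (!isTRUE(table$frozen)) {
      gt <- array(0, dim(table$value))
      for (sl in seq_len(d[4])) {
        gt[axial_idx[sl], , ] <- gt[axial_idx[sl], , ] +
          rowSums(g[, , , sl, drop = FALSE], dims = 2)
      }
      acc_grad(table, gt)
    }
  }
  nd
}

# replicate per-patient clinical embeddings over the (h, w) plane:
# Z (Npat x D) -> (h, w, D, Nsl) with pat_of_slice mapping slices to rows
op_clinical_expand <- function(tape, Z, h, w, pat_of_slice) {
  D <- ncol(Z$value)
  Nsl <- length(pat_of_slice)
  y <- array(0, c(h, w, D, Nsl))
  for (sl in seq_len(Nsl)) {
    zv <- Z$value[pat_of_slice[sl], ]
    y[, , , sl] <- rep(zv, each = h * w)
  }
  nd <- node_new(tape, y)
  nd$backward <- function(g) {
    gz <- matrix(0, nrow(Z$value), D)
    for (sl in seq_len(Nsl)) {
      p <- pat_of_slice[sl]
      gz[p, ] <- gz[p, ] + colSums(matrix(g[, , , sl], nrow = h * w))
    }
    acc_grad(Z, gz)
  }
  nd
}

# (h, w, C, N) -> token matrix (S*N x C), rows grouped in N blocks of
# S = h*w tokens
op_tokens <- function(tape, x) {
  d <- dim(x$value)
  S <- d[1] * d[2]
  xs <- array(x$value, c(S, d[3], d[4]))
  M <- matrix(aperm(xs, c(1, 3, 2)), nrow = S * d[4], ncol = d[3])
  nd <- node_new(tape, M)
  nd$S <- S; nd$N <- d[4]
  nd$backward <- function(g) {
    ga <- aperm(array(g, c(S, d[4], d[3])), c(1, 3, 2))
    acc_grad(x, array(ga, d))
  }
  nd
}

op_linear <- function(tape, X, W, b = NULL) {
  y <- X$value %*% W$value
  if (!is.null(b)) y <- sweep(y, 2, b$value, `+`)
  nd <- node_new(tape, y)
  nd$backward <- function(g) {
    acc_grad(X, g %*% t(W$value))
    acc_grad(W, crossprod(X$value, g))
    if (!is.null(b)) acc_grad(b, colSums(g))
  }
  nd
}

# add a learned positional embedding P (S x d) to each block of S rows
op_pos_add <- function(tape, X, P, S, N) {
  rep_idx <- rep(seq_len(S), N)
  nd <- node_new(tape, X$value + P$value[rep_idx, , drop = FALSE])
  nd$backward <- function(g) {
    acc_grad(X, g)
    if (!isTRUE(P$frozen))
      acc_grad(P, rowsum(g, rep_idx, reorder = TRUE))
  }
  nd
}

op_layernorm <- function(tape, X, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(X$value)
  xc <- X$value - mu
  v <- rowMeans(xc * xc)
  invstd <- 1 / sqrt(v + eps)
  xhat <- xc * invstd
  y <- sweep(sweep(xhat, 2, gamma$value, `*`), 2, beta$value, `+`)
  d <- ncol(X$value)
  nd <- node_new(tape, y)
  nd$backward <- function(g) {
    gg <- sweep(g, 2, gamma$value, `*`)
    s1 <- rowSums(gg)
    s2 <- rowSums(gg * xhat)
    dx <- invstd * (gg - (s1 + xhat * s2) / d)
    acc_grad(X, dx)
    acc_grad(gamma, colSums(g * xhat))
    acc_grad(beta, colSums(g))
  }
  nd
}

softmax_rows <- function(M) {
  M <- M - apply(M, 1, max)
  E <- exp(M)
  E / rowSums(E)
}

# multi-head self-attention over N independent blocks of S tokens.
# X: (S*N x d). Projections Wqkv (d x 3d), Wo (d x d).
op_mha <- function(tape, X, Wqkv, bqkv, Wo, bo, n_heads, S, N) {
  d <- ncol(X$value)
  dh <- d %/% n_heads
  QKV <- sweep(X$value %*% Wqkv$value, 2, bqkv$value, `+`)
  Q <- QKV[, 1:d, drop = FALSE]
  K <- QKV[, d + 1:d, drop = FALSE]
  V <- QKV[, 2 * d + 1:d, drop = FALSE]
  O <- matrix(0, S * N, d)
  A_cache <- vector("list", N)
  scale <- 1 / sqrt(dh)
  for (n in seq_len(N)) {
    rows <- (n - 1) * S + seq_len(S)
    An <- vector("list", n_heads)
    for (h in seq_len(n_heads)) {
      cols <- (h - 1) * dh + seq_len(dh)
      q <- Q[rows, cols, drop = FALSE]
      k <- K[rows, cols, drop = FALSE]
      v <- V[rows, cols, drop = FALSE]
      A <- softmax_rows(tcrossprod(q, k) * scale)
      O[rows, cols] <- A %*% v
      An[[h]] <- A
    }
    A_cache[[n]] <- An
  }
  Y <- sweep(O %*% Wo$value, 2, bo$value, `+`)
  nd <- node_new(tape, Y)
  nd$backward <- function(g) {
    gO <- g %*% t(Wo$value)
    acc_grad(Wo, crossprod(O, g))
    acc_grad(bo, colSums(g))
    gQ <- matrix(0, S * N, d); gK <- gQ; gV <- gQ
    for (n in seq_len(N)) {
      rows <- (n - 1) * S + seq_len(S)
      for (h in seq_len(n_heads)) {
        cols <- (h - 1) * dh + seq_len(dh)
        A <- A_cache[[n]][[h]]
        q <- Q[rows, cols, drop = FALSE]
        k <- K[rows, cols, drop = FALSE]
        v <- V[rows, cols, drop = FALSE]
        go <- gO[rows, cols, drop = FALSE]
        gA <- tcrossprod(go, v)
        gV[rows, cols] <- crossprod(A, go)
        # softmax backward per row
        gS <- A * (gA - rowSums(gA * A))
        gQ[rows, cols] <- gS %*% k * scale
        gK[rows, cols] <- crossprod(gS, q) * scale
      }
    }
    gQKV <- cbind(gQ, gK, gV)
    acc_grad(X, gQKV %*% t(Wqkv$value))
    acc_grad(Wqkv, crossprod(X$value, gQKV))
    acc_grad(bqkv, colSums(gQKV))
  }
  nd
}

op_dropout <- function(tape, x, p) {
  if (!tape$training || p <= 0) return(x)
  keep <- (array(stats::runif(length(x$value)), dim(x$value) %||%
                   length(x$value)) >= p) / (1 - p)
  nd <- node_new(tape, x$value * keep)
  nd$backward <- function(g) acc_grad(x, g * keep)
  nd
}

# mean over each block of S token rows -> (N x d)
op_token_mean <- function(tape, X, S, N) {
  grp <- rep(seq_len(N), each = S)
  nd <- node_new(tape, rowsum(X$value, grp, reorder = TRUE) / S)
  nd$backward <- function(g)
    acc_grad(X, g[grp, , drop = FALSE] / S)
  nd
}

# elementwise multiply by a constant mask (used to zero padding positions)
op_mask <- function(tape, x, mask) {
  nd <- node_new(tape, x$value * mask)
  nd$backward <- function(g) acc_grad(x, g * mask)
  nd
}

op_transpose <- function(tape, x) {
  nd <- node_new(tape, t(x$value))
  nd$backward <- function(g) acc_grad(x, t(g))
  nd
}

op_reshape <- function(tape, x, new_dim) {
  old <- dim(x$value) %||% length(x$value)
  nd <- node_new(tape, array(x$value, new_dim))
  nd$backward <- function(g) acc_grad(x, array(g, old))
  nd
}

# fused sigmoid + binary cross-entropy on logits (numerically stable);
# prediction probabilities are exposed as an attribute of the value
op_sigmoid_bce <- function(tape, logits, y, eps = 1e-7, weights = NULL) {
  z <- as.numeric(logits$value)
  p <- 1 / (1 + exp(-z))
  pc <- pmin(pmax(p, eps), 1 - eps)
  if (is.null(weights)) weights <- rep(1, length(y))
  wsum <- sum(weights)
  loss <- -sum(weights * (y * log(pc) + (1 - y) * log(1 - pc))) / wsum
  nd <- node_new(tape, loss)
  nd$probs <- p
  nd$backward <- function(g) {
    gl <- g * weights * (p - y) / wsum
    acc_grad(logits, array(gl, dim(logits$value)))
  }
  nd
}
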