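# Reverse-mode autodiff tape over dense 4-d tensors, dim = c(C, H, W, N).
#
# Channels vary fastest in memory, so per-channel vectors (biases, batch-norm
# scales) broadcast along C by plain R recycling. Nodes are environments; ids
# increase with creation order, which makes decreasing id a valid topological
# order for the backward sweep.

.ad_state <- new.env(parent = emptyenv())
.ad_state$id <- 0L

ad_node <- function(val, parents = list(), backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$val <- val
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  .ad_state$id <- .ad_state$id + 1L
  node$id <- .ad_state$id
  class(node) <- "ad_tensor"
  node
}

#' @keywords internal
ad_leaf <- function(val) ad_node(val)

is_ad <- function(x) inherits(x, "ad_tensor")
ad_val <- function(x) if (is_ad(x)) x$val else x

.acc_grad <- function(node, g) {
  if (is.null(g) || !is_ad(node)) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Backward sweep from a scalar (or supplied seed gradient).
ad_backward <- function(root, seed = NULL) {
  if (is.null(seed)) {
    seed <- ad_val(root)
    seed[] <- 1
  }
  root$grad <- seed
  # collect reachable nodes
  seen <- new.env(parent = emptyenv())
  stack <- list(root)
  nodes <- list()
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- nd
    for (p in nd$parents) if (is_ad(p)) stack[[length(stack) + 1L]] <- p
  }
  ids <- vapply(nodes, function(n) n$id, integer(1))
  for (nd in nodes[order(ids, decreasing = TRUE)]) {
    if (is.null(nd$backward) || is.null(nd$grad)) next
    gs <- nd$backward(nd$grad)
    for (i in seq_along(nd$parents)) .acc_grad(nd$parents[[i]], gs[[i]])
  }
  invisible(root)
}

# ---- broadcasting helpers ----------------------------------------------------

.expand_to <- function(x, d) {
  dx <- dim(x)
  if (is.null(dx)) return(array(x, d))
  if (identical(as.integer(dx), as.integer(d))) return(x)
  idx <- lapply(seq_along(d), function(k) {
    if (dx[k] == d[k]) seq_len(d[k]) else rep(1L, d[k])
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

.reduce_axis <- function(g, k) {
  d <- dim(g)
  nd <- length(d)
  others <- setdiff(seq_len(nd), k)
  s <- colSums(aperm(g, c(k, others)))
  out <- array(s, c(d[others], 1L))
  aperm(out, match(seq_len(nd), c(others, k)))
}

.reduce_to <- function(g, d) {
  if (is.null(d)) return(sum(g))
  dg <- dim(g)
  if (identical(as.integer(dg), as.integer(d))) return(g)
  for (k in seq_along(d)) {
    if (d[k] == 1L && dim(g)[k] > 1L) g <- .reduce_axis(g, k)
  }
  g
}

.common_dim <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  if (is.null(da)) return(db)
  if (is.null(db)) return(da)
  pmax(da, db)
}

# ---- elementwise ops ---------------------------------------------------------

ad_add <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  d <- .common_dim(av, bv)
  val <- if (is.null(d)) av + bv else .expand_to(av, d) + .expand_to(bv, d)
  ad_node(val, list(a, b), function(gy) {
    list(.reduce_to(gy, dim(av)), .reduce_to(gy, dim(bv)))
  })
}

ad_mul <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  d <- .common_dim(av, bv)
  if (is.null(d)) {
    return(ad_node(av * bv, list(a, b), function(gy) list(gy * bv, gy * av)))
  }
  ea <- .expand_to(av, d); eb <- .expand_to(bv, d)
  ad_node(ea * eb, list(a, b), function(gy) {
    list(.reduce_to(gy * eb, dim(av)), .reduce_to(gy * ea, dim(bv)))
  })
}

ad_scale <- function(a, k) {
  ad_node(ad_val(a) * k, list(a), function(gy) list(gy * k))
}

ad_relu <- function(a) {
  av <- ad_val(a)
  mask <- av > 0
  ad_node(av * mask, list(a), function(gy) list(gy * mask))
}

ad_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-ad_val(a)))
  ad_node(y, list(a), function(gy) list(gy * y * (1 - y)))
}

ad_sum <- function(a) {
  av <- ad_val(a)
  ad_node(sum(av), list(a), function(gy) {
    g <- av
    g[] <- gy
    list(g)
  })
}

# scalar division (used by the soft Dice ratio)
ad_div <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  ad_node(av / bv, list(a, b), function(gy) {
    list(gy / bv, -gy * av / bv^2)
  })
}

# ---- convolutions ------------------------------------------------------------

ad_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, dil = 1L) {
  xv <- ad_val(x); wv <- ad_val(w)
  bv <- if (is.null(b)) numeric(0) else ad_val(b)
  val <- cpp_conv2d(xv, wv, bv, stride, pad, dil)
  kh <- dim(wv)[2]; kw <- dim(wv)[3]
  H <- dim(xv)[2]; W <- dim(xv)[3]
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ad_node(val, parents, function(gy) {
    gx <- cpp_conv2d_bwd_input(gy, wv, H, W, stride, pad, dil)
    gw <- cpp_conv2d_bwd_weight(xv, gy, kh, kw, stride, pad, dil)
    if (is.null(b)) list(gx, gw)
    else list(gx, gw, rowSums(matrix(gy, nrow = dim(gy)[1])))
  })
}

# Transposed convolution: weight dim c(Cout, kh, kw, Cin); forward is the
# adjoint of a stride-s convolution mapping the output grid back to the input.
ad_tconv2d <- function(x, w, b = NULL, stride = 2L, pad = 1L, outpad = 1L) {
  xv <- ad_val(x); wv <- ad_val(w)
  dm <- dim(xv)
  kh <- dim(wv)[2]; kw <- dim(wv)[3]
  Ho <- (dm[2] - 1L) * stride - 2L * pad + kh + outpad
  Wo <- (dm[3] - 1L) * stride - 2L * pad + kw + outpad
  val <- cpp_conv2d_bwd_input(xv, wv, Ho, Wo, stride, pad, 1L)
  if (!is.null(b)) val <- val + as.vector(ad_val(b))  # recycles along C
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ad_node(val, parents, function(gy) {
    gx <- cpp_conv2d(gy, wv, numeric(0), stride, pad, 1L)
    gw <- cpp_conv2d_bwd_weight(gy, xv, kh, kw, stride, pad, 1L)
    if (is.null(b)) list(gx, gw)
    else list(gx, gw, rowSums(matrix(gy, nrow = dim(gy)[1])))
  })
}

# ---- pooling / resize --------------------------------------------------------

ad_maxpool <- function(x, k, s = k) {
  xv <- ad_val(x)
  k <- min(k, dim(xv)[2], dim(xv)[3])
  res <- cpp_maxpool(xv, k, s)
  H <- dim(xv)[2]; W <- dim(xv)[3]
  ad_node(res$y, list(x), function(gy) list(cpp_maxpool_bwd(gy, res$idx, H, W)))
}

ad_gmaxpool <- function(x) {
  xv <- ad_val(x)
  d <- dim(xv)
  S <- d[2] * d[3]
  m <- array(xv, c(d[1], S, d[4]))
  val <- apply(m, c(1, 3), max)
  idx <- apply(m, c(1, 3), which.max)
  ad_node(array(val, c(d[1], 1L, 1L, d[4])), list(x), function(gy) {
    gx <- numeric(length(xv))
    ci <- rep(seq_len(d[1]), times = d[4])
    ni <- rep(seq_len(d[4]), each = d[1])
    flat <- ci + d[1] * ((as.vector(idx) - 1) + S * (ni - 1))
    gx[flat] <- as.vector(gy)
    dim(gx) <- d
    list(gx)
  })
}

ad_gavgpool <- function(x) {
  xv <- ad_val(x)
  d <- dim(xv)
  S <- d[2] * d[3]
  m <- array(xv, c(d[1], S, d[4]))
  val <- apply(m, c(1, 3), mean)
  ad_node(array(val, c(d[1], 1L, 1L, d[4])), list(x), function(gy) {
    list(.expand_to(gy / S, d))
  })
}

ad_resize_bilinear <- function(x, Ho, Wo) {
  xv <- ad_val(x)
  H <- dim(xv)[2]; W <- dim(xv)[3]
  if (H == Ho && W == Wo) return(ad_node(xv, list(x), function(gy) list(gy)))
  ad_node(cpp_resize_bilinear(xv, Ho, Wo), list(x), function(gy) {
    list(cpp_resize_bilinear_bwd(gy, H, W))
  })
}

# ---- channel-axis statistics -------------------------------------------------

ad_cmax <- function(x) {
  xv <- ad_val(x)
  d <- dim(xv)
  C <- d[1]; L <- d[2] * d[3] * d[4]
  m <- matrix(xv, nrow = C)
  idx <- max.col(t(m), ties.method = "first")
  val <- m[(seq_len(L) - 1L) * C + idx]
  ad_node(array(val, c(1L, d[2], d[3], d[4])), list(x), function(gy) {
    gx <- numeric(length(xv))
    gx[(seq_len(L) - 1L) * C + idx] <- as.vector(gy)
    dim(gx) <- d
    list(gx)
  })
}

ad_cmean <- function(x) {
  xv <- ad_val(x)
  d <- dim(xv)
  C <- d[1]
  val <- colMeans(matrix(xv, nrow = C))
  ad_node(array(val, c(1L, d[2], d[3], d[4])), list(x), function(gy) {
    gx <- rep(as.vector(gy) / C, each = C)
    dim(gx) <- d
    list(gx)
  })
}

# Mode statistic is piecewise constant; treated as a constant in the backward
# sweep (no gradient flows through it).
ad_cmode <- function(x, bins) {
  ad_node(cpp_channel_mode(ad_val(x), bins))
}

# Softmax over all H*W positions, per sample; input dim c(1, H, W, N).
ad_softmax_hw <- function(x) {
  xv <- ad_val(x)
  d <- dim(xv)
  stopifnot(d[1] == 1L)
  m <- matrix(xv, nrow = d[2] * d[3], ncol = d[4])
  m <- sweep(m, 2, apply(m, 2, max))
  e <- exp(m)
  p <- sweep(e, 2, colSums(e), "/")
  ad_node(array(p, d), list(x), function(gy) {
    gm <- matrix(gy, nrow = d[2] * d[3], ncol = d[4])
    dot <- colSums(gm * p)
    gx <- p * sweep(gm, 2, dot)
    dim(gx) <- d
    list(gx)
  })
}

# ---- channel concatenation ---------------------------------------------------

ad_concat_c <- function(xs) {
  vals <- lapply(xs, ad_val)
  Cs <- vapply(vals, function(v) dim(v)[1], integer(1))
  d1 <- dim(vals[[1]])
  val <- array(0, c(sum(Cs), d1[2], d1[3], d1[4]))
  off <- 0L
  for (v in vals) {
    val[off + seq_len(dim(v)[1]), , , ] <- v
    off <- off + dim(v)[1]
  }
  ad_node(val, xs, function(gy) {
    out <- vector("list", length(xs))
    off <- 0L
    for (i in seq_along(xs)) {
      out[[i]] <- gy[off + seq_len(Cs[i]), , , , drop = FALSE]
      off <- off + Cs[i]
    }
    out
  })
}

# ---- batch normalization -----------------------------------------------------

# state is an environment; running moments live under <name>.mean / <name>.var.
ad_batchnorm <- function(x, gamma, beta, state, name, training,
                         momentum = 0.1, eps = 1e-5) {
  xv <- ad_val(x)
  d <- dim(xv)
  C <- d[1]
  gv <- as.vector(ad_val(gamma))
  bv <- as.vector(ad_val(beta))
  if (training) {
    mu <- rowMeans(matrix(xv, nrow = C))
    v <- rowMeans(matrix(xv * xv, nrow = C)) - mu^2
    v <- pmax(v, 0)
    km <- paste0(name, ".mean"); kv <- paste0(name, ".var")
    state[[km]] <- if (is.null(state[[km]])) mu else (1 - momentum) * state[[km]] + momentum * mu
    state[[kv]] <- if (is.null(state[[kv]])) v else (1 - momentum) * state[[kv]] + momentum * v
  } else {
    mu <- state[[paste0(name, ".mean")]]
    v <- state[[paste0(name, ".var")]]
    if (is.null(mu)) { mu <- numeric(C); v <- rep(1, C) }
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (xv - mu) * inv  # recycles along C
  val <- xhat * gv + bv
  m <- prod(d[-1])
  ad_node(val, list(x, gamma, beta), function(gy) {
    ggamma <- rowSums(matrix(gy * xhat, nrow = C))
    gbeta <- rowSums(matrix(gy, nrow = C))
    dxhat <- gy * gv
    if (training) {
      mdx <- rowMeans(matrix(dxhat, nrow = C))
      mdxx <- rowMeans(matrix(dxhat * xhat, nrow = C))
      gx <- (dxhat - mdx - xhat * mdxx) * inv
    } else {
      gx <- dxhat * inv
    }
    list(gx, ggamma, gbeta)
  })
}
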