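#' @useDynLib mcigate, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Minimal reverse-mode automatic differentiation.
#
# A node is a mutable environment holding `val` (an R array), the list of
# parent nodes it was computed from, and a `backward` closure mapping the
# gradient at this node to the list of gradients for its parents. Feature
# maps are column-major arrays of shape (D, H, W, C, B); the network code
# builds a fresh graph on every forward pass while parameter nodes persist.
# ---------------------------------------------------------------------------

ag_node <- function(val, parents = list(), backward = NULL, name = NULL) {
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$parents <- parents
  e$backward <- backward
  e$grad <- NULL
  e$name <- name
  class(e) <- "ag_node"
  e
}

ag_leaf <- function(val, name = NULL) ag_node(val, name = name)

is_ag_node <- function(x) inherits(x, "ag_node")

# Topological order via iterative depth-first search (leaves first).
ag_topo <- function(root) {
  order <- list()
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    id <- format.default(node)   # environment identity string
    if (top$stage == 1L) {
      if (!is.null(seen[[id]])) next
      seen[[id]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        pid <- format.default(p)
        if (is.null(seen[[pid]]))
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
      }
    } else {
      order[[length(order) + 1L]] <- node
    }
  }
  order
}

# Backpropagate from `root`; afterwards every reachable node carries $grad.
ag_backward <- function(root, seed_grad = NULL) {
  order <- ag_topo(root)
  for (n in order) n$grad <- NULL
  if (is.null(seed_grad)) seed_grad <- array(1, dim = dim_or_len(root$val))
  root$grad <- seed_grad
  for (i in rev(seq_along(order))) {
    n <- order[[i]]
    if (is.null(n$grad) || is.null(n$backward)) next
    gs <- n$backward(n$grad)
    for (j in seq_along(n$parents)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- n$parents[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)

as_dim5 <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 5L)
  x
}

# --- elementwise and structural ops ----------------------------------------

op_add <- function(a, b) {
  ag_node(a$val + b$val, list(a, b), function(g) list(g, g))
}

op_relu <- function(a) {
  val <- cpp_relu_fwd(a$val)
  ag_node(val, list(a), function(g) list(cpp_relu_bwd(g, val)))
}

op_scale <- function(a, s) {
  ag_node(a$val * s, list(a), function(g) list(g * s))
}

# Add a per-channel bias vector to a (D,H,W,C,B) map.
op_bias_channel <- function(a, bias) {
  d <- dim(a$val)
  P <- prod(d[1:3]); C <- d[4]; B <- d[5]
  val <- cpp_col_scale_shift(a$val, P, rep(1, C * B), rep(bias$val, times = B))
  ag_node(val, list(a, bias), function(g) {
    gm <- g
    dim(gm) <- c(P, C * B)
    gb <- rowSums(matrix(.colSums(gm, P, C * B), C, B))
    list(g, gb)
  })
}

# Multiply a 1-channel spatial map alpha (D,H,W,1,B) into every channel of x.
op_gate <- function(x, alpha) {
  d <- dim(x$val)
  P <- prod(d[1:3]); C <- d[4]; B <- d[5]
  val <- cpp_gate_fwd(x$val, alpha$val, P, C, B)
  ag_node(val, list(x, alpha), function(g) {
    gr <- cpp_gate_bwd(g, x$val, alpha$val, P, C, B)
    ga <- gr$galpha
    dim(ga) <- dim(alpha$val)
    list(gr$gx, ga)
  })
}

op_concat_channels <- function(nodes) {
  dims <- lapply(nodes, function(n) dim(n$val))
  chans <- vapply(dims, `[`, integer(1), 4L)
  d <- dims[[1]]
  d[4] <- sum(chans)
  val <- array(0, dim = d)
  hi <- cumsum(chans)
  lo <- hi - chans + 1L
  for (i in seq_along(nodes)) val[, , , lo[i]:hi[i], ] <- nodes[[i]]$val
  ag_node(val, nodes, function(g) {
    lapply(seq_along(nodes), function(i) g[, , , lo[i]:hi[i], , drop = FALSE])
  })
}

# --- compiled-kernel ops ---------------------------------------------------

op_conv3d <- function(x, w, b, stride = c(1L, 1L, 1L), dilation = c(1L, 1L, 1L),
                      pad = NULL) {
  kd <- dim(w$val)[1:3]
  if (is.null(pad)) {  # "same" padding for stride 1; halves dims at stride 2
    eff <- kd + (kd - 1L) * (dilation - 1L)
    pad <- (eff - 1L) %/% 2L
  }
  stride <- as.integer(stride); dilation <- as.integer(dilation)
  pad <- as.integer(pad)
  val <- cpp_conv3d_fwd(x$val, w$val, b$val, stride, dilation, pad)
  ag_node(val, list(x, w, b), function(g) {
    gr <- cpp_conv3d_bwd(x$val, w$val, g, stride, dilation, pad)
    list(gr$gx, gr$gw, gr$gb)
  })
}

op_maxpool <- function(x, ksize = c(2L, 2L, 2L), stride = ksize) {
  fw <- cpp_maxpool3d_fwd(x$val, as.integer(ksize), as.integer(stride))
  xdim <- dim(x$val)
  ag_node(fw$y, list(x), function(g) {
    list(cpp_maxpool3d_bwd(g, fw$argmax, as.integer(xdim)))
  })
}

op_adaptive_avgpool <- function(x, out_grid) {
  xdim <- dim(x$val)
  if (all(xdim[1:3] == out_grid)) return(x)
  val <- cpp_adapool3d_fwd(x$val, as.integer(out_grid))
  ag_node(val, list(x), function(g) list(cpp_adapool3d_bwd(g, as.integer(xdim))))
}

op_resize_trilinear <- function(x, out_grid) {
  xdim <- dim(x$val)
  if (all(xdim[1:3] == out_grid)) return(x)
  val <- cpp_resize3d_fwd(x$val, as.integer(out_grid))
  ag_node(val, list(x), function(g) list(cpp_resize3d_bwd(g, as.integer(xdim))))
}

# Global average pool (D,H,W,C,B) -> (B,C) matrix.
op_gap <- function(x) {
  d <- dim(x$val)
  nvox <- prod(d[1:3])
  m <- apply(x$val, c(5, 4), mean)            # B x C
  dim(m) <- c(d[5], d[4])
  ag_node(m, list(x), function(g) {
    gx <- array(0, dim = d)
    for (bb in seq_len(d[5]))
      for (c in seq_len(d[4]))
        gx[, , , c, bb] <- g[bb, c] / nvox
    list(gx)
  })
}

# Fully connected: (B,Cin) x (Cin,Cout) + bias.
op_linear <- function(x, w, b) {
  val <- x$val %*% w$val + matrix(b$val, nrow(x$val), length(b$val), byrow = TRUE)
  ag_node(val, list(x, w, b), function(g) {
    list(g %*% t(w$val), t(x$val) %*% g, colSums(g))
  })
}

# Softmax over the flattened spatial positions of a 1-channel map, per sample.
op_softmax_spatial <- function(q) {
  d <- dim(q$val)
  stopifnot(d[4] == 1L)
  P <- prod(d[1:3])
  m <- matrix(q$val, P, d[5])
  m <- sweep(m, 2, apply(m, 2, max))
  e <- exp(m)
  a <- sweep(e, 2, colSums(e), "/")
  val <- array(a, dim = d)
  ag_node(val, list(q), function(g) {
    gm <- matrix(g, P, d[5])
    dot <- colSums(gm * a)
    gq <- a * sweep(gm, 2, dot)
    list(array(gq, dim = d))
  })
}

op_sigmoid <- function(q) {
  s <- 1 / (1 + exp(-q$val))
  ag_node(s, list(q), function(g) list(g * s * (1 - s)))
}

# Batch normalization over (spatial x batch) per channel. `state` is a
# mutable environment carrying running_mean / running_var for eval mode.
# Works on the (P, C*B) reshape (columns ordered channel-fastest) to avoid
# permuting the big arrays.
op_batchnorm <- function(x, gamma, beta, state, training, momentum = 0.1,
                         eps = 1e-5) {
  d <- dim(x$val)
  P <- prod(d[1:3]); C <- d[4]; B <- d[5]
  n <- P * B
  xm <- x$val
  dim(xm) <- c(P, C * B)
  chan_sum <- function(v) rowSums(matrix(v, C, B))   # aggregate per channel
  if (training) {
    mu <- chan_sum(.colMeans(xm, P, C * B)) / B
    m2 <- chan_sum(.colMeans(xm * xm, P, C * B)) / B
    v <- pmax(m2 - mu^2, 0)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var +
      momentum * v * n / max(1, n - 1)
  } else {
    mu <- state$running_mean
    v <- state$running_var
  }
  inv <- 1 / sqrt(v + eps)
  sc <- rep(gamma$val * inv, times = B)
  off <- rep(beta$val - gamma$val * inv * mu, times = B)
  val <- cpp_col_scale_shift(x$val, P, sc, off)
  ag_node(val, list(x, gamma, beta), function(g) {
    xhat <- cpp_col_scale_shift(x$val, P, rep(inv, times = B),
                                rep(-mu * inv, times = B))
    ggamma <- chan_sum(.colSums(g * xhat, P, C * B))
    gbeta <- chan_sum(.colSums(g, P, C * B))
    if (training) {
      gx <- cpp_bn_bwd_fused(g, xhat, P, rep(gbeta / n, times = B),
                             rep(ggamma / n, times = B), sc)
    } else {
      gx <- cpp_bn_bwd_fused(g, xhat, P, rep(0, C * B), rep(0, C * B), sc)
    }
    list(gx, ggamma, gbeta)
  })
}

# Mean cross-entropy of two-class scores (B x 2) against labels in {0,1}.
op_cross_entropy <- function(scores, labels) {
  s <- scores$val
  B <- nrow(s)
  m <- apply(s, 1, max)
  e <- exp(s - m)
  p <- e / rowSums(e)
  idx <- cbind(seq_len(B), labels + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  ag_node(loss, list(scores), function(g) {
    gs <- p
    gs[idx] <- gs[idx] - 1
    list(gs * (as.numeric(g) / B))
  })
}

softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}
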