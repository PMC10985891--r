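# A minimal reverse-mode tape over (H, W, C, N) tensors. Forward calls append
# nodes in topological order; backward() walks the list in reverse, each node
# routing its accumulated gradient to its parents and to layer parameters.
# Only the operations the segmentation network needs are implemented.

new_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t
}

tape_push <- function(tape, value, parents = list(), backward = NULL, cache = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  node$cache <- cache
  tape$nodes[[length(tape$nodes) + 1L]] <- node
  node
}

acc_grad <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

tape_backward <- function(tape, out_node, out_grad) {
  acc_grad(out_node, out_grad)
  for (i in rev(seq_along(tape$nodes))) {
    node <- tape$nodes[[i]]
    if (!is.null(node$grad) && !is.null(node$backward)) {
      node$backward(node, node$grad)
      node$grad <- NULL  # release memory as we go; leaf grads are kept
    }
  }
  invisible(NULL)
}

op_input <- function(tape, value) tape_push(tape, as_tensor4(value))

op_conv <- function(tape, x, layer) {
  y <- .conv2d_fwd(x$value, layer$w, layer$b, layer$stride, layer$dil, layer$pad)
  tape_push(tape, y, list(x), backward = function(node, g) {
    r <- .conv2d_bwd(node$parents[[1]]$value, layer$w, g, layer$stride, layer$dil, layer$pad)
    layer$gw <- layer$gw + r$gw
    layer$gb <- layer$gb + r$gb
    acc_grad(node$parents[[1]], r$gx)
  })
}

op_relu <- function(tape, x) {
  v <- x$value
  mask <- v > 0
  v[!mask] <- 0
  tape_push(tape, v, list(x), backward = function(node, g) {
    g[!mask] <- 0
    acc_grad(node$parents[[1]], g)
  })
}

op_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  tape_push(tape, s, list(x), backward = function(node, g) {
    acc_grad(node$parents[[1]], g * s * (1 - s))
  })
}

op_add <- function(tape, a, b) {
  tape_push(tape, a$value + b$value, list(a, b), backward = function(node, g) {
    acc_grad(node$parents[[1]], g)
    acc_grad(node$parents[[2]], g)
  })
}

op_concat <- function(tape, nodes) {
  d <- dim(nodes[[1]]$value)
  chans <- vapply(nodes, function(n) dim(n$value)[3], integer(1))
  out <- array(0, c(d[1], d[2], sum(chans), d[4]))
  at <- 0L
  for (i in seq_along(nodes)) {
    out[, , at + seq_len(chans[i]), ] <- nodes[[i]]$value
    at <- at + chans[i]
  }
  tape_push(tape, out, nodes, backward = function(node, g) {
    at <- 0L
    for (i in seq_along(node$parents)) {
      acc_grad(node$parents[[i]], g[, , at + seq_len(chans[i]), , drop = FALSE])
      at <- at + chans[i]
    }
  })
}

# Batch normalization over (H, W, N) per channel. Biased batch variance, as is
# conventional; running statistics updated with momentum when training.
op_bn <- function(tape, x, layer, training) {
  d <- dim(x$value)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  m <- H * W * N
  xp <- aperm(x$value, c(1, 2, 4, 3))
  dim(xp) <- c(m, C)
  if (training) {
    mu <- colMeans(xp)
    va <- colMeans(xp * xp) - mu^2
    layer$running_mean <- (1 - layer$momentum) * layer$running_mean + layer$momentum * mu
    layer$running_var <- (1 - layer$momentum) * layer$running_var + layer$momentum * va
  } else {
    mu <- layer$running_mean
    va <- layer$running_var
  }
  inv_std <- 1 / sqrt(va + layer$eps)
  xhat <- sweep(xp, 2, mu, "-")
  xhat <- sweep(xhat, 2, inv_std, "*")
  yp <- sweep(xhat, 2, layer$gamma, "*")
  yp <- sweep(yp, 2, layer$beta, "+")
  dim(yp) <- c(H, W, N, C)
  y <- aperm(yp, c(1, 2, 4, 3))
  tape_push(tape, y, list(x), backward = function(node, g) {
    gp <- aperm(g, c(1, 2, 4, 3))
    dim(gp) <- c(m, C)
    layer$ggamma <- layer$ggamma + colSums(gp * xhat)
    layer$gbeta <- layer$gbeta + colSums(gp)
    dxhat <- sweep(gp, 2, layer$gamma, "*")
    if (training) {
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * xhat)
      gx <- sweep(dxhat, 2, s1 / m, "-") - sweep(xhat, 2, s2 / m, "*")
      gx <- sweep(gx, 2, inv_std, "*")
    } else {
      gx <- sweep(dxhat, 2, inv_std, "*")
    }
    dim(gx) <- c(H, W, N, C)
    acc_grad(node$parents[[1]], aperm(gx, c(1, 2, 4, 3)))
  })
}

# Channel-wise mean pooling: (H,W,C,N) -> (H,W,1,N).
op_chan_mean <- function(tape, x) {
  d <- dim(x$value)
  a <- x$value
  dim(a) <- c(d[1] * d[2], d[3], d[4])
  out <- array(0, c(d[1], d[2], 1L, d[4]))
  for (n in seq_len(d[4])) out[, , 1, n] <- rowMeans(a[, , n, drop = FALSE][, , 1])
  tape_push(tape, out, list(x), backward = function(node, g) {
    acc_grad(node$parents[[1]], g[, , rep(1L, d[3]), , drop = FALSE] / d[3])
  })
}

# Channel-wise max pooling with argmax routing for the backward pass.
op_chan_max <- function(tape, x) {
  d <- dim(x$value)
  a <- x$value
  dim(a) <- c(d[1] * d[2], d[3], d[4])
  out <- array(0, c(d[1], d[2], 1L, d[4]))
  idx <- matrix(0L, d[1] * d[2], d[4])
  for (n in seq_len(d[4])) {
    mslice <- a[, , n, drop = FALSE][, , 1, drop = TRUE]
    if (d[3] == 1L) mslice <- matrix(mslice, ncol = 1L)
    w <- max.col(mslice, ties.method = "first")
    idx[, n] <- w
    out[, , 1, n] <- mslice[cbind(seq_len(d[1] * d[2]), w)]
  }
  tape_push(tape, out, list(x), backward = function(node, g) {
    gx <- array(0, d)
    dim(gx) <- c(d[1] * d[2], d[3], d[4])
    gflat <- g
    dim(gflat) <- c(d[1] * d[2], d[4])
    for (n in seq_len(d[4]))
      gx[cbind(seq_len(d[1] * d[2]), idx[, n], n)] <- gflat[, n]
    dim(gx) <- d
    acc_grad(node$parents[[1]], gx)
  })
}

# Broadcast-multiply a feature (H,W,C,N) by a one-channel map (H,W,1,N).
op_mul_map <- function(tape, feature, map) {
  d <- dim(feature$value)
  mb <- map$value[, , rep(1L, d[3]), , drop = FALSE]
  tape_push(tape, feature$value * mb, list(feature, map), backward = function(node, g) {
    acc_grad(node$parents[[1]], g * mb)
    gm <- g * node$parents[[1]]$value
    dim(gm) <- c(d[1] * d[2], d[3], d[4])
    out <- array(0, c(d[1], d[2], 1L, d[4]))
    for (n in seq_len(d[4])) out[, , 1, n] <- rowSums(gm[, , n, drop = FALSE][, , 1])
    acc_grad(node$parents[[2]], out)
  })
}

op_upsample_bilinear <- function(tape, x, out_h, out_w) {
  d <- dim(x$value)
  y <- .resize_bilinear_fwd(x$value, as.integer(out_h), as.integer(out_w))
  tape_push(tape, y, list(x), backward = function(node, g) {
    acc_grad(node$parents[[1]], .resize_bilinear_bwd(g, d[1], d[2]))
  })
}
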