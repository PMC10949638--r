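# Minimal reverse-mode autodiff for the segmentation networks. There is
# no torch in this stack, so convolutional forward/backward is built from
# im2col/col2im kernels (src/conv_ops.cpp) plus BLAS matrix products.
# Values are numeric arrays in H x W x C layout (single image; batching
# is done by gradient accumulation). A "tape" records nodes in creation
# order; backward walks it in reverse. Parameters are environments with
# $value/$grad plus Adam moments, reused across iterations.

nn_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

nn_node <- function(tp, value, bwd = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$bwd <- bwd
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) length(tp$nodes) <- 2L * tp$n
  tp$nodes[[tp$n]] <- nd
  nd
}

nn_accum <- function(nd, g) {
  if (is.null(nd)) return(invisible(NULL))
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# seed: gradient of the loss w.r.t. root$value
nn_backward <- function(tp, root, seed) {
  root$grad <- seed
  for (i in rev(seq_len(tp$n))) {
    nd <- tp$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$bwd)) nd$bwd(nd)
  }
  invisible(NULL)
}

# ---- parameters ------------------------------------------------------------

nn_param <- function(value, name = "") {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$m <- 0
  p$v <- 0
  p$name <- name
  class(p) <- "nn_param"
  p
}

nn_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

nn_adam_step <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, t = 1, scale = 1) {
  for (p in params) {
    if (is.null(p$grad)) next
    g <- p$grad * scale
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g * g
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(NULL)
}

# He-normal initialised convolution parameters. Weights are stored as a
# (kh*kw*cin) x cout matrix ready for the im2col product.
nn_conv_param <- function(kh, kw, cin, cout, name = "conv") {
  fan_in <- kh * kw * cin
  w <- nn_param(matrix(rnorm(fan_in * cout, 0, sqrt(2 / fan_in)),
                       fan_in, cout), paste0(name, ".w"))
  w$kh <- kh; w$kw <- kw; w$cin <- cin; w$cout <- cout
  b <- nn_param(numeric(cout), paste0(name, ".b"))
  list(w = w, b = b)
}

nn_bn_param <- function(c, name = "bn") {
  list(gamma = nn_param(rep(1, c), paste0(name, ".g")),
       beta = nn_param(numeric(c), paste0(name, ".b")))
}

nn_dense_param <- function(cin, cout, name = "fc") {
  list(w = nn_param(matrix(rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout),
                    paste0(name, ".w")),
       b = nn_param(numeric(cout), paste0(name, ".b")))
}

# ---- ops -------------------------------------------------------------------

op_input <- function(tp, value) {
  nd <- nn_node(tp, value, bwd = NULL)
  nd$stop_grad <- TRUE
  nd
}

op_conv <- function(tp, x, prm, stride = 1L, pad = 1L, dil = 1L) {
  w <- prm$w; b <- prm$b
  d <- dim(x$value)
  cols <- im2col_cpp(as.numeric(x$value), d[1], d[2], d[3],
                     w$kh, w$kw, stride, pad, dil)
  out <- cols %*% w$value
  out <- sweep(out, 2, b$value, `+`)
  ho <- (d[1] + 2 * pad - dil * (w$kh - 1) - 1) %/% stride + 1
  wo <- (d[2] + 2 * pad - dil * (w$kw - 1) - 1) %/% stride + 1
  nd <- nn_node(tp, array(out, c(ho, wo, w$cout)))
  nd$bwd <- function(self) {
    g <- matrix(self$grad, ho * wo, w$cout)
    nn_accum(w, crossprod(cols, g))
    nn_accum(b, colSums(g))
    if (is.null(x$stop_grad)) {
      nn_accum(x, col2im_cpp(tcrossprod(g, w$value), d[1], d[2], d[3],
                             w$kh, w$kw, stride, pad, dil))
    }
  }
  nd
}

op_relu <- function(tp, x) {
  mask <- x$value > 0
  nd <- nn_node(tp, x$value * mask)
  nd$bwd <- function(self) nn_accum(x, self$grad * mask)
  nd
}

op_sigmoid <- function(tp, x) {
  v <- 1 / (1 + exp(-x$value))
  nd <- nn_node(tp, v)
  nd$bwd <- function(self) nn_accum(x, self$grad * v * (1 - v))
  nd
}

op_maxpool2 <- function(tp, x) {
  r <- maxpool2_cpp(as.numeric(x$value), dim(x$value)[1], dim(x$value)[2],
                    dim(x$value)[3])
  nd <- nn_node(tp, r$value)
  nd$bwd <- function(self) {
    dx <- array(0, dim(x$value))
    dx[r$argmax] <- self$grad
    nn_accum(x, dx)
  }
  nd
}

op_upsample_nearest <- function(tp, x, factor = 2L) {
  d <- dim(x$value)
  ri <- rep(seq_len(d[1]), each = factor)
  ci <- rep(seq_len(d[2]), each = factor)
  nd <- nn_node(tp, x$value[ri, ci, , drop = FALSE])
  nd$bwd <- function(self) {
    g <- self$grad
    a <- array(g, c(factor, d[1], factor, d[2], d[3]))
    dx <- colSums(aperm(a, c(1, 3, 2, 4, 5)), dims = 2)
    nn_accum(x, array(dx, d))
  }
  nd
}

op_concat <- function(tp, xs) {
  dims <- lapply(xs, function(x) dim(x$value))
  cs <- vapply(dims, function(d) d[3], numeric(1))
  nd <- nn_node(tp, array(unlist(lapply(xs, function(x) x$value)),
                          c(dims[[1]][1], dims[[1]][2], sum(cs))))
  nd$bwd <- function(self) {
    off <- 0
    for (i in seq_along(xs)) {
      if (is.null(xs[[i]]$stop_grad)) {
        nn_accum(xs[[i]],
                 self$grad[, , off + seq_len(cs[i]), drop = FALSE])
      }
      off <- off + cs[i]
    }
  }
  nd
}

op_add <- function(tp, a, b) {
  nd <- nn_node(tp, a$value + b$value)
  nd$bwd <- function(self) {
    if (is.null(a$stop_grad)) nn_accum(a, self$grad)
    if (is.null(b$stop_grad)) nn_accum(b, self$grad)
  }
  nd
}

# Per-channel normalization over the spatial positions of the single
# image (instance normalization); used wherever an architecture calls for
# batch normalization, which degenerates to this at batch size one.
op_bn <- function(tp, x, prm, eps = 1e-5) {
  d <- dim(x$value)
  n <- d[1] * d[2]
  xm <- matrix(x$value, n, d[3])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  va <- colMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  y <- sweep(sweep(xhat, 2, prm$gamma$value, `*`), 2, prm$beta$value, `+`)
  nd <- nn_node(tp, array(y, d))
  nd$bwd <- function(self) {
    g <- matrix(self$grad, n, d[3])
    nn_accum(prm$beta, colSums(g))
    nn_accum(prm$gamma, colSums(g * xhat))
    if (is.null(x$stop_grad)) {
      gh <- sweep(g, 2, prm$gamma$value, `*`)
      m1 <- colMeans(gh)
      m2 <- colMeans(gh * xhat)
      dx <- sweep(gh, 2, m1) - sweep(xhat, 2, m2, `*`)
      dx <- sweep(dx, 2, istd, `*`)
      nn_accum(x, array(dx, d))
    }
  }
  nd
}

op_global_avg <- function(tp, x) {
  d <- dim(x$value)
  n <- d[1] * d[2]
  nd <- nn_node(tp, colMeans(matrix(x$value, n, d[3])))
  nd$bwd <- function(self) {
    nn_accum(x, array(rep(self$grad / n, each = n), d))
  }
  nd
}

op_dense <- function(tp, x, prm) {
  v <- as.numeric(x$value)
  nd <- nn_node(tp, as.numeric(v %*% prm$w$value) + prm$b$value)
  nd$bwd <- function(self) {
    g <- self$grad
    nn_accum(prm$w, outer(v, g))
    nn_accum(prm$b, g)
    nn_accum(x, as.numeric(prm$w$value %*% g))
  }
  nd
}

op_relu_vec <- function(tp, x) {
  mask <- x$value > 0
  nd <- nn_node(tp, x$value * mask)
  nd$bwd <- function(self) nn_accum(x, self$grad * mask)
  nd
}

op_sigmoid_vec <- op_sigmoid

# x (H x W x C) scaled per channel by vector node s (length C); the
# squeeze-and-excitation recalibration.
op_scale_channels <- function(tp, x, s) {
  d <- dim(x$value)
  sv <- s$value
  nd <- nn_node(tp, sweep(x$value, 3, sv, `*`))
  nd$bwd <- function(self) {
    if (is.null(x$stop_grad)) nn_accum(x, sweep(self$grad, 3, sv, `*`))
    n <- d[1] * d[2]
    nn_accum(s, colSums(matrix(self$grad * x$value, n, d[3])))
  }
  nd
}

# Broadcast a length-C vector node to an H x W x C map.
op_broadcast <- function(tp, s, hw) {
  cvec <- s$value
  nd <- nn_node(tp, array(rep(cvec, each = hw[1] * hw[2]),
                          c(hw[1], hw[2], length(cvec))))
  nd$bwd <- function(self) {
    nn_accum(s, colSums(matrix(self$grad, hw[1] * hw[2], length(cvec))))
  }
  nd
}
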