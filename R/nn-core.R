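# Minimal reverse-mode neural-network layers for the cGAN translators.
#
# Design notes:
# - batch size is fixed at 1 (as in training), so feature maps are plain
#   3-D arrays [H, W, C] and token matrices are [N, D];
# - convolutions are im2col/col2im over precomputed index tables, so the
#   heavy lifting is BLAS matrix multiplication;
# - every layer is an environment with forward(x, training)/backward(dout)
#   and a list of parameter environments (value/grad/Adam state);
# - geometry is resolved at construction time (input shape is part of the
#   layer spec), which keeps the index tables static.

new_param <- function(dim, sd = NULL) {
  n_in <- prod(dim[-length(dim)])
  if (is.null(sd)) sd <- sqrt(2 / max(n_in, 1))
  p <- new.env(parent = emptyenv())
  p$value <- array(stats::rnorm(prod(dim), 0, sd), dim = dim)
  p$grad <- array(0, dim = dim)
  p$m <- array(0, dim = dim)
  p$v <- array(0, dim = dim)
  p
}

zero_param <- function(dim) {
  p <- new_param(dim, sd = 0)
  p
}

pad_hw <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  out
}

unpad_hw <- function(x, p, H, W) {
  if (p == 0) return(x)
  x[p + seq_len(H), p + seq_len(W), , drop = FALSE]
}

# im2col geometry for a conv over an [H, W, C] array.
conv_geom <- function(H, W, C, k, stride, pad) {
  Hp <- H + 2 * pad; Wp <- W + 2 * pad
  if (Hp < k || Wp < k)
    stop("conv kernel larger than padded input: H=", H, " W=", W,
         " k=", k, " pad=", pad)
  # flooring output size (trailing padded rows/cols beyond the last full
  # kernel placement are simply never indexed)
  Ho <- (Hp - k) %/% stride + 1
  Wo <- (Wp - k) %/% stride + 1
  P <- Ho * Wo
  oi <- rep(seq_len(Ho), Wo); oj <- rep(seq_len(Wo), each = Ho)
  base_r <- (oi - 1) * stride
  base_c <- (oj - 1) * stride
  ki <- rep(seq_len(k), times = k * C)
  kj <- rep(rep(seq_len(k), each = k), times = C)
  cc <- rep(seq_len(C), each = k * k)
  idx <- outer(base_r, ki, `+`) +
    outer(base_c, kj - 1, `+`) * Hp +
    matrix((cc - 1) * Hp * Wp, P, k * k * C, byrow = TRUE)
  scat <- Matrix::sparseMatrix(
    i = as.vector(idx), j = seq_len(length(idx)),
    x = 1, dims = c(Hp * Wp * C, length(idx)))
  list(H = H, W = W, C = C, k = k, stride = stride, pad = pad,
       Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, P = P,
       idx = idx, scat = scat)
}

im2col <- function(xp, g) {
  out <- xp[g$idx]
  dim(out) <- c(g$P, g$k * g$k * g$C)
  out
}

col2im <- function(col, g) {
  dim(col) <- NULL
  v <- as.vector(g$scat %*% col)
  dim(v) <- c(g$Hp, g$Wp, g$C)
  v
}

# reshape without the matrix()/array() copy; x must be a local value
reshape2 <- function(x, n, m) { dim(x) <- c(n, m); x }
reshape3 <- function(x, a, b, c) { dim(x) <- c(a, b, c); x }

# add a per-channel bias to [P, C] (columns) or [H, W, C] (3rd margin)
addbias_cols <- function(y, b) y + rep(b, each = nrow(y))
addbias_ch <- function(y, b) {
  d <- dim(y)
  y + rep(b, each = d[1] * d[2])
}
sum_ch <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3])
  colSums(x)
}

#' @noRd
layer_conv2d <- function(H, W, in_ch, out_ch, k = 3, stride = 1, pad = 1) {
  self <- new.env(parent = emptyenv())
  g <- conv_geom(H, W, in_ch, k, stride, pad)
  self$g <- g
  self$W <- new_param(c(k * k * in_ch, out_ch))
  self$b <- zero_param(c(out_ch))
  self$out_shape <- c(g$Ho, g$Wo, out_ch)
  self$params <- list(self$W, self$b)
  self$forward <- function(x, training = TRUE) {
    xp <- pad_hw(x, g$pad)
    self$Xcol <- im2col(xp, g)
    y <- addbias_cols(self$Xcol %*% self$W$value,
                      as.vector(self$b$value))
    reshape3(y, g$Ho, g$Wo, out_ch)
  }
  self$backward <- function(dout) {
    dY <- reshape2(dout, g$P, out_ch)
    self$W$grad <- self$W$grad + crossprod(self$Xcol, dY)
    self$b$grad <- self$b$grad + colSums(dY)
    dXcol <- dY %*% t(self$W$value)
    dxp <- col2im(dXcol, g)
    unpad_hw(dxp, g$pad, g$H, g$W)
  }
  self
}

# Transposed convolution: the adjoint of a conv mapping the (big) output
# back to the (small) input. For k = 4, stride = 2, pad = 1 it exactly
# doubles both spatial dimensions.
#' @noRd
layer_tconv2d <- function(h, w, in_ch, out_ch, k = 4, stride = 2, pad = 1) {
  self <- new.env(parent = emptyenv())
  H <- stride * h + k - 2 * pad - stride   # stride*(h-1) + k - 2*pad
  W <- stride * w + k - 2 * pad - stride
  g <- conv_geom(H, W, out_ch, k, stride, pad)
  stopifnot(g$Ho == h, g$Wo == w)
  self$g <- g
  self$W <- new_param(c(k * k * out_ch, in_ch),
                      sd = sqrt(2 / (k * k * in_ch)))
  self$b <- zero_param(c(out_ch))
  self$out_shape <- c(H, W, out_ch)
  self$params <- list(self$W, self$b)
  self$forward <- function(x, training = TRUE) {
    self$Xmat <- reshape2(x, h * w, in_ch)
    Ycol <- self$Xmat %*% t(self$W$value)
    yp <- col2im(Ycol, g)
    y <- unpad_hw(yp, g$pad, H, W)
    addbias_ch(y, as.vector(self$b$value))
  }
  self$backward <- function(dout) {
    dp <- pad_hw(dout, g$pad)
    Dcol <- im2col(dp, g)
    dX <- Dcol %*% self$W$value
    self$W$grad <- self$W$grad + crossprod(Dcol, self$Xmat)
    self$b$grad <- self$b$grad + sum_ch(dout)
    reshape3(dX, h, w, in_ch)
  }
  self
}

# Batch normalization at batch size 1: moments over the spatial extent per
# channel, with running statistics for inference.
#' @noRd
layer_batchnorm <- function(C, eps = 1e-5, momentum = 0.1) {
  self <- new.env(parent = emptyenv())
  self$gamma <- zero_param(c(C)); self$gamma$value[] <- 1
  self$beta <- zero_param(c(C))
  self$run_mean <- rep(0, C); self$run_var <- rep(1, C)
  self$params <- list(self$gamma, self$beta)
  self$forward <- function(x, training = TRUE) {
    d <- dim(x); N <- d[1] * d[2]
    xm <- reshape2(x, N, d[3])
    if (training) {
      mu <- colMeans(xm)
      xc <- sweep(xm, 2, mu)
      va <- colMeans(xc^2)
      self$run_mean <- (1 - momentum) * self$run_mean + momentum * mu
      self$run_var <- (1 - momentum) * self$run_var + momentum * va
    } else {
      mu <- self$run_mean; va <- self$run_var
      xc <- sweep(xm, 2, mu)
    }
    self$istd <- 1 / sqrt(va + eps)
    self$xhat <- sweep(xc, 2, self$istd, `*`)
    y <- addbias_cols(
      self$xhat * rep(as.vector(self$gamma$value), each = N),
      as.vector(self$beta$value))
    self$training <- training
    reshape3(y, d[1], d[2], d[3])
  }
  self$backward <- function(dout) {
    d <- dim(dout); N <- d[1] * d[2]
    dy <- reshape2(dout, N, d[3])
    self$gamma$grad <- self$gamma$grad + colSums(dy * self$xhat)
    self$beta$grad <- self$beta$grad + colSums(dy)
    dxhat <- dy * rep(as.vector(self$gamma$value), each = N)
    if (isTRUE(self$training)) {
      t1 <- sweep(dxhat, 2, colMeans(dxhat))
      t2 <- self$xhat * rep(colMeans(dxhat * self$xhat), each = N)
      dx <- (t1 - t2) * rep(self$istd, each = N)
    } else {
      dx <- dxhat * rep(self$istd, each = N)
    }
    reshape3(dx, d[1], d[2], d[3])
  }
  self
}

# Layer normalization over the whole [H, W, C] tensor with per-channel
# affine parameters (the patch-discriminator normalization).
#' @noRd
layer_layernorm_cnn <- function(C, eps = 1e-5) {
  self <- new.env(parent = emptyenv())
  self$gamma <- zero_param(c(C)); self$gamma$value[] <- 1
  self$beta <- zero_param(c(C))
  self$params <- list(self$gamma, self$beta)
  self$forward <- function(x, training = TRUE) {
    d <- dim(x); N <- prod(d)
    mu <- mean(x); va <- mean((x - mu)^2)
    self$istd <- 1 / sqrt(va + eps)
    self$xhat <- (x - mu) * self$istd
    HW <- d[1] * d[2]
    addbias_ch(self$xhat * rep(as.vector(self$gamma$value), each = HW),
               as.vector(self$beta$value))
  }
  self$backward <- function(dout) {
    d <- dim(dout); HW <- d[1] * d[2]
    self$gamma$grad <- self$gamma$grad + sum_ch(dout * self$xhat)
    self$beta$grad <- self$beta$grad + sum_ch(dout)
    dxhat <- dout * rep(as.vector(self$gamma$value), each = HW)
    m1 <- mean(dxhat); m2 <- mean(dxhat * self$xhat)
    (dxhat - m1 - self$xhat * m2) * self$istd
  }
  self
}

#' @noRd
layer_act <- function(type = c("leaky_relu", "relu", "sigmoid"),
                      slope = 0.2) {
  type <- match.arg(type)
  self <- new.env(parent = emptyenv())
  self$params <- list()
  self$forward <- function(x, training = TRUE) {
    if (type == "sigmoid") {
      y <- 1 / (1 + exp(-x))
      self$y <- y
      return(y)
    }
    pos <- x > 0
    self$pos <- pos
    if (type == "relu") x * pos else x * (pos + slope * !pos)
  }
  self$backward <- function(dout) {
    switch(type,
           leaky_relu = dout * (self$pos + slope * !self$pos),
           relu = dout * self$pos,
           sigmoid = dout * self$y * (1 - self$y))
  }
  self
}

#' @noRd
layer_dropout <- function(p = 0.5) {
  self <- new.env(parent = emptyenv())
  self$params <- list()
  self$forward <- function(x, training = TRUE) {
    if (!training || p <= 0) { self$mask <- NULL; return(x) }
    self$mask <- array(stats::rbinom(length(x), 1, 1 - p) / (1 - p),
                       dim = dim(x))
    x * self$mask
  }
  self$backward <- function(dout) {
    if (is.null(self$mask)) dout else dout * self$mask
  }
  self
}

# ---- token-space layers (ViT) ------------------------------------------

#' @noRd
layer_linear <- function(in_dim, out_dim, sd = NULL) {
  self <- new.env(parent = emptyenv())
  if (is.null(sd)) sd <- sqrt(2 / in_dim)
  self$W <- new_param(c(in_dim, out_dim), sd = sd)
  self$b <- zero_param(c(out_dim))
  self$params <- list(self$W, self$b)
  self$forward <- function(x, training = TRUE) {
    self$x <- x
    sweep(x %*% self$W$value, 2, as.vector(self$b$value), `+`)
  }
  self$backward <- function(dout) {
    self$W$grad <- self$W$grad + crossprod(self$x, dout)
    self$b$grad <- self$b$grad + colSums(dout)
    dout %*% t(self$W$value)
  }
  self
}

#' @noRd
layer_layernorm_tokens <- function(D, eps = 1e-5) {
  self <- new.env(parent = emptyenv())
  self$gamma <- zero_param(c(D)); self$gamma$value[] <- 1
  self$beta <- zero_param(c(D))
  self$params <- list(self$gamma, self$beta)
  self$forward <- function(x, training = TRUE) {
    mu <- rowMeans(x)
    xc <- x - mu
    va <- rowMeans(xc^2)
    self$istd <- 1 / sqrt(va + eps)
    self$xhat <- xc * self$istd
    sweep(sweep(self$xhat, 2, as.vector(self$gamma$value), `*`),
          2, as.vector(self$beta$value), `+`)
  }
  self$backward <- function(dout) {
    D <- ncol(dout)
    self$gamma$grad <- self$gamma$grad + colSums(dout * self$xhat)
    self$beta$grad <- self$beta$grad + colSums(dout)
    dxhat <- sweep(dout, 2, as.vector(self$gamma$value), `*`)
    m1 <- rowMeans(dxhat); m2 <- rowMeans(dxhat * self$xhat)
    (dxhat - m1 - self$xhat * m2) * self$istd
  }
  self
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

#' @noRd
layer_mlp_tokens <- function(D, hidden = 4 * D) {
  self <- new.env(parent = emptyenv())
  self$fc1 <- layer_linear(D, hidden)
  self$fc2 <- layer_linear(hidden, D)
  self$params <- c(self$fc1$params, self$fc2$params)
  self$forward <- function(x, training = TRUE) {
    self$h <- self$fc1$forward(x, training)
    self$fc2$forward(gelu(self$h), training)
  }
  self$backward <- function(dout) {
    dh <- self$fc2$backward(dout) * gelu_grad(self$h)
    self$fc1$backward(dh)
  }
  self
}

#' @noRd
layer_mha <- function(D, n_heads) {
  stopifnot(D %% n_heads == 0)
  dh <- D %/% n_heads
  self <- new.env(parent = emptyenv())
  self$q <- layer_linear(D, D, sd = sqrt(1 / D))
  self$k <- layer_linear(D, D, sd = sqrt(1 / D))
  self$v <- layer_linear(D, D, sd = sqrt(1 / D))
  self$o <- layer_linear(D, D, sd = sqrt(1 / D))
  self$params <- c(self$q$params, self$k$params, self$v$params,
                   self$o$params)
  self$forward <- function(x, training = TRUE) {
    N <- nrow(x)
    Q <- self$q$forward(x, training)
    K <- self$k$forward(x, training)
    V <- self$v$forward(x, training)
    self$A <- vector("list", n_heads)
    self$Qh <- vector("list", n_heads)
    self$Kh <- vector("list", n_heads)
    self$Vh <- vector("list", n_heads)
    O <- matrix(0, N, D)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      Qh <- Q[, cols, drop = FALSE]; Kh <- K[, cols, drop = FALSE]
      Vh <- V[, cols, drop = FALSE]
      S <- Qh %*% t(Kh) / sqrt(dh)
      S <- S - apply(S, 1, max)
      A <- exp(S); A <- A / rowSums(A)
      O[, cols] <- A %*% Vh
      self$A[[h]] <- A; self$Qh[[h]] <- Qh
      self$Kh[[h]] <- Kh; self$Vh[[h]] <- Vh
    }
    self$o$forward(O, training)
  }
  self$backward <- function(dout) {
    dO <- self$o$backward(dout)
    N <- nrow(dO)
    dQ <- matrix(0, N, D); dK <- matrix(0, N, D); dV <- matrix(0, N, D)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      dOh <- dO[, cols, drop = FALSE]
      A <- self$A[[h]]
      dA <- dOh %*% t(self$Vh[[h]])
      dV[, cols] <- t(A) %*% dOh
      dS <- A * (dA - rowSums(dA * A))
      dQ[, cols] <- dS %*% self$Kh[[h]] / sqrt(dh)
      dK[, cols] <- t(dS) %*% self$Qh[[h]] / sqrt(dh)
    }
    self$q$backward(dQ) + self$k$backward(dK) + self$v$backward(dV)
  }
  self
}

# Pre-norm transformer encoder block: x + MHA(LN(x)), then x + MLP(LN(x)).
#' @noRd
layer_transformer_block <- function(D, n_heads) {
  self <- new.env(parent = emptyenv())
  self$ln1 <- layer_layernorm_tokens(D)
  self$att <- layer_mha(D, n_heads)
  self$ln2 <- layer_layernorm_tokens(D)
  self$mlp <- layer_mlp_tokens(D)
  self$params <- c(self$ln1$params, self$att$params, self$ln2$params,
                   self$mlp$params)
  self$forward <- function(x, training = TRUE) {
    a <- x + self$att$forward(self$ln1$forward(x, training), training)
    a + self$mlp$forward(self$ln2$forward(a, training), training)
  }
  self$backward <- function(dout) {
    da <- dout + self$ln2$backward(self$mlp$backward(dout))
    da + self$ln1$backward(self$att$backward(da))
  }
  self
}

# Nearest-neighbour spatial upsampling by an integer factor.
#' @noRd
layer_upsample_nn <- function(factor = 2L) {
  self <- new.env(parent = emptyenv())
  self$params <- list()
  self$forward <- function(x, training = TRUE) {
    d <- dim(x)
    self$in_shape <- d
    ri <- rep(seq_len(d[1]), each = factor)
    ci <- rep(seq_len(d[2]), each = factor)
    x[ri, ci, , drop = FALSE]
  }
  self$backward <- function(dout) {
    d <- self$in_shape
    out <- array(0, d)
    for (a in seq_len(factor)) for (b in seq_len(factor)) {
      out <- out + dout[seq(a, by = factor, length.out = d[1]),
                        seq(b, by = factor, length.out = d[2]), ,
                        drop = FALSE]
    }
    out
  }
  self
}

# ---- optimizer ----------------------------------------------------------

adam_state <- function(lr, beta1 = 0.5, beta2 = 0.999,
                       weight_decay = 1e-4, eps = 1e-8) {
  env <- new.env(parent = emptyenv())
  env$lr <- lr; env$beta1 <- beta1; env$beta2 <- beta2
  env$weight_decay <- weight_decay; env$eps <- eps; env$t <- 0
  env
}

adam_step <- function(params, opt) {
  opt$t <- opt$t + 1
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (p in params) {
    g <- p$grad + opt$weight_decay * p$value
    p$m <- opt$beta1 * p$m + (1 - opt$beta1) * g
    p$v <- opt$beta2 * p$v + (1 - opt$beta2) * g^2
    p$value <- p$value - opt$lr * (p$m / bc1) /
      (sqrt(p$v / bc2) + opt$eps)
    p$grad[] <- 0
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$grad[] <- 0
  invisible(NULL)
}

# Deep-copy parameter values (for checkpoint selection).
snapshot_params <- function(params) lapply(params, function(p) p$value)
restore_params <- function(params, snap) {
  for (i in seq_along(params)) params[[i]]$value <- snap[[i]]
  invisible(NULL)
}
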