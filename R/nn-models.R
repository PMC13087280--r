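#' Generator specification
#'
#' Geometry-parameterized so the full-size (2048 x 512) and desk-scale
#' instantiations share code. The `pix2pix` variant is a U-Net encoder/
#' decoder (4 x 4 kernels, stride 2, filters doubling from `base_filters`
#' up to `filter_cap`); the ViT variants embed non-overlapping 16 x 16
#' patches and process them with 2 (shallow) or 5 (deep) transformer
#' encoder blocks before a transposed-convolution decoder. The deep
#' variant adds reshape-and-upsample skip paths from early transformer
#' blocks into the decoder.
#'
#' @param variant `"pix2pix"`, `"vit_shallow"`, or `"vit_deep"`.
#' @param rows,cols Input/output shape; must be divisible by
#'   `2^n_levels` (pix2pix) or `patch_size` (ViT).
#' @param base_filters First-level encoder filters (pix2pix).
#' @param n_levels Encoder depth (pix2pix; 7 reproduces the full-scale
#'   design).
#' @param filter_cap Maximum encoder width (pix2pix).
#' @param patch_size ViT patch side (16).
#' @param embed_dim Token embedding width.
#' @param n_heads Attention heads.
#' @param n_blocks Transformer blocks; defaults to 2 (shallow) / 5 (deep).
#' @param decoder_filters Channel plan of the three hidden decoder stages
#'   (ViT variants).
#' @param skip_channels Channels of the 1 x 1 projections on the deep-ViT
#'   skip paths.
#' @param dropout Dropout rate on the early pix2pix decoder blocks.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(variant = c("pix2pix", "vit_shallow", "vit_deep"),
                           rows, cols, base_filters = 64, n_levels = 7,
                           filter_cap = 512, patch_size = 16,
                           embed_dim = 256, n_heads = 8, n_blocks = NULL,
                           decoder_filters = c(128, 64, 32),
                           skip_channels = 64, dropout = 0.5) {
  variant <- match.arg(variant)
  if (variant == "pix2pix") {
    if (rows %% 2^n_levels != 0 || cols %% 2^n_levels != 0)
      stop("rows and cols must be divisible by 2^n_levels")
  } else {
    if (rows %% patch_size != 0 || cols %% patch_size != 0)
      stop("rows and cols must be divisible by patch_size")
    if (is.null(n_blocks))
      n_blocks <- if (variant == "vit_shallow") 2L else 5L
    if (embed_dim %% n_heads != 0)
      stop("embed_dim must be divisible by n_heads")
  }
  structure(list(variant = variant, rows = rows, cols = cols,
                 base_filters = base_filters, n_levels = n_levels,
                 filter_cap = filter_cap, patch_size = patch_size,
                 embed_dim = embed_dim, n_heads = n_heads,
                 n_blocks = n_blocks, decoder_filters = decoder_filters,
                 skip_channels = skip_channels, dropout = dropout),
            class = "generator_spec")
}

#' Discriminator specification
#'
#' Patch discriminator: B-mode and RF are channel-concatenated, passed
#' through three stride-2 3 x 3 down-sampling blocks and two stride-1
#' head convolutions, ending in a sigmoid probability map of shape
#' `(rows/8, cols/8)`.
#'
#' @param rows,cols Input shape (divisible by 8).
#' @param down_filters Filters of the three down-sampling blocks.
#' @param head_filters Filters of the two stride-1 head convolutions.
#' @return A `discriminator_spec` list.
#' @export
discriminator_spec <- function(rows, cols,
                               down_filters = c(64, 128, 256),
                               head_filters = c(512, 1)) {
  if (rows %% 8 != 0 || cols %% 8 != 0)
    stop("rows and cols must be divisible by 8")
  structure(list(rows = rows, cols = cols, down_filters = down_filters,
                 head_filters = head_filters),
            class = "discriminator_spec")
}

#' Number of ViT patches for a frame geometry
#'
#' @param rows,cols Frame shape.
#' @param patch_size Patch side length.
#' @return `(rows / patch_size) * (cols / patch_size)`.
#' @examples
#' patch_count(2048, 512, 16)  # 4096
#' @export
patch_count <- function(rows, cols, patch_size = 16) {
  if (rows %% patch_size != 0 || cols %% patch_size != 0)
    stop("rows and cols must be divisible by patch_size")
  (rows %/% patch_size) * (cols %/% patch_size)
}

# Non-overlapping patch index table: PIDX[t, ] are the linear pixel
# indices of token t in a [rows, cols] matrix (tokens column-major over
# the patch grid, pixels column-major within a patch).
patch_index <- function(rows, cols, ps) {
  gh <- rows %/% ps; gw <- cols %/% ps
  pi_ <- rep(seq_len(gh), gw); pj_ <- rep(seq_len(gw), each = gh)
  ki <- rep(seq_len(ps), ps); kj <- rep(seq_len(ps), each = ps)
  outer((pi_ - 1) * ps, ki, `+`) +
    outer((pj_ - 1) * ps, kj - 1, `+`) * rows
}

#' Build a generator model
#'
#' Returns a model object with `forward(x, training)`, `backward(dout)`,
#' and `params` (the trainable parameter list); input and output are
#' `[0, 1]` matrices of shape `spec$rows x spec$cols`.
#'
#' @param spec A [generator_spec()].
#' @return An object of class `rf_generator`.
#' @export
build_generator <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  switch(spec$variant,
         pix2pix = build_pix2pix(spec),
         vit_shallow = build_vit(spec),
         vit_deep = build_vit(spec))
}

build_pix2pix <- function(spec) {
  L <- spec$n_levels
  f <- pmin(spec$base_filters * 2^(0:(L - 1)), spec$filter_cap)
  rows <- spec$rows; cols <- spec$cols
  enc <- list(); enc_bn <- list(); enc_act <- list()
  h <- rows; w <- cols; ch <- 1
  for (i in seq_len(L)) {
    enc[[i]] <- layer_conv2d(h, w, ch, f[i], k = 4, stride = 2, pad = 1)
    enc_bn[i] <- list(if (i > 1) layer_batchnorm(f[i]) else NULL)
    enc_act[[i]] <- layer_act("leaky_relu")
    h <- h %/% 2; w <- w %/% 2; ch <- f[i]
  }
  dec <- list(); dec_bn <- list(); dec_drop <- list(); dec_act <- list()
  in_ch <- f[L]
  for (j in seq_len(L - 1)) {
    out_ch <- f[L - j]
    dec[[j]] <- layer_tconv2d(h, w, in_ch, out_ch, k = 4, stride = 2,
                              pad = 1)
    dec_bn[[j]] <- layer_batchnorm(out_ch)
    dec_drop[j] <- list(if (j <= 3) layer_dropout(spec$dropout) else NULL)
    dec_act[[j]] <- layer_act("relu")
    h <- h * 2; w <- w * 2
    in_ch <- 2 * out_ch          # concat with the mirrored encoder output
  }
  final <- layer_tconv2d(h, w, in_ch, 1, k = 4, stride = 2, pad = 1)
  final_act <- layer_act("sigmoid")
  layers <- c(enc, Filter(Negate(is.null), enc_bn), enc_act,
              dec, dec_bn, Filter(Negate(is.null), dec_drop), dec_act,
              list(final, final_act))
  params <- do.call(c, lapply(layers, `[[`, "params"))
  self <- new.env(parent = emptyenv())
  self$spec <- spec
  self$params <- params
  self$forward <- function(x, training = TRUE) {
    a <- array(x, c(spec$rows, spec$cols, 1))
    e <- vector("list", L)
    for (i in seq_len(L)) {
      a <- enc[[i]]$forward(a, training)
      if (!is.null(enc_bn[[i]])) a <- enc_bn[[i]]$forward(a, training)
      a <- enc_act[[i]]$forward(a, training)
      e[[i]] <- a
    }
    self$skip_ch <- integer(L - 1)
    for (j in seq_len(L - 1)) {
      a <- dec[[j]]$forward(a, training)
      a <- dec_bn[[j]]$forward(a, training)
      if (!is.null(dec_drop[[j]])) a <- dec_drop[[j]]$forward(a, training)
      a <- dec_act[[j]]$forward(a, training)
      sk <- e[[L - j]]
      self$skip_ch[j] <- dim(a)[3]
      a <- abind3(a, sk)
    }
    out <- final_act$forward(final$forward(a, training), training)
    matrix(out, spec$rows, spec$cols)
  }
  self$backward <- function(dout) {
    d <- final$backward(final_act$backward(
      array(dout, c(spec$rows, spec$cols, 1))))
    dskip <- vector("list", L)   # gradients flowing into encoder outputs
    for (j in rev(seq_len(L - 1))) {
      nc <- self$skip_ch[j]
      dskip[[L - j]] <- d[, , (nc + 1):dim(d)[3], drop = FALSE]
      d <- d[, , seq_len(nc), drop = FALSE]
      d <- dec_act[[j]]$backward(d)
      if (!is.null(dec_drop[[j]])) d <- dec_drop[[j]]$backward(d)
      d <- dec_bn[[j]]$backward(d)
      d <- dec[[j]]$backward(d)
    }
    for (i in rev(seq_len(L))) {
      if (!is.null(dskip[[i]])) d <- d + dskip[[i]]
      d <- enc_act[[i]]$backward(d)
      if (!is.null(enc_bn[[i]])) d <- enc_bn[[i]]$backward(d)
      d <- enc[[i]]$backward(d)
    }
    matrix(d, spec$rows, spec$cols)
  }
  class(self) <- c("rf_generator", "pix2pix")
  self
}

abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

build_vit <- function(spec) {
  ps <- spec$patch_size; D <- spec$embed_dim
  gh <- spec$rows %/% ps; gw <- spec$cols %/% ps
  N <- gh * gw
  deep <- spec$variant == "vit_deep"
  PIDX <- patch_index(spec$rows, spec$cols, ps)
  embed <- layer_linear(ps * ps, D, sd = sqrt(1 / (ps * ps)))
  posemb <- new_param(c(N, D), sd = 0.02)
  blocks <- lapply(seq_len(spec$n_blocks), function(i)
    layer_transformer_block(D, spec$n_heads))
  df <- spec$decoder_filters
  sc <- spec$skip_channels
  if (deep) {
    skip1_proj <- layer_conv2d(gh, gw, D, sc, k = 1, stride = 1, pad = 0)
    skip1_up <- layer_upsample_nn(2L)
    skip3_proj <- layer_conv2d(gh, gw, D, sc, k = 1, stride = 1, pad = 0)
  }
  in1 <- if (deep) D + sc else D
  dec1 <- layer_tconv2d(gh, gw, in1, df[1], k = 4, stride = 2, pad = 1)
  bn1 <- layer_batchnorm(df[1]); act1 <- layer_act("leaky_relu")
  in2 <- if (deep) df[1] + sc else df[1]
  dec2 <- layer_tconv2d(gh * 2, gw * 2, in2, df[2], k = 4, stride = 2,
                        pad = 1)
  bn2 <- layer_batchnorm(df[2]); act2 <- layer_act("leaky_relu")
  dec3 <- layer_tconv2d(gh * 4, gw * 4, df[2], df[3], k = 4, stride = 2,
                        pad = 1)
  bn3 <- layer_batchnorm(df[3]); act3 <- layer_act("leaky_relu")
  dec4 <- layer_tconv2d(gh * 8, gw * 8, df[3], 1, k = 4, stride = 2,
                        pad = 1)
  act4 <- layer_act("sigmoid")
  layers <- c(list(embed), blocks,
              list(dec1, bn1, act1, dec2, bn2, act2,
                   dec3, bn3, act3, dec4, act4))
  if (deep) layers <- c(layers, list(skip1_proj, skip3_proj))
  params <- c(do.call(c, lapply(layers, `[[`, "params")), list(posemb))
  self <- new.env(parent = emptyenv())
  self$spec <- spec
  self$n_transformer_blocks <- spec$n_blocks
  self$params <- params
  self$forward <- function(x, training = TRUE) {
    P <- matrix(x[PIDX], N, ps * ps)
    tok <- embed$forward(P, training) + posemb$value
    taps <- list()
    for (bi in seq_along(blocks)) {
      tok <- blocks[[bi]]$forward(tok, training)
      if (deep && bi %in% c(1, 3)) taps[[as.character(bi)]] <- tok
    }
    a <- array(tok, c(gh, gw, D))
    if (deep) {
      s3 <- skip3_proj$forward(array(taps[["3"]], c(gh, gw, D)), training)
      a <- abind3(a, s3)
    }
    a <- act1$forward(bn1$forward(dec1$forward(a, training), training),
                      training)
    if (deep) {
      s1 <- skip1_up$forward(
        skip1_proj$forward(array(taps[["1"]], c(gh, gw, D)), training),
        training)
      a <- abind3(a, s1)
    }
    a <- act2$forward(bn2$forward(dec2$forward(a, training), training),
                      training)
    a <- act3$forward(bn3$forward(dec3$forward(a, training), training),
                      training)
    out <- act4$forward(dec4$forward(a, training), training)
    matrix(out, spec$rows, spec$cols)
  }
  self$backward <- function(dout) {
    d <- dec4$backward(act4$backward(
      array(dout, c(spec$rows, spec$cols, 1))))
    d <- dec3$backward(bn3$backward(act3$backward(d)))
    d <- dec2$backward(bn2$backward(act2$backward(d)))
    dtap1 <- NULL; dtap3 <- NULL
    if (deep) {
      nc <- dim(d)[3] - spec$skip_channels
      ds1 <- d[, , (nc + 1):dim(d)[3], drop = FALSE]
      d <- d[, , seq_len(nc), drop = FALSE]
      dtap1 <- matrix(skip1_proj$backward(skip1_up$backward(ds1)), N, D)
    }
    d <- dec1$backward(bn1$backward(act1$backward(d)))
    if (deep) {
      nc <- dim(d)[3] - spec$skip_channels
      ds3 <- d[, , (nc + 1):dim(d)[3], drop = FALSE]
      d <- d[, , seq_len(nc), drop = FALSE]
      dtap3 <- matrix(skip3_proj$backward(ds3), N, D)
    }
    dtok <- matrix(d, N, D)
    for (bi in rev(seq_along(blocks))) {
      dtok <- blocks[[bi]]$backward(dtok)
      if (deep && bi == 4 && !is.null(dtap3)) dtok <- dtok + dtap3
      if (deep && bi == 2 && !is.null(dtap1)) dtok <- dtok + dtap1
    }
    posemb$grad <- posemb$grad + dtok
    dP <- embed$backward(dtok)
    dimg <- matrix(0, spec$rows, spec$cols)
    dimg[as.vector(PIDX)] <- as.vector(dP)
    dimg
  }
  class(self) <- c("rf_generator", spec$variant)
  self
}

#' Build the patch discriminator
#'
#' @param spec A [discriminator_spec()].
#' @return An object of class `rf_discriminator` with
#'   `forward(bmode, rf, training)` returning the patch probability map
#'   and `backward(dout)` returning the gradient with respect to the RF
#'   input.
#' @export
build_discriminator <- function(spec) {
  stopifnot(inherits(spec, "discriminator_spec"))
  rows <- spec$rows; cols <- spec$cols
  convs <- list(); norms <- list(); acts <- list()
  h <- rows; w <- cols; ch <- 2
  for (i in seq_along(spec$down_filters)) {
    f <- spec$down_filters[i]
    convs[[i]] <- layer_conv2d(h, w, ch, f, k = 3, stride = 2, pad = 1)
    norms[[i]] <- layer_layernorm_cnn(f)
    acts[[i]] <- layer_act("leaky_relu")
    h <- h %/% 2; w <- w %/% 2; ch <- f
  }
  head1 <- layer_conv2d(h, w, ch, spec$head_filters[1], k = 3,
                        stride = 1, pad = 1)
  head1_norm <- layer_layernorm_cnn(spec$head_filters[1])
  head1_act <- layer_act("leaky_relu")
  head2 <- layer_conv2d(h, w, spec$head_filters[1], spec$head_filters[2],
                        k = 3, stride = 1, pad = 1)
  out_act <- layer_act("sigmoid")
  layers <- c(convs, norms, acts,
              list(head1, head1_norm, head1_act, head2, out_act))
  params <- do.call(c, lapply(layers, `[[`, "params"))
  self <- new.env(parent = emptyenv())
  self$spec <- spec
  self$out_shape <- c(as.integer(h), as.integer(w))
  self$params <- params
  self$forward <- function(bmode, rf, training = TRUE) {
    if (!identical(dim(bmode), dim(rf)))
      stop("B-mode and RF inputs must share shape")
    a <- array(c(bmode, rf), c(rows, cols, 2))
    for (i in seq_along(convs)) {
      a <- acts[[i]]$forward(norms[[i]]$forward(
        convs[[i]]$forward(a, training), training), training)
    }
    a <- head1_act$forward(head1_norm$forward(
      head1$forward(a, training), training), training)
    out <- out_act$forward(head2$forward(a, training), training)
    matrix(out, h, w)
  }
  self$backward <- function(dout) {
    d <- head2$backward(out_act$backward(array(dout, c(h, w, 1))))
    d <- head1$backward(head1_norm$backward(head1_act$backward(d)))
    for (i in rev(seq_along(convs))) {
      d <- convs[[i]]$backward(norms[[i]]$backward(acts[[i]]$backward(d)))
    }
    list(dbmode = matrix(d[, , 1], rows, cols),
         drf = matrix(d[, , 2], rows, cols))
  }
  class(self) <- "rf_discriminator"
  self
}

#' Number of trainable parameters of a model
#' @param model An `rf_generator` or `rf_discriminator`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, function(p) length(p$value), numeric(1)))
}

#' Desk-scale model specifications for smoke training
#'
#' Narrow instantiations of the three generator variants and the patch
#' discriminator used for CPU smoke experiments at 256 x 64 geometry:
#' the architecture topology (level counts, block counts, patch size,
#' stride plan) matches the full-scale design while channel widths are
#' reduced for minutes-scale runtimes.
#'
#' @param variant Generator variant.
#' @param rows,cols Geometry (defaults 256 x 64).
#' @return A [generator_spec()] / [discriminator_spec()].
#' @export
desk_generator_spec <- function(variant, rows = 256, cols = 64) {
  if (variant == "pix2pix")
    generator_spec(variant, rows, cols, base_filters = 4, n_levels = 5,
                   filter_cap = 32)
  else
    generator_spec(variant, rows, cols, embed_dim = 32, n_heads = 4,
                   decoder_filters = c(16, 8, 8), skip_channels = 4)
}

#' @rdname desk_generator_spec
#' @export
desk_discriminator_spec <- function(rows = 256, cols = 64) {
  discriminator_spec(rows, cols, down_filters = c(8, 16, 32),
                     head_filters = c(32, 1))
}
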