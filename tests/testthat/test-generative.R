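test_that("patch count and discriminator map shapes follow the geometry
           algebra", {
  expect_equal(patch_count(2048, 512, 16), 4096)
  expect_equal(patch_count(16, 16, 16), 1)
  expect_equal(patch_count(256, 64, 16), 64)
  expect_error(patch_count(100, 64, 16), "divisible")

  d <- build_discriminator(discriminator_spec(256, 64,
                                              down_filters = c(4, 6, 8),
                                              head_filters = c(8, 1)))
  expect_identical(d$out_shape, c(32L, 8L))
  expect_error(discriminator_spec(100, 30), "divisible")
})

test_that("all generator variants map [0,1] input to [0,1] output of the
           same shape", {
  set.seed(10)
  x <- matrix(runif(64 * 32), 64, 32)
  for (v in c("pix2pix", "vit_shallow", "vit_deep")) {
    spec <- if (v == "pix2pix")
      generator_spec(v, 64, 32, base_filters = 4, n_levels = 4,
                     filter_cap = 16)
    else generator_spec(v, 64, 32, embed_dim = 16, n_heads = 2,
                        decoder_filters = c(8, 6, 4), skip_channels = 4)
    G <- build_generator(spec)
    y <- G$forward(x, training = FALSE)
    expect_identical(dim(y), dim(x))
    expect_true(all(y >= 0 & y <= 1))
    # inference is deterministic
    expect_identical(y, G$forward(x, training = FALSE))
    expect_identical(y, synthesize_rf(G, x))
  }
  expect_error(generator_spec("pix2pix", 100, 30, n_levels = 4),
               "divisible")
})

test_that("architecture introspection: block counts and capacity ordering", {
  s2 <- build_generator(generator_spec("vit_shallow", 32, 32,
                                       embed_dim = 16, n_heads = 2,
                                       decoder_filters = c(8, 6, 4)))
  s5 <- build_generator(generator_spec("vit_deep", 32, 32,
                                       embed_dim = 16, n_heads = 2,
                                       decoder_filters = c(8, 6, 4),
                                       skip_channels = 4))
  expect_identical(s2$n_transformer_blocks, 2L)
  expect_identical(s5$n_transformer_blocks, 5L)

  p7 <- build_generator(generator_spec("pix2pix", 128, 128,
                                       base_filters = 4, n_levels = 7,
                                       filter_cap = 32))
  p5 <- build_generator(generator_spec("pix2pix", 128, 128,
                                       base_filters = 4, n_levels = 5,
                                       filter_cap = 32))
  expect_gt(n_parameters(p7), n_parameters(p5))
})

test_that("discriminator output lies in (0,1) and shapes must match", {
  set.seed(11)
  D <- build_discriminator(discriminator_spec(64, 32,
                                              down_filters = c(4, 6, 8),
                                              head_filters = c(8, 1)))
  bm <- matrix(runif(64 * 32), 64, 32)
  rf <- matrix(runif(64 * 32), 64, 32)
  m <- D$forward(bm, rf, training = FALSE)
  expect_identical(dim(m), c(8L, 4L))
  expect_true(all(m > 0 & m < 1))
  expect_error(D$forward(bm, matrix(0, 32, 32)), "share shape")
})

test_that("loss closed forms", {
  # constant reconstruction error 0.1: L1 term 100, L2 term 1
  syn <- matrix(0.6, 16, 8); tgt <- matrix(0.5, 16, 8)
  dm <- matrix(0.5, 2, 1)
  gl <- generator_loss(syn, tgt, dm)
  expect_equal(gl$l1 * 1000, 100, tolerance = 1e-12)
  expect_equal(gl$l2 * 100, 1, tolerance = 1e-9)
  expect_equal(gl$adv, -log(0.5), tolerance = 1e-9)
  expect_equal(gl$total, gl$adv + 100 + 1, tolerance = 1e-9)

  # identical reconstruction: only the adversarial term remains
  g0 <- generator_loss(tgt, tgt, dm)
  expect_equal(g0$total, g0$adv)

  # half-confident discriminator, no smoothing: 2 ln 2
  expect_equal(discriminator_loss(matrix(0.5, 2, 2), matrix(0.5, 2, 2),
                                  label_smoothing = 0),
               2 * log(2), tolerance = 1e-9)
  # near-perfect discriminator: loss near 0
  expect_lt(discriminator_loss(matrix(1 - 1e-9, 2, 2),
                               matrix(1e-9, 2, 2), 0), 1e-6)
  # with smoothing eps, the real-term optimum sits at 1 - eps
  eps <- 0.1
  bce_real <- function(p) -mean((1 - eps) * log(p) + eps * log(1 - p))
  expect_lt(bce_real(0.9), bce_real(0.99))
  expect_lt(bce_real(0.9), bce_real(0.8))
})

test_that("backpropagated gradients match finite differences", {
  set.seed(12)
  spec <- generator_spec("vit_deep", 32, 32, embed_dim = 16, n_heads = 2,
                         decoder_filters = c(8, 6, 4), skip_channels = 4)
  G <- build_generator(spec)
  x <- matrix(runif(32 * 32), 32, 32)
  tgt <- matrix(runif(32 * 32), 32, 32)
  lossf <- function(xx) sum((G$forward(xx, training = FALSE) - tgt)^2)
  y <- G$forward(x, training = FALSE)
  gx <- G$backward(2 * (y - tgt))
  idx <- sample(length(x), 12)
  ng <- vapply(idx, function(i) {
    eps <- 1e-5
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (lossf(xp) - lossf(xm)) / (2 * eps)
  }, numeric(1))
  expect_equal(gx[idx], ng, tolerance = 1e-4)

  # and a parameter gradient
  p <- G$params[[1]]
  idx <- seq_len(min(6, length(p$value)))
  ng <- vapply(idx, function(i) {
    eps <- 1e-5
    old <- p$value[i]
    p$value[i] <- old + eps; lp <- lossf(x)
    p$value[i] <- old - eps; lm <- lossf(x)
    p$value[i] <- old
    (lp - lm) / (2 * eps)
  }, numeric(1))
  expect_equal(p$grad[idx], ng, tolerance = 1e-4)
})

test_that("training on a tiny task reduces loss, selects in-window, and is
           seed-reproducible", {
  set.seed(13)
  # a learnable task: rf is a smoothed transform of bmode
  mkpair <- function() {
    b <- matrix(runif(32 * 32), 32, 32)
    list(bmode = b, rf = 0.3 + 0.4 * b)
  }
  tr <- replicate(4, mkpair(), simplify = FALSE)
  va <- replicate(2, mkpair(), simplify = FALSE)
  gspec <- generator_spec("pix2pix", 32, 32, base_filters = 4,
                          n_levels = 3, filter_cap = 16)
  dspec <- discriminator_spec(32, 32, down_filters = c(4, 6, 8),
                              head_filters = c(8, 1))
  cfg <- train_config(lr_generator = 1e-3, epochs_main = 10,
                      epochs_select = 3, seed = 77)
  tt <- train_cgan(tr, va, gspec, dspec, config = cfg)
  expect_identical(nrow(tt$log), 13L)
  expect_lt(min(tt$log$val_recon), tt$log$val_recon[1])
  expect_true(tt$selected_epoch > 10 && tt$selected_epoch <= 13)
  expect_equal(min(tt$log$val_recon[tt$log$epoch > 10]),
               tt$log$val_recon[tt$log$epoch == tt$selected_epoch])

  tt2 <- train_cgan(tr, va, gspec, dspec, config = cfg)
  expect_equal(tt$log$g_total, tt2$log$g_total, tolerance = 1e-12)
  expect_error(train_cgan(list(), va, gspec, dspec, config = cfg),
               "empty")
})
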