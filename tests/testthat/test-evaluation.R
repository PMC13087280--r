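test_that("normalized error metrics: identities, arithmetic, and ordering", {
  x <- matrix(runif(400), 20, 20)
  expect_equal(nrmse(x, x), 0)
  expect_equal(nmae(x, x), 0)

  # reference spanning [0,1], constant error 0.05 -> NMAE = 5%
  ref <- matrix(seq(0, 1, length.out = 400), 20, 20)
  cand <- ref + 0.05
  expect_equal(nmae(ref, cand), 5, tolerance = 1e-9)
  expect_equal(nrmse(ref, cand), 5, tolerance = 1e-9)

  # Jensen: NRMSE >= NMAE on random pairs
  set.seed(21)
  for (i in 1:20) {
    a <- matrix(runif(100), 10, 10)
    b <- a + matrix(rnorm(100, 0, 0.1), 10, 10)
    expect_gte(nrmse(a, b) + 1e-12, nmae(a, b))
  }
  expect_error(nrmse(matrix(1, 3, 3), matrix(1, 3, 3)), "dynamic range")
  expect_error(nmae(matrix(1, 2, 2), matrix(1, 3, 3)), "share shape")
})

test_that("SSIM: self-identity, degradation ordering, and agreement with
           an independent reference implementation", {
  set.seed(4242)
  x <- matrix(runif(48 * 40), 48, 40)
  y <- pmin(pmax(x + matrix(rnorm(48 * 40, 0, 0.1), 48, 40), 0), 1)
  expect_equal(ssim(x, x), 1, tolerance = 1e-12)
  expect_lt(ssim(x, 1 - x), ssim(x, x))
  expect_gt(ssim(x, y), ssim(x, matrix(runif(48 * 40), 48, 40)))

  # frozen oracle values (scikit-image structural_similarity with the
  # standard 11x11 Gaussian window, sigma 1.5)
  expect_equal(ssim(x, y, data_range = 1), 0.949209185473,
               tolerance = 1e-6)
  set.seed(777)
  a <- matrix(runif(32 * 32, 0, 5), 32, 32)
  b <- a * 0.8 + matrix(rnorm(32 * 32, 0, 0.3), 32, 32)
  expect_equal(ssim(a, b, data_range = 5), 0.928646951869,
               tolerance = 1e-6)
  expect_error(ssim(matrix(1, 8, 8), matrix(1, 8, 8)), "11 x 11")
})

test_that("PSNR closed forms", {
  x <- matrix(0.5, 16, 16)
  e <- matrix(0.1, 16, 16)   # MSE = 0.01
  expect_equal(psnr(x, x + e, peak = 1), 20, tolerance = 1e-9)
  expect_identical(psnr(x, x), Inf)
  # doubling the error amplitude costs 6.02 dB
  expect_equal(psnr(x, x + e) - psnr(x, x + 2 * e), 20 * log10(2),
               tolerance = 1e-9)
  expect_equal(psnr(x, x + e, peak = 2) - psnr(x, x + e, peak = 1),
               20 * log10(2), tolerance = 1e-9)
})

test_that("cohort sample metrics report per-frame values and mean/SD", {
  set.seed(30)
  mk <- function(s) rf_frame(matrix(rnorm(64 * 32, sd = s), 64, 32),
                             40, 1540, 0.1)
  orig <- list(mk(1), mk(1), mk(1))
  syn <- lapply(orig, function(r)
    rf_frame(r$samples + matrix(rnorm(64 * 32, sd = 0.05), 64, 32),
             40, 1540, 0.1, provenance = "synthetic"))
  sm <- sample_metrics(orig, syn)
  expect_identical(nrow(sm$per_frame), 3L)
  expect_identical(sm$summary$metric,
                   c("NRMSE", "NMAE", "SSIM_rf", "SSIM_bmode",
                     "PSNR_bmode"))
  expect_equal(sm$summary$mean[1], mean(sm$per_frame$NRMSE))
  expect_true(all(sm$per_frame$NRMSE >= sm$per_frame$NMAE))
  expect_true(all(sm$per_frame$SSIM_rf <= 1))
})

test_that("feature histograms summarize both provenances", {
  set.seed(31)
  orig <- matrix(rnorm(60), 12, 5,
                 dimnames = list(NULL, paste0(c("MBF", "SS", "SI", "ESD",
                                                "EAC"), "-MEAN")))
  syn <- orig + rnorm(60, 0, 0.1)
  fh <- feature_histograms(orig, syn)
  expect_identical(nrow(fh$summary), 10L)  # 5 features x 2 provenances
  expect_length(fh$plots, 5)
  expect_s3_class(fh$plots[[1]], "ggplot")
  row <- fh$summary[fh$summary$feature == "MBF-MEAN" &
                    fh$summary$provenance == "original", ]
  expect_equal(row$mean, mean(orig[, "MBF-MEAN"]))
  same <- feature_histograms(orig, orig)
  expect_equal(same$summary$mean[same$summary$provenance == "original"],
               same$summary$mean[same$summary$provenance == "synthetic"])
})

test_that("UMAP embedding comparison: paired identity gives zero distance
           and a fixed seed reproduces", {
  set.seed(32)
  feats <- matrix(rnorm(30 * 25), 30, 25)
  cmp <- compare_feature_embeddings(feats, feats, seed = 7)
  expect_equal(cmp$umap_mae, 0, tolerance = 1e-6)
  expect_identical(dim(cmp$embedding_original), c(30L, 2L))

  pert <- feats + matrix(rnorm(30 * 25, 0, 0.3), 30, 25)
  c1 <- compare_feature_embeddings(feats, pert, seed = 7)
  c2 <- compare_feature_embeddings(feats, pert, seed = 7)
  expect_equal(c1$umap_mae, c2$umap_mae, tolerance = 1e-8)
  expect_gt(c1$umap_mae, 0)
  # larger perturbations displace the embedding further (in expectation)
  big <- compare_feature_embeddings(feats,
                                    feats + matrix(rnorm(30 * 25, 0, 3),
                                                   30, 25), seed = 7)
  expect_gt(big$umap_mae, c1$umap_mae)
  expect_error(compare_feature_embeddings(feats, feats[1:10, ]),
               "paired")
})
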