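test_that("scatterer counts follow the density x area expectation", {
  scene <- phantom_scene(list(
    acoustic_region("background", a_eff_um = 60, n_per_mm2 = 12)),
    seed = 5)
  field <- sample_scatterer_field(scene, width_mm = 60, depth_mm = 40)
  lambda <- 12 * 60 * 40   # 28,800
  expect_lt(abs(nrow(field) - lambda), 4 * sqrt(lambda))

  zero <- phantom_scene(list(
    acoustic_region("background", a_eff_um = 60, n_per_mm2 = 0)),
    seed = 5)
  expect_identical(nrow(sample_scatterer_field(zero, 10, 10)), 0L)

  again <- sample_scatterer_field(scene, width_mm = 60, depth_mm = 40)
  expect_identical(field, again)

  expect_error(sample_scatterer_field(scene, 0, 10), "field of view")
})

test_that("region override removes background scatterers inside a lesion", {
  geom <- list(type = "ellipse", cx_mm = 5, cz_mm = 5, rx_mm = 2,
               rz_mm = 2)
  scene <- phantom_scene(list(
    acoustic_region("background", a_eff_um = 60, n_per_mm2 = 50),
    acoustic_region(geom, a_eff_um = 40, n_per_mm2 = 50)),
    seed = 9)
  field <- sample_scatterer_field(scene, 10, 10)
  inside <- ((field$x_mm - 5) / 2)^2 + ((field$z_mm - 5) / 2)^2 <= 1
  expect_true(all(field$region[inside] == 2))
  expect_true(all(field$region[!inside] == 1))
})

test_that("a point target echoes at the delay round(2 z fs / c)", {
  p <- pulse_model()
  g <- fov_grid(2048, 8)
  scene <- phantom_scene(list(
    acoustic_region("background", a_eff_um = 50, n_per_mm2 = 1,
                    alpha = 0)), seed = 1)
  field <- data.frame(x_mm = 0.2, z_mm = 20, amp = 1, region = 1)
  rf <- simulate_rf_frame(scene, p, g, field = field)
  env <- rf_envelope(rf)
  line <- which.max(apply(env, 2, max))
  peak0 <- which.max(env[, line]) - 1   # 0-based sample index
  expected <- round(2 * 20e-3 / 1540 * 40e6)
  expect_lte(abs(peak0 - expected), 1)
})

test_that("an empty scatterer field yields an all-zero frame", {
  p <- pulse_model()
  scene <- phantom_scene(list(
    acoustic_region("background", a_eff_um = 50, n_per_mm2 = 0)),
    seed = 1)
  rf <- simulate_rf_frame(scene, p, fov_grid(128, 4))
  expect_true(all(rf$samples == 0))
})

test_that("a lesion outside the field of view is rejected", {
  p <- pulse_model()
  scene <- phantom_scene(list(
    acoustic_region("background", a_eff_um = 60, n_per_mm2 = 10),
    acoustic_region(list(type = "ellipse", cx_mm = 100, cz_mm = 5,
                         rx_mm = 2, rz_mm = 2),
                    a_eff_um = 50, n_per_mm2 = 10)), seed = 1)
  expect_error(simulate_rf_frame(scene, p, fov_grid(128, 16)),
               "outside the field of view")
})

test_that("the reference phantom carries its known acoustic properties", {
  p <- pulse_model()
  ref <- simulate_reference_frame(p, fov_grid(128, 8), seed = 4)
  expect_equal(ref$calibration$alpha, 0.786)
  expect_equal(ref$calibration$speed_of_sound, 1540)
  expect_identical(ref$provenance, "reference")
})

test_that("different reference seeds share the expected spectrum", {
  p <- pulse_model()
  g <- fov_grid(512, 64)
  r1 <- simulate_reference_frame(p, g, alpha = 0, seed = 21)
  r2 <- simulate_reference_frame(p, g, alpha = 0, seed = 22)
  expect_false(identical(r1$samples, r2$samples))
  s1 <- mean_power_spectrum(r1$samples[100:299, ], 40)
  s2 <- mean_power_spectrum(r2$samples[100:299, ], 40)
  band <- s1$f_mhz >= 9 & s1$f_mhz <= 11
  # Monte-Carlo tolerance: 64-line averages of the same ensemble
  expect_lt(mean(abs(s1$power_db[band] - s2$power_db[band])), 1.5)
})

test_that("B-mode formation handles constant, zero, and single-echo input", {
  p <- pulse_model()
  mk <- function(samples) rf_frame(samples, 40, 1540, 0.1)
  zero <- form_bmode(mk(matrix(0, 64, 8)))
  expect_true(all(zero$pixels == 0))

  const <- form_bmode(mk(matrix(1, 64, 8)))  # constant envelope magnitude
  expect_true(all(abs(const$pixels[10:54, ] - 1) < 1e-6))

  g <- fov_grid(2048, 8)
  scene <- phantom_scene(list(
    acoustic_region("background", a_eff_um = 50, n_per_mm2 = 1,
                    alpha = 0)), seed = 1)
  field <- data.frame(x_mm = 0.2, z_mm = 20, amp = 1, region = 1)
  rf <- simulate_rf_frame(scene, p, g, field = field)
  bm30 <- form_bmode(rf, dynamic_range = 30)
  bm60 <- form_bmode(rf, dynamic_range = 60)
  expect_equal(which.max(apply(bm30$pixels, 1, max)),
               round(2 * 20e-3 / 1540 * 40e6) + 1, tolerance = 2)
  # larger dynamic range lifts the compressed floor
  expect_gt(mean(bm60$pixels), mean(bm30$pixels))
})

test_that("B-mode resampling preserves shape contract", {
  rf <- rf_frame(matrix(rnorm(128 * 16), 128, 16), 40, 1540, 0.1)
  bm <- form_bmode(rf, out_shape = c(37, 54))
  expect_identical(dim(bm$pixels), c(37L, 54L))
  expect_true(all(bm$pixels >= 0 & bm$pixels <= 1))
})

test_that("paired dataset counting, determinism, and ground truth", {
  cfg <- dataset_config(n_per_class = 2, planes = 4,
                        grid = fov_grid(256, 64))
  ds <- build_paired_dataset(cfg, seed = 3)
  expect_length(ds$frames, 16)   # 2 classes x 2 lesions x 4 planes
  labs <- vapply(ds$frames, `[[`, character(1), "class_label")
  expect_equal(sum(labs == "benign"), 8)

  ds2 <- build_paired_dataset(cfg, seed = 3)
  expect_identical(ds$frames[[5]]$rf$samples, ds2$frames[[5]]$rf$samples)
  expect_identical(ds$frames[[16]]$bmode$pixels,
                   ds2$frames[[16]]$bmode$pixels)

  # class parameter distributions: benign larger radius than malignant
  a_ben <- vapply(ds$frames[labs == "benign"],
                  function(f) f$truth$a_eff_um, numeric(1))
  a_mal <- vapply(ds$frames[labs == "malignant"],
                  function(f) f$truth$a_eff_um, numeric(1))
  expect_gt(min(a_ben), max(a_mal))
  expect_error(build_paired_dataset(dataset_config(n_per_class = 0)),
               "n_lesions")
})
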