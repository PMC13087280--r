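test_that("ROI margin dilation matches the physical distance oracle", {
  # isotropic 0.02 mm grid so distances are exact: fs with c/(2 fs) = 0.02
  rf <- rf_frame(matrix(0, 560, 560), sampling_rate = 38.5,
                 speed_of_sound = 1540, lateral_pitch = 0.02)
  geom <- list(type = "ellipse", cx_mm = 5.6, cz_mm = 5.6, rx_mm = 2.5,
               rz_mm = 2.5)
  roi <- make_roi_mask(geom, rf, margin_mm = 2.5)
  # distance-transform oracle: combined mask should equal points within
  # 5 mm of the center (circle dilated by its own radius)
  z <- (seq_len(560) - 0.5) * 0.02
  x <- (seq_len(560) - 0.5) * 0.02
  dist <- sqrt(outer((z - 5.6)^2, (x - 5.6)^2, `+`))
  inner <- dist <= 5 - 0.03   # one-pixel guard band
  outer_ <- dist >= 5 + 0.03
  expect_true(all(roi$combined[inner]))
  expect_false(any(roi$combined[outer_]))

  # margin 0 -> combined == core; core touching edge clips without error
  roi0 <- make_roi_mask(geom, rf, margin_mm = 0)
  expect_identical(roi0$combined, roi0$core)
  edge <- make_roi_mask(list(type = "ellipse", cx_mm = 1, cz_mm = 1,
                             rx_mm = 0.9, rz_mm = 0.9), rf, margin_mm = 3)
  expect_true(any(edge$combined[1, ]))
  expect_error(make_roi_mask(matrix(FALSE, 560, 560), rf), "empty")
})

test_that("window tiling follows the step arithmetic", {
  rf <- rf_frame(matrix(0, 560, 560), sampling_rate = 38.5,
                 speed_of_sound = 1540, lateral_pitch = 0.02)
  core <- matrix(FALSE, 560, 560)
  core[31:530, 31:530] <- TRUE   # 10 x 10 mm square ROI
  roi <- make_roi_mask(core, rf, margin_mm = 0)
  wins <- tile_windows(roi, window_mm = 2, overlap = 0.94)
  # step = 6% of 2 mm = 0.12 mm = 6 px; floor((500 - 100)/6) + 1 = 67
  expect_identical(attr(wins, "grid_rows"), 67L)
  expect_identical(attr(wins, "grid_cols"), 67L)
  expect_identical(nrow(wins), 67L * 67L)

  # overlap 0 -> non-overlapping tiling
  w0 <- tile_windows(roi, window_mm = 2, overlap = 0)
  expect_identical(attr(w0, "grid_rows"), 5L)
  expect_true(all(diff(sort(unique(w0$ax0))) == 100))

  # ROI smaller than a window -> empty with warning
  tiny <- matrix(FALSE, 560, 560); tiny[1:20, 1:20] <- TRUE
  roi_t <- make_roi_mask(tiny, rf, margin_mm = 0)
  expect_warning(we <- tile_windows(roi_t, window_mm = 2), "smaller")
  expect_identical(nrow(we), 0L)
})

test_that("mean power spectrum: tone location, gain scaling, flatness", {
  fs <- 40; n <- 256
  t <- (0:(n - 1)) / fs
  tone <- matrix(sin(2 * pi * 5 * t), n, 8)
  sp <- mean_power_spectrum(tone, fs, nfft = 1024)
  expect_equal(sp$f_mhz[which.max(sp$power_db)], 5, tolerance = 0.05)

  set.seed(1)
  noise <- matrix(rnorm(n * 64), n, 64)
  s1 <- mean_power_spectrum(noise, fs, nfft = 1024)
  s2 <- mean_power_spectrum(2 * noise, fs, nfft = 1024)
  expect_equal(s2$power_db - s1$power_db,
               rep(20 * log10(2), length(s1$power_db)), tolerance = 1e-9)

  # white noise: flat within 1.5 dB over the band after line averaging
  set.seed(2)
  big <- mean_power_spectrum(matrix(rnorm(n * 500), n, 500), fs,
                             nfft = 1024)
  band <- big$f_mhz >= 2 & big$f_mhz <= 18
  expect_lt(diff(range(big$power_db[band])), 1.5)

  expect_error(mean_power_spectrum(matrix(0, 64, 1), fs), "2 lines")
  flagged <- mean_power_spectrum(matrix(0, 64, 4), fs)
  expect_true(flagged$flagged)
})

test_that("reference normalization subtracts spectra on a shared grid", {
  set.seed(3)
  x <- matrix(rnorm(128 * 8), 128, 8)
  a <- mean_power_spectrum(x, 40)
  b <- mean_power_spectrum(x * 10^(3 / 20), 40)
  ns <- normalize_spectrum(b, a)
  expect_equal(ns$db, rep(3, length(ns$db)), tolerance = 1e-9)
  expect_equal(normalize_spectrum(a, a)$db, rep(0, length(a$f_mhz)))
  bad <- mean_power_spectrum(x, 40, nfft = 512)
  expect_error(normalize_spectrum(a, bad), "different frequency grids")
})

test_that("point compensation adds the layered round-trip attenuation", {
  f <- seq(1, 10, by = 0.5)
  zero <- correct_attenuation(rep(0, length(f)),
                              data.frame(alpha = 0, path_cm = 2),
                              f_mhz = f)
  expect_equal(zero, rep(0, length(f)))
  one <- correct_attenuation(rep(0, length(f)),
                             data.frame(alpha = 1, path_cm = 1),
                             f_mhz = f)
  expect_equal(one[f == 5], 10)   # 2 * 1 * 5 * 1
  # layered: 2 * (0.5*1 + 1.5*2) * f
  two <- correct_attenuation(rep(0, length(f)),
                             data.frame(alpha = c(0.5, 1.5),
                                        path_cm = c(1, 2)), f_mhz = f)
  expect_equal(two, 2 * 3.5 * f)
  expect_error(correct_attenuation(rep(0, length(f)),
                                   data.frame(alpha = 1, path_cm = -1),
                                   f_mhz = f), "negative")

  # forward decay then compensation is the identity to float tolerance
  base <- rnorm(length(f))
  decayed <- base - 2 * 0.9 * f * 1.7
  back <- correct_attenuation(decayed,
                              data.frame(alpha = 0.9, path_cm = 1.7),
                              f_mhz = f)
  expect_equal(back, base, tolerance = 1e-12)
})

test_that("linear spectral fit recovers closed-form lines exactly", {
  f <- seq(3, 8, by = 0.1)
  flat <- fit_spectral_params(rep(0, length(f)), c(3, 8), f_mhz = f)
  expect_equal(flat$SS, 0); expect_equal(flat$SI, 0)
  expect_equal(flat$MBF, 0)

  lin <- fit_spectral_params(2 * f - 5, c(3, 8), f_mhz = f)
  expect_equal(lin$SS, 2, tolerance = 1e-12)
  expect_equal(lin$SI, -5, tolerance = 1e-12)
  expect_equal(lin$MBF, 2 * 5.5 - 5, tolerance = 1e-12)
  expect_equal(lin$MBF, lin$SS * lin$f_center + lin$SI)  # exact identity

  up <- fit_spectral_params(2 * f - 5 + 3, c(3, 8), f_mhz = f)
  expect_equal(up$SS, lin$SS, tolerance = 1e-12)
  expect_equal(up$SI, lin$SI + 3, tolerance = 1e-12)
  expect_equal(up$MBF, lin$MBF + 3, tolerance = 1e-12)
  expect_error(fit_spectral_params(rep(0, 3), c(3, 8),
                                   f_mhz = c(3, 5, 8)), "5 frequency")
})

test_that("BSC estimation rescales the reference model", {
  cal <- list(a_eff_um = 12, n_per_mm2 = 500, kappa = 1,
              speed_of_sound = 1540)
  f <- seq(4, 10, by = 0.2)
  b0 <- estimate_bsc(rep(0, length(f)), cal, f_mhz = f)
  expect_equal(b0$bsc, bsc_model(f, 12, 500))
  b10 <- estimate_bsc(rep(10, length(f)), cal, f_mhz = f)
  expect_equal(b10$bsc, 10 * b0$bsc, tolerance = 1e-12)
  expect_error(estimate_bsc(rep(0, length(f)), NULL, f_mhz = f),
               "calibration")
})

test_that("Gaussian form-factor fit is exact on model data and robust to
           scaling and noise", {
  f <- seq(3, 12, by = 0.1)
  bsc <- structure(list(f_mhz = f, bsc = bsc_model(f, 50, 300)),
                   class = "backscatter_curve")
  fit <- fit_gaussian_form_factor(bsc, c(3, 12))
  expect_equal(fit$ESD_um, 100, tolerance = 1e-9)
  expect_equal(fit$a_eff_um, 50, tolerance = 1e-9)
  expect_equal(fit$EAC_db, 10 * log10(300), tolerance = 1e-9)
  expect_equal(fit$gaussian_constant, 0.827)

  # scaling: ESD unchanged, EAC + 10 log10(s)
  s <- 25
  bscs <- structure(list(f_mhz = f, bsc = s * bsc$bsc),
                    class = "backscatter_curve")
  fits <- fit_gaussian_form_factor(bscs, c(3, 12))
  expect_equal(fits$ESD_um, fit$ESD_um, tolerance = 1e-9)
  expect_equal(fits$EAC_db - fit$EAC_db, 10 * log10(s),
               tolerance = 1e-9)

  # 5% multiplicative noise, 50 bins: median relative ESD error < 10%
  set.seed(11)
  f50 <- seq(3, 12, length.out = 50)
  errs <- replicate(100, {
    noisy <- structure(list(
      f_mhz = f50,
      bsc = bsc_model(f50, 50, 300) * (1 + rnorm(50, 0, 0.05))),
      class = "backscatter_curve")
    abs(fit_gaussian_form_factor(noisy, c(3, 12))$ESD_um - 100) / 100
  })
  expect_lt(median(errs), 0.10)

  # rising BSC carries no size information -> degenerate flag
  deg <- structure(list(f_mhz = f, bsc = f^4), class = "backscatter_curve")
  dfit <- fit_gaussian_form_factor(deg, c(3, 12))
  expect_true(dfit$degenerate)
  expect_equal(dfit$a_eff_um, 0)
  expect_error(fit_gaussian_form_factor(
    structure(list(f_mhz = f, bsc = -bsc$bsc),
              class = "backscatter_curve"), c(3, 12)), "positive")
})

test_that("spectral-difference ACE recovers known attenuation", {
  f <- seq(3, 10, by = 0.25)
  depths <- seq(1, 2.2, by = 0.2)
  # sample medium identical to the reference -> ACE = alpha_ref
  same <- make_decay_spectra(0.786, 0.786, depths, f)
  expect_equal(estimate_ace(same, depths, c(3, 10))$ACE, 0.786,
               tolerance = 1e-9)
  # alpha = 1.5 recovered within 0.1 dB/MHz/cm
  dec <- make_decay_spectra(1.5, 0.786, depths, f)
  expect_lt(abs(estimate_ace(dec, depths, c(3, 10))$ACE - 1.5), 0.1)

  expect_error(estimate_ace(dec[1:2], depths[1:2], c(3, 10)), "3 depths")
  expect_error(estimate_ace(make_decay_spectra(1, 0.786, c(1, 1.1, 1.2), f),
                            c(1, 1.1, 1.2), c(3, 10)), "0.5 cm")
})

test_that("simulator round trip: homogeneous-frame spectra match the
           backscatter model and ESD/EAC recover the truth", {
  fx <- fix_homog_pair()
  nfft <- 1024
  esds <- c(); resid <- NULL
  for (l0 in seq(1, 200, by = 40)) for (a0 in seq(1, 400, by = 100)) {
    s <- mean_power_spectrum(fx$rf$samples[a0:(a0 + 103), l0:(l0 + 19)],
                             40, nfft)
    r <- mean_power_spectrum(fx$ref$samples[a0:(a0 + 103), l0:(l0 + 19)],
                             40, nfft)
    ns <- normalize_spectrum(s, r)
    bsc <- estimate_bsc(ns, fx$ref$calibration)
    ff <- fit_gaussian_form_factor(bsc, c(8.5, 12.5))
    esds <- c(esds, ff$ESD_um)
    band <- ns$f_mhz >= 8.5 & ns$f_mhz <= 12.5
    model_db <- 10 * log10(bsc_model(ns$f_mhz[band], 75, 500) /
                           bsc_model(ns$f_mhz[band], 12, 500))
    resid <- rbind(resid, ns$db[band] - model_db)
  }
  expect_lt(abs(median(esds) - 150) / 150, 0.10)
  # window-averaged spectral contract: <= 1 dB RMS over the band
  avg <- colMeans(resid)
  expect_lt(sqrt(mean(avg^2)), 1)
})

test_that("RF amplitude gain shifts MBF/SI/EAC by 20 log10(s) and leaves
           SS and ESD unchanged", {
  fx <- fix_homog_pair()
  s <- 3.5
  win <- fx$rf$samples[101:204, 41:80]
  r <- mean_power_spectrum(fx$ref$samples[101:204, 41:80], 40)
  f1 <- mean_power_spectrum(win, 40)
  f2 <- mean_power_spectrum(s * win, 40)
  n1 <- normalize_spectrum(f1, r); n2 <- normalize_spectrum(f2, r)
  band <- c(8.5, 12.5)
  sf1 <- fit_spectral_params(n1, band); sf2 <- fit_spectral_params(n2, band)
  g <- 20 * log10(s)
  expect_equal(sf2$MBF - sf1$MBF, g, tolerance = 1e-9)
  expect_equal(sf2$SI - sf1$SI, g, tolerance = 1e-9)
  expect_equal(sf2$SS, sf1$SS, tolerance = 1e-9)
  ff1 <- fit_gaussian_form_factor(estimate_bsc(n1, fx$ref$calibration),
                                  band)
  ff2 <- fit_gaussian_form_factor(estimate_bsc(n2, fx$ref$calibration),
                                  band)
  expect_equal(ff2$ESD_um, ff1$ESD_um, tolerance = 1e-9)
  expect_equal(ff2$EAC_db - ff1$EAC_db, g, tolerance = 1e-9)
})

test_that("parametric maps: self-normalization nulls, grid bookkeeping,
           and ground-truth contrast", {
  fx <- fix_lesion_maps()
  pm <- fx$maps
  expect_identical(sort(names(pm$maps)),
                   sort(c("MBF", "SS", "SI", "ESD", "EAC")))
  expect_identical(dim(pm$valid), dim(pm$maps$MBF))
  # every tiled window maps to a cell of the shared grid; valid cells are
  # exactly the non-NA map entries
  expect_true(all(pm$windows$row <= nrow(pm$valid) &
                  pm$windows$col <= ncol(pm$valid)))
  expect_identical(sum(pm$valid), sum(!is.na(pm$maps$MBF)))
  expect_lte(sum(pm$valid), nrow(pm$windows))

  # two-region scene: ESD contrast matches ground-truth sign
  core_esd <- mean_value_features(pm, "core")["ESD"]
  margin_esd <- mean_value_features(pm, "margin")["ESD"]
  expect_lt(core_esd, margin_esd)   # 50 um lesion inside 100 um background
  expect_lt(abs(core_esd - 100) / 100, 0.25)

  # sample == reference phantom -> MBF ~ 0 dB, SS ~ 0 map-wide
  p <- fx$pulse
  g2 <- fov_grid(384, 96)
  samp <- simulate_reference_frame(p, g2, seed = 31)
  samp$provenance <- "original"
  ref2 <- simulate_reference_frame(p, g2, seed = 32)
  core <- matrix(FALSE, 384, 96); core[100:300, 20:75] <- TRUE
  roi2 <- make_roi_mask(core, samp, margin_mm = 0)
  pm2 <- build_parametric_maps(samp, ref2, roi2,
                               qus_config(overlap = 0.25,
                                          intervening_alpha = 0.786,
                                          tumor_alpha = 0.786))
  expect_lt(abs(mean(pm2$maps$MBF[pm2$valid])), 1)
  expect_lt(abs(mean(pm2$maps$SS[pm2$valid])), 0.5)
})
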