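#' Mean power spectrum of an RF analysis window
#'
#' Per line: mean subtraction, Hann gating, periodogram (zero-padded FFT);
#' periodograms are averaged across the lines of the window and converted
#' to dB. All-zero windows return the numeric floor and are flagged.
#'
#' @param window Numeric matrix (axial samples x lines, >= 2 lines).
#' @param sampling_rate Sampling rate in MHz.
#' @param nfft FFT length (zero-padded; fixed so all windows share a grid).
#' @return An object of class `mean_power_spectrum` with `f_mhz` (one-sided
#'   uniform grid up to Nyquist), `power_db`, `n_lines`, `flagged`.
#' @export
mean_power_spectrum <- function(window, sampling_rate, nfft = 1024) {
  window <- as.matrix(window)
  if (ncol(window) < 2) stop("analysis window needs at least 2 lines")
  n <- nrow(window)
  if (nfft < n) stop("nfft must be >= window length")
  gate <- as.numeric(signal::hanning(n))
  x <- sweep(window, 2, colMeans(window)) * gate
  xp <- rbind(x, matrix(0, nfft - n, ncol(x)))
  per <- Mod(stats::mvfft(xp))^2 / n
  p <- rowMeans(per)[seq_len(nfft %/% 2 + 1)]
  flagged <- all(p <= 0)
  structure(list(f_mhz = (0:(nfft %/% 2)) * sampling_rate / nfft,
                 power_db = 10 * log10(pmax(p, .Machine$double.xmin)),
                 n_lines = ncol(window), flagged = flagged),
            class = "mean_power_spectrum")
}

#' Normalize a sample spectrum by a reference-phantom spectrum
#'
#' Reference-phantom normalization cancels the system transfer function and
#' beamforming effects: the output is the dB difference of the two mean
#' power spectra computed for the same window geometry.
#'
#' @param sample,reference [mean_power_spectrum()]s on identical frequency
#'   grids.
#' @return An object of class `normalized_spectrum` (`f_mhz`, `db`).
#' @export
normalize_spectrum <- function(sample, reference) {
  if (length(sample$f_mhz) != length(reference$f_mhz) ||
      max(abs(sample$f_mhz - reference$f_mhz)) > 1e-9)
    stop("sample and reference spectra are on different frequency grids")
  structure(list(f_mhz = sample$f_mhz,
                 db = sample$power_db - reference$power_db),
            class = "normalized_spectrum")
}

#' Point-compensation attenuation correction
#'
#' Adds back the round-trip attenuation accumulated over a layered path:
#' `+ 2 sum_i alpha_i f path_i` dB at each frequency (one-way attenuation
#' convention, explicit round-trip factor 2; equivalently a factor 4 in
#' nepers-amplitude terms).
#'
#' @param spectrum A `normalized_spectrum`, or a numeric dB vector.
#' @param layers data.frame or list of rows with `alpha` (dB/MHz/cm) and
#'   `path_cm` (one-way path length, >= 0).
#' @param f_mhz Frequency grid (required when `spectrum` is a bare vector).
#' @return Same type as the input with the compensation added.
#' @export
correct_attenuation <- function(spectrum, layers, f_mhz = NULL) {
  if (inherits(spectrum, "normalized_spectrum")) {
    f <- spectrum$f_mhz; db <- spectrum$db
  } else {
    if (is.null(f_mhz)) stop("f_mhz required for a bare dB vector")
    f <- f_mhz; db <- as.numeric(spectrum)
  }
  layers <- as.data.frame(layers)
  if (nrow(layers) > 0) {
    if (any(layers$path_cm < 0)) stop("negative attenuation path")
    total <- sum(layers$alpha * layers$path_cm)   # dB/MHz, one-way
    db <- db + 2 * total * f
  }
  if (inherits(spectrum, "normalized_spectrum"))
    structure(list(f_mhz = f, db = db), class = "normalized_spectrum")
  else db
}

#' Linear spectral fit: mid-band fit, spectral slope, spectral intercept
#'
#' Ordinary least squares of the corrected normalized spectrum (dB) on
#' frequency over the analysis band. SS is the slope (dB/MHz), SI the
#' intercept at f = 0 (dB), and MBF the fitted value at the band center,
#' so `MBF = SS f_center + SI` holds exactly.
#'
#' @param spectrum A `normalized_spectrum` or dB vector.
#' @param band `c(f_lo, f_hi)` in MHz.
#' @param f_mhz Frequency grid when `spectrum` is a bare vector.
#' @return A list of class `spectral_fit`: `MBF`, `SS`, `SI`, `f_center`,
#'   `band`, `r2`.
#' @export
fit_spectral_params <- function(spectrum, band, f_mhz = NULL) {
  if (inherits(spectrum, "normalized_spectrum")) {
    f <- spectrum$f_mhz; db <- spectrum$db
  } else { f <- f_mhz; db <- as.numeric(spectrum) }
  sel <- f >= band[1] & f <= band[2]
  if (sum(sel) < 5) stop("need at least 5 frequency bins in the band")
  fit <- stats::lm.fit(cbind(1, f[sel]), db[sel])
  ss <- unname(fit$coefficients[2]); si <- unname(fit$coefficients[1])
  fc <- mean(band)
  tss <- sum((db[sel] - mean(db[sel]))^2)
  r2 <- if (tss > 0) 1 - sum(fit$residuals^2) / tss else 1
  structure(list(MBF = ss * fc + si, SS = ss, SI = si, f_center = fc,
                 band = band, r2 = r2),
            class = "spectral_fit")
}

#' Backscatter coefficient from a corrected normalized spectrum
#'
#' `BSC_sample(f) = BSC_ref(f) 10^(corrected_dB / 10)` where the reference
#' BSC comes from the phantom's known microstructure via [bsc_model()].
#'
#' @param spectrum Corrected `normalized_spectrum` (or dB vector with
#'   `f_mhz`).
#' @param calibration Reference calibration list (`a_eff_um`, `n_per_mm2`,
#'   `kappa`, `speed_of_sound`), e.g. from a reference frame.
#' @param f_mhz Frequency grid for a bare vector.
#' @return List of class `backscatter_curve`: `f_mhz`, `bsc`.
#' @export
estimate_bsc <- function(spectrum, calibration, f_mhz = NULL) {
  if (is.null(calibration)) stop("missing reference calibration")
  if (inherits(spectrum, "normalized_spectrum")) {
    f <- spectrum$f_mhz; db <- spectrum$db
  } else { f <- f_mhz; db <- as.numeric(spectrum) }
  ref <- bsc_model(f, calibration$a_eff_um, calibration$n_per_mm2,
                   calibration$kappa, calibration$speed_of_sound)
  structure(list(f_mhz = f, bsc = ref * 10^(db / 10)),
            class = "backscatter_curve")
}

#' Fit the spherical Gaussian form factor to a backscatter curve
#'
#' Linearized fit: `y(f) = ln BSC - 4 ln f` is regressed on `f^2`; the
#' slope gives the effective radius via
#' `a_eff = sqrt(-b1 c^2 / (0.827 4 pi^2))` (with the MHz/Hz unit factor
#' handled explicitly), ESD = 2 a_eff, and the intercept gives the
#' effective acoustic concentration `EAC = 10 log10(n_est)` after removing
#' the frequency-unit constant. A non-negative slope means the data carry
#' no resolvable size information; the fit is flagged degenerate with
#' `a_eff = 0`.
#'
#' @param bsc A `backscatter_curve` (positive on the band).
#' @param band `c(f_lo, f_hi)` MHz.
#' @param speed_of_sound m/s.
#' @param kappa Model constant (must match the calibration convention).
#' @return List of class `form_factor_fit`: `a_eff_um`, `ESD_um`, `EAC_db`,
#'   `kappa`, `gaussian_constant`, `band`, `residual`, `degenerate`.
#' @export
fit_gaussian_form_factor <- function(bsc, band, speed_of_sound = 1540,
                                     kappa = 1) {
  sel <- bsc$f_mhz >= band[1] & bsc$f_mhz <= band[2]
  f <- bsc$f_mhz[sel]; b <- bsc$bsc[sel]
  if (any(b <= 0)) stop("BSC must be positive over the fit band")
  if (length(f) < 3) stop("need at least 3 bins in the fit band")
  y <- log(b) - 4 * log(f)
  fit <- stats::lm.fit(cbind(1, f^2), y)
  b0 <- unname(fit$coefficients[1]); b1 <- unname(fit$coefficients[2])
  kconst <- 2 * pi * 1e6 / speed_of_sound        # k = kconst * f_mhz
  if (b1 >= 0) {
    return(structure(list(a_eff_um = 0, ESD_um = 0, EAC_db = NA_real_,
                          kappa = kappa, gaussian_constant = 0.827,
                          band = band,
                          residual = sqrt(mean(fit$residuals^2)),
                          degenerate = TRUE),
                     class = "form_factor_fit"))
  }
  a_m <- sqrt(-b1 / (0.827 * kconst^2))
  n_est <- exp(b0 - 4 * log(kconst)) / (kappa * a_m^6)
  structure(list(a_eff_um = a_m * 1e6, ESD_um = 2 * a_m * 1e6,
                 EAC_db = 10 * log10(n_est), kappa = kappa,
                 gaussian_constant = 0.827, band = band,
                 residual = sqrt(mean(fit$residuals^2)),
                 degenerate = FALSE),
            class = "form_factor_fit")
}

#' Attenuation coefficient estimate by the spectral difference method
#'
#' For each frequency in the band, the rate of change of the normalized
#' spectrum with depth is measured by least squares; the per-frequency
#' sample attenuation is `alpha_s(f) = alpha_ref - m(f) / (2 f)` (dB/MHz/cm,
#' one-way, round-trip factor 2 explicit), and the band-averaged ACE is the
#' slope of the regression of `alpha_s(f) f` on `f`.
#'
#' @param spectra List of `normalized_spectrum`s at increasing depths
#'   (>= 3).
#' @param depths_cm Window-center depths in cm (span >= 0.5 cm).
#' @param band `c(f_lo, f_hi)` MHz.
#' @param alpha_ref Reference-phantom attenuation in dB/MHz/cm.
#' @param r2_threshold Flag the estimate when the final regression r^2
#'   falls below this value.
#' @return List of class `attenuation_estimate`: `ACE` (dB/MHz/cm),
#'   `alpha_f` (per-frequency estimates), `f_mhz`, `r2`, `flagged`.
#' @export
estimate_ace <- function(spectra, depths_cm, band, alpha_ref = 0.786,
                         r2_threshold = 0.1) {
  if (length(spectra) < 3) stop("need normalized spectra at >= 3 depths")
  if (diff(range(depths_cm)) < 0.5)
    stop("depth span must be at least 0.5 cm")
  f <- spectra[[1]]$f_mhz
  sel <- f >= band[1] & f <= band[2]
  mat <- vapply(spectra, function(s) s$db[sel], numeric(sum(sel)))
  # per-frequency depth slope m(f) in dB/cm
  X <- cbind(1, depths_cm)
  coefs <- t(qr.coef(qr(X), t(mat)))
  m_f <- coefs[, 2]
  fb <- f[sel]
  alpha_f <- alpha_ref - m_f / (2 * fb)
  fit <- stats::lm.fit(cbind(1, fb), alpha_f * fb)
  ace <- unname(fit$coefficients[2])
  tss <- sum((alpha_f * fb - mean(alpha_f * fb))^2)
  r2 <- if (tss > 0) 1 - sum(fit$residuals^2) / tss else 1
  structure(list(ACE = ace, alpha_f = alpha_f, f_mhz = fb, r2 = r2,
                 flagged = !is.finite(ace) || r2 < r2_threshold),
            class = "attenuation_estimate")
}
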