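#' Transmit pulse and acquisition model
#'
#' Describes the imaging system used for both simulation and spectral
#' analysis: a Gaussian-envelope transmit pulse plus the digitizer geometry.
#' The default mirrors a linear-array acquisition with a 10 MHz nominal
#' center frequency sampled at 40 MHz in tissue with a speed of sound of
#' 1540 m/s.
#'
#' @param center_frequency Pulse center frequency in MHz.
#' @param fractional_bandwidth Fractional -6 dB bandwidth of the Gaussian
#'   amplitude spectrum, in (0, 1].
#' @param sampling_rate RF sampling rate in MHz. Must exceed twice the
#'   center frequency.
#' @param speed_of_sound Speed of sound in m/s.
#' @return An object of class `pulse_model`.
#' @examples
#' p <- pulse_model()
#' axial_pitch_mm(p)  # c / (2 fs), in mm
#' @export
pulse_model <- function(center_frequency = 10, fractional_bandwidth = 0.6,
                        sampling_rate = 40, speed_of_sound = 1540) {
  stopifnot(center_frequency > 0, sampling_rate > 0, speed_of_sound > 0)
  if (center_frequency >= sampling_rate / 2)
    stop("center_frequency must be below Nyquist (sampling_rate/2)")
  if (fractional_bandwidth <= 0 || fractional_bandwidth > 1)
    stop("fractional_bandwidth must lie in (0, 1]")
  structure(list(center_frequency = center_frequency,
                 fractional_bandwidth = fractional_bandwidth,
                 sampling_rate = sampling_rate,
                 speed_of_sound = speed_of_sound),
            class = "pulse_model")
}

#' Axial sample pitch implied by a pulse model
#'
#' @param pulse A [pulse_model()].
#' @return Axial pitch c/(2 fs) in mm per sample.
#' @export
axial_pitch_mm <- function(pulse) {
  # c [m/s] / (2 * fs [MHz] * 1e6) -> m, *1e3 -> mm
  pulse$speed_of_sound / (2 * pulse$sampling_rate * 1e6) * 1e3
}

#' Gaussian pulse amplitude spectrum
#'
#' Amplitude spectrum of the transmit pulse on a frequency grid; the -6 dB
#' amplitude points sit at f0 * (1 +/- bw/2).
#'
#' @param pulse A [pulse_model()].
#' @param f_mhz Frequency grid in MHz (non-negative).
#' @return Numeric vector of amplitudes (peak 1 at the center frequency).
#' @export
pulse_spectrum <- function(pulse, f_mhz) {
  half_width <- pulse$fractional_bandwidth * pulse$center_frequency / 2
  sigma <- half_width / sqrt(2 * log(2))   # |A| = 0.5 at f0 +/- half_width
  exp(-(f_mhz - pulse$center_frequency)^2 / (2 * sigma^2))
}

#' Raw radiofrequency frame
#'
#' Container for one RF echo frame: a matrix of echo samples
#' (axial samples x scan lines) plus the acquisition geometry needed to map
#' samples to physical depth and lines to lateral position.
#'
#' @param samples Numeric matrix, axial samples x scan lines; finite values.
#' @param sampling_rate Sampling rate in MHz.
#' @param speed_of_sound Speed of sound in m/s.
#' @param lateral_pitch Lateral line spacing in mm per line.
#' @param provenance One of `"original"`, `"synthetic"`, `"reference"`.
#' @param calibration Optional list of known acoustic properties (used for
#'   reference frames): `alpha` (dB/MHz/cm), `a_eff_um`, `n_per_mm2`,
#'   `kappa`.
#' @return An object of class `rf_frame`.
#' @export
rf_frame <- function(samples, sampling_rate, speed_of_sound,
                     lateral_pitch,
                     provenance = c("original", "synthetic", "reference"),
                     calibration = NULL) {
  provenance <- match.arg(provenance)
  samples <- as.matrix(samples)
  if (!all(is.finite(samples))) stop("rf_frame samples must be finite")
  stopifnot(sampling_rate > 0, speed_of_sound > 0, lateral_pitch > 0)
  structure(list(samples = samples,
                 sampling_rate = sampling_rate,
                 speed_of_sound = speed_of_sound,
                 lateral_pitch = lateral_pitch,
                 provenance = provenance,
                 calibration = calibration),
            class = "rf_frame")
}

#' @export
print.rf_frame <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("<rf_frame> %d axial samples x %d lines (%s)\n",
              d[1], d[2], x$provenance))
  cat(sprintf("  fs = %g MHz, c = %g m/s, depth = %.2f mm, width = %.2f mm\n",
              x$sampling_rate, x$speed_of_sound,
              d[1] * x$speed_of_sound / (2 * x$sampling_rate * 1e6) * 1e3,
              d[2] * x$lateral_pitch))
  invisible(x)
}

#' Frame depth and width in mm
#' @param rf An [rf_frame()].
#' @return Named vector `c(depth_mm, width_mm)`.
#' @export
frame_extent_mm <- function(rf) {
  pitch <- rf$speed_of_sound / (2 * rf$sampling_rate * 1e6) * 1e3
  c(depth_mm = nrow(rf$samples) * pitch,
    width_mm = ncol(rf$samples) * rf$lateral_pitch)
}

#' B-mode image
#'
#' Log-compressed envelope raster covering the same physical extent as its
#' source RF frame.
#'
#' @param pixels Matrix of pixel values in `[0, 1]`.
#' @param dynamic_range Displayed dynamic range in dB.
#' @param extent_mm Named vector `c(depth_mm, width_mm)` mapping the raster
#'   to RF coordinates.
#' @return An object of class `bmode_image`.
#' @export
bmode_image <- function(pixels, dynamic_range, extent_mm) {
  pixels <- as.matrix(pixels)
  if (min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9)
    stop("bmode pixels must lie in [0, 1]")
  structure(list(pixels = pixels, dynamic_range = dynamic_range,
                 extent_mm = extent_mm),
            class = "bmode_image")
}

#' @export
print.bmode_image <- function(x, ...) {
  cat(sprintf("<bmode_image> %d x %d, %g dB dynamic range\n",
              nrow(x$pixels), ncol(x$pixels), x$dynamic_range))
  invisible(x)
}
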