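
# Analytic signal per column via the frequency-domain Hilbert construction:
# double positive frequencies, zero negative ones.
analytic_signal <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n
}

#' Envelope of an RF frame
#'
#' Magnitude of the per-line analytic signal.
#'
#' @param rf An [rf_frame()] or a numeric matrix (axial x lines).
#' @return Matrix of envelope values, same shape as the input samples.
#' @export
rf_envelope <- function(rf) {
  x <- if (inherits(rf, "rf_frame")) rf$samples else as.matrix(rf)
  Mod(analytic_signal(x))
}

#' Form a B-mode image from an RF frame
#'
#' Envelope detection (per-line analytic signal), log compression to
#' `[-dynamic_range, 0]` dB relative to the frame maximum, rescaling to
#' `[0, 1]`, and optional bilinear resampling to a display raster. An
#' all-zero frame maps to an all-zero image (no log-domain failure).
#'
#' @param rf An [rf_frame()].
#' @param dynamic_range Displayed dynamic range in dB.
#' @param out_shape Optional `c(rows, cols)` display size; `NULL` keeps the
#'   RF grid.
#' @return A [bmode_image()].
#' @export
form_bmode <- function(rf, dynamic_range = 50, out_shape = NULL) {
  stopifnot(inherits(rf, "rf_frame"), dynamic_range > 0)
  env <- rf_envelope(rf)
  peak <- max(env)
  if (peak <= 0) {
    img <- matrix(0, nrow(env), ncol(env))
  } else {
    db <- 20 * log10(pmax(env / peak, 10^(-dynamic_range / 20 - 2)))
    img <- pmax(db, -dynamic_range) / dynamic_range + 1
  }
  if (!is.null(out_shape))
    img <- resize_bilinear(img, out_shape[1], out_shape[2])
  bmode_image(pmin(pmax(img, 0), 1), dynamic_range, frame_extent_mm(rf))
}

# Bilinear resize backed by EBImage; EBImage images are (x, y) indexed so
# the matrix is transposed in and out.
resize_bilinear <- function(mat, rows, cols) {
  if (rows <= 0 || cols <= 0) stop("target shape must be positive")
  if (rows == nrow(mat) && cols == ncol(mat)) return(mat)
  t(EBImage::resize(EBImage::Image(t(mat)), w = cols, h = rows,
                    filter = "bilinear")@.Data)
}
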