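#' Normalized error metrics
#'
#' RMSE / MAE between a candidate and a reference, divided by the
#' reference dynamic range and expressed in percent. The dynamic range
#' defaults to the range of the reference argument; pass `dynamic_range`
#' explicitly to normalize by a cohort-global range.
#'
#' @param reference,candidate Numeric arrays of identical shape.
#' @param dynamic_range Normalizing range (reference global max - min).
#' @return Percent error (scalar).
#' @export
nrmse <- function(reference, candidate, dynamic_range = NULL) {
  check_pair(reference, candidate)
  dr <- if (is.null(dynamic_range)) diff(range(reference)) else dynamic_range
  if (dr <= 0) stop("zero dynamic range")
  sqrt(mean((candidate - reference)^2)) / dr * 100
}

#' @rdname nrmse
#' @export
nmae <- function(reference, candidate, dynamic_range = NULL) {
  check_pair(reference, candidate)
  dr <- if (is.null(dynamic_range)) diff(range(reference)) else dynamic_range
  if (dr <= 0) stop("zero dynamic range")
  mean(abs(candidate - reference)) / dr * 100
}

check_pair <- function(a, b) {
  if (!identical(dim(as.matrix(a)), dim(as.matrix(b))))
    stop("reference and candidate must share shape")
  invisible(NULL)
}

# 1-D Gaussian kernel with the 11-tap support used by the standard SSIM
# window (sigma 1.5, truncated at 5 samples).
ssim_kernel <- function(sigma = 1.5, radius = 5L) {
  k <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable filtering with nearest (replicate) boundary handling.
filter_sep <- function(x, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(x); m <- ncol(x)
  xp <- x[c(rep(1, r), seq_len(n), rep(n, r)), , drop = FALSE]
  y <- matrix(0, n, m)
  for (i in seq_along(k)) y <- y + k[i] * xp[(i - 1) + seq_len(n), ,
                                             drop = FALSE]
  yp <- y[, c(rep(1, r), seq_len(m), rep(m, r)), drop = FALSE]
  z <- matrix(0, n, m)
  for (i in seq_along(k)) z <- z + k[i] * yp[, (i - 1) + seq_len(m),
                                             drop = FALSE]
  z
}

#' Structural similarity index
#'
#' Standard SSIM with an 11 x 11 Gaussian weighting window (sigma 1.5),
#' K1 = 0.01, K2 = 0.03, averaged over the map after cropping the filter
#' support from the borders.
#'
#' @param reference,candidate Images of identical shape (larger than the
#'   11 x 11 window).
#' @param data_range Value range of the data (1 for normalized images).
#' @return Mean SSIM (scalar in `[-1, 1]`).
#' @export
ssim <- function(reference, candidate, data_range = 1) {
  check_pair(reference, candidate)
  x <- as.matrix(reference); y <- as.matrix(candidate)
  if (nrow(x) < 11 || ncol(x) < 11)
    stop("images must be at least 11 x 11 for the SSIM window")
  stopifnot(data_range > 0)
  k <- ssim_kernel()
  c1 <- (0.01 * data_range)^2; c2 <- (0.03 * data_range)^2
  mx <- filter_sep(x, k); my <- filter_sep(y, k)
  sxx <- filter_sep(x * x, k) - mx^2
  syy <- filter_sep(y * y, k) - my^2
  sxy <- filter_sep(x * y, k) - mx * my
  s <- ((2 * mx * my + c1) * (2 * sxy + c2)) /
    ((mx^2 + my^2 + c1) * (sxx + syy + c2))
  r <- 5L
  mean(s[(r + 1):(nrow(s) - r), (r + 1):(ncol(s) - r)])
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)` in dB; identical inputs return `Inf`.
#'
#' @param reference,candidate Images of identical shape.
#' @param peak Peak signal value (1 for normalized, 255 for 8-bit).
#' @return PSNR in dB.
#' @export
psnr <- function(reference, candidate, peak = 1) {
  check_pair(reference, candidate)
  mse <- mean((candidate - reference)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Sample-level fidelity metrics for a cohort of synthetic frames
#'
#' Per frame: NRMSE and NMAE of the denormalized synthetic RF (normalized
#' by the cohort-global RF dynamic range), SSIM of the RF pair, and SSIM /
#' PSNR of the B-mode images reconstructed from the synthetic RF.
#'
#' @param originals,synthetics Lists of [rf_frame()]s paired by position.
#' @param dynamic_range_db B-mode dynamic range used for reconstruction.
#' @return List with `per_frame` (data.frame) and `summary`
#'   (mean and SD per metric).
#' @export
sample_metrics <- function(originals, synthetics, dynamic_range_db = 50) {
  stopifnot(length(originals) == length(synthetics),
            length(originals) >= 1)
  global_rng <- range(vapply(originals, function(r) range(r$samples),
                             numeric(2)))
  dr <- diff(global_rng)
  rows <- lapply(seq_along(originals), function(i) {
    o <- originals[[i]]$samples; s <- synthetics[[i]]$samples
    bo <- form_bmode(originals[[i]], dynamic_range_db)$pixels
    bs <- form_bmode(synthetics[[i]], dynamic_range_db)$pixels
    data.frame(
      frame = i,
      NRMSE = nrmse(o, s, dr),
      NMAE = nmae(o, s, dr),
      SSIM_rf = ssim(o, s, data_range = dr),
      SSIM_bmode = ssim(bo, bs, data_range = 1),
      PSNR_bmode = psnr(bo, bs, peak = 1))
  })
  per_frame <- do.call(rbind, rows)
  met <- per_frame[, -1, drop = FALSE]
  summary <- data.frame(metric = names(met),
                        mean = vapply(met, mean, numeric(1)),
                        sd = vapply(met, stats::sd, numeric(1)),
                        row.names = NULL)
  list(per_frame = per_frame, summary = summary)
}
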