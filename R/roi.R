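#' Build an ROI mask (tumor core + margin band) on the RF grid
#'
#' The core is rasterized from an ellipse geometry (or taken as a logical
#' matrix) and dilated by a physical distance to form the margin band.
#' Dilation uses an elliptical structuring element expressed in pixels, so
#' the anisotropic RF grid (fine axially, coarse laterally) is handled in
#' physical units; the band is clipped at the frame boundary without error.
#'
#' @param core Either a geometry list
#'   (`list(type = "ellipse", cx_mm =, cz_mm =, rx_mm =, rz_mm =)`) or a
#'   logical matrix on the RF grid.
#' @param rf The [rf_frame()] supplying the grid geometry.
#' @param margin_mm Width of the margin band in mm (default 5).
#' @return An object of class `roi_mask` with logical matrices `core`,
#'   `margin` (band only), `combined`, and the grid pitches.
#' @export
make_roi_mask <- function(core, rf, margin_mm = 5) {
  pitch_ax <- rf$speed_of_sound / (2 * rf$sampling_rate * 1e6) * 1e3
  pitch_lat <- rf$lateral_pitch
  n_ax <- nrow(rf$samples); n_ln <- ncol(rf$samples)
  if (is.matrix(core)) {
    core_mask <- core > 0
    if (!identical(dim(core_mask), dim(rf$samples)))
      stop("core mask must match the RF grid")
  } else {
    stopifnot(core$type == "ellipse")
    z <- (seq_len(n_ax) - 0.5) * pitch_ax
    x <- (seq_len(n_ln) - 0.5) * pitch_lat
    core_mask <- outer(z, x, function(zz, xx)
      ((xx - core$cx_mm) / core$rx_mm)^2 +
      ((zz - core$cz_mm) / core$rz_mm)^2 <= 1)
  }
  if (!any(core_mask)) stop("empty ROI core")
  combined <- if (margin_mm > 0)
    dilate_mm(core_mask, margin_mm, pitch_ax, pitch_lat) else core_mask
  structure(list(core = core_mask, margin = combined & !core_mask,
                 combined = combined,
                 pitch_ax_mm = pitch_ax, pitch_lat_mm = pitch_lat,
                 margin_mm = margin_mm),
            class = "roi_mask")
}

# Morphological dilation by a physical radius on an anisotropic grid,
# implemented as an FFT convolution with an elliptical kernel followed by
# thresholding. Exact to within one pixel.
dilate_mm <- function(mask, radius_mm, pitch_ax, pitch_lat) {
  ra <- max(1L, as.integer(ceiling(radius_mm / pitch_ax)))
  rl <- max(1L, as.integer(ceiling(radius_mm / pitch_lat)))
  kz <- (-ra:ra) * pitch_ax
  kx <- (-rl:rl) * pitch_lat
  kern <- outer(kz, kx, function(z, x) (z^2 + x^2) <= radius_mm^2) * 1
  n1 <- stats::nextn(nrow(mask) + nrow(kern) - 1, c(2, 3, 5))
  n2 <- stats::nextn(ncol(mask) + ncol(kern) - 1, c(2, 3, 5))
  pad <- function(m) { out <- matrix(0, n1, n2)
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m; out }
  conv <- Re(stats::fft(stats::fft(pad(mask * 1)) * stats::fft(pad(kern)),
                        inverse = TRUE)) / (n1 * n2)
  off_a <- ra; off_l <- rl   # kernel center offset
  full <- conv[off_a + seq_len(nrow(mask)), off_l + seq_len(ncol(mask))]
  full > 0.5
}

#' Tile sliding analysis windows over an ROI
#'
#' Windows of a fixed physical size step across the combined (core +
#' margin) mask with the requested fractional overlap; a window is kept
#' when its center pixel lies inside the mask. Windows whose footprint
#' would spill outside the frame are shifted inward and flagged.
#'
#' @param roi A [make_roi_mask()] result.
#' @param window_mm Window side length in mm (axial and lateral).
#' @param overlap Fractional overlap in both directions (e.g. 0.94 means
#'   the step is 6% of the window size).
#' @return A data.frame of windows (`ax0`, `ax1`, `ln0`, `ln1`,
#'   `center_ax`, `center_ln`, `z_cm`, `row`, `col`, `in_core`,
#'   `clamped`), with attributes `grid_rows`/`grid_cols` giving the
#'   window-center grid shape. Empty (with a warning) when the mask cannot
#'   hold one window.
#' @export
tile_windows <- function(roi, window_mm = 2, overlap = 0.94) {
  stopifnot(overlap >= 0, overlap < 1)
  win_ax <- max(2L, as.integer(round(window_mm / roi$pitch_ax_mm)))
  win_ln <- max(2L, as.integer(round(window_mm / roi$pitch_lat_mm)))
  step_ax <- max(1L, as.integer(round(win_ax * (1 - overlap))))
  step_ln <- max(1L, as.integer(round(win_ln * (1 - overlap))))
  idx <- which(roi$combined, arr.ind = TRUE)
  bb <- c(min(idx[, 1]), max(idx[, 1]), min(idx[, 2]), max(idx[, 2]))
  n_ax <- nrow(roi$combined); n_ln <- ncol(roi$combined)
  span_ax <- bb[2] - bb[1] + 1; span_ln <- bb[4] - bb[3] + 1
  if (span_ax < win_ax || span_ln < win_ln) {
    warning("ROI smaller than one analysis window; no windows tiled")
    return(data.frame())
  }
  ax_starts <- seq(bb[1], bb[2] - win_ax + 1, by = step_ax)
  ln_starts <- seq(bb[3], bb[4] - win_ln + 1, by = step_ln)
  out <- vector("list", length(ax_starts) * length(ln_starts))
  kk <- 0
  for (j in seq_along(ln_starts)) for (i in seq_along(ax_starts)) {
    a0 <- ax_starts[i]; l0 <- ln_starts[j]
    clamped <- FALSE
    if (a0 + win_ax - 1 > n_ax) { a0 <- n_ax - win_ax + 1; clamped <- TRUE }
    if (l0 + win_ln - 1 > n_ln) { l0 <- n_ln - win_ln + 1; clamped <- TRUE }
    ca <- a0 + win_ax %/% 2; cl <- l0 + win_ln %/% 2
    if (!roi$combined[ca, cl]) next
    kk <- kk + 1
    out[[kk]] <- data.frame(
      ax0 = a0, ax1 = a0 + win_ax - 1L, ln0 = l0, ln1 = l0 + win_ln - 1L,
      center_ax = ca, center_ln = cl,
      z_cm = ca * roi$pitch_ax_mm / 10,
      row = i, col = j,
      in_core = roi$core[ca, cl], clamped = clamped)
  }
  if (kk == 0) {
    warning("no window centers inside the ROI mask")
    return(data.frame())
  }
  res <- do.call(rbind, out[seq_len(kk)])
  attr(res, "grid_rows") <- length(ax_starts)
  attr(res, "grid_cols") <- length(ln_starts)
  attr(res, "win_ax") <- win_ax
  attr(res, "win_ln") <- win_ln
  res
}
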