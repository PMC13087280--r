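#' QUS analysis configuration
#'
#' @param window_mm Analysis window side length in mm.
#' @param overlap Fractional window overlap in both directions.
#' @param band_mhz Absolute analysis band limits in MHz; the effective band
#'   is this interval intersected with the -6 dB bandwidth of the reference
#'   spectrum.
#' @param nfft FFT length for the common spectral grid.
#' @param intervening_alpha One-way attenuation prior for the tissue above
#'   the ROI, in dB/MHz/cm.
#' @param tumor_alpha Prior used for the tumor layer when ACE estimation is
#'   disabled (or fails).
#' @param estimate_ace Estimate the tumor attenuation from core windows
#'   (spectral difference method) instead of using `tumor_alpha`.
#' @param min_lines Minimum number of lines per window.
#' @return A config list.
#' @export
qus_config <- function(window_mm = 2, overlap = 0.94,
                       band_mhz = c(3, 13), nfft = 1024,
                       intervening_alpha = 1.0, tumor_alpha = 1.0,
                       estimate_ace = FALSE, min_lines = 2) {
  list(window_mm = window_mm, overlap = overlap, band_mhz = band_mhz,
       nfft = nfft, intervening_alpha = intervening_alpha,
       tumor_alpha = tumor_alpha, estimate_ace = estimate_ace,
       min_lines = min_lines)
}

# Analysis band: -6 dB bandwidth of a reference spectrum intersected with
# the configured absolute band.
analysis_band <- function(ref_spectrum, band_mhz) {
  db <- ref_spectrum$power_db
  f <- ref_spectrum$f_mhz
  keep <- db >= max(db) - 6
  f6 <- range(f[keep])
  lo <- max(band_mhz[1], f6[1]); hi <- min(band_mhz[2], f6[2])
  if (hi <= lo) stop("empty analysis band (reference bandwidth does not ",
                     "overlap the configured band)")
  c(lo, hi)
}

#' Build the five QUS parametric maps for one frame
#'
#' Full sliding-window composition: for every analysis window inside the
#' ROI (core + margin), the mean power spectrum of the sample frame is
#' normalized by the reference-phantom spectrum for the same window,
#' attenuation-corrected with a two-layer point-compensation model
#' (intervening tissue above the ROI top, tumor below), and summarized by
#' the linear spectral fit (MBF, SS, SI) and the Gaussian form-factor fit
#' (ESD, EAC). Values are assigned at window centers; maps share one grid
#' and one validity mask.
#'
#' @param rf Sample [rf_frame()].
#' @param ref Reference [rf_frame()] with calibration metadata, same
#'   geometry as `rf`.
#' @param roi A [make_roi_mask()] result on the same grid.
#' @param config A [qus_config()].
#' @return An object of class `parametric_maps`: `maps` (named list of
#'   matrices MBF, SS, SI, ESD, EAC on the window-center grid), `valid`
#'   (logical matrix), `windows` (the tiling), `band`, `ace`, and the
#'   window geometry.
#' @export
build_parametric_maps <- function(rf, ref, roi, config = qus_config()) {
  if (!identical(dim(rf$samples), dim(ref$samples)))
    stop("sample and reference frames must share geometry")
  if (is.null(ref$calibration))
    stop("reference frame carries no calibration metadata")
  wins <- tile_windows(roi, config$window_mm, config$overlap)
  if (nrow(wins) == 0) stop("no valid analysis windows in the ROI")
  cal <- ref$calibration
  fs <- rf$sampling_rate

  spectra <- vector("list", nrow(wins))
  ref_spectra <- vector("list", nrow(wins))
  for (i in seq_len(nrow(wins))) {
    w <- wins[i, ]
    spectra[[i]] <- mean_power_spectrum(
      rf$samples[w$ax0:w$ax1, w$ln0:w$ln1], fs, config$nfft)
    ref_spectra[[i]] <- mean_power_spectrum(
      ref$samples[w$ax0:w$ax1, w$ln0:w$ln1], fs, config$nfft)
  }
  band <- analysis_band(ref_spectra[[which.max(wins$in_core)]],
                        config$band_mhz)
  norm <- Map(normalize_spectrum, spectra, ref_spectra)

  # ROI top depth (cm): boundary between the intervening layer and tumor
  z_top_cm <- (min(which(apply(roi$combined, 1, any))) - 1) *
    roi$pitch_ax_mm / 10

  ace <- NULL
  tumor_alpha <- config$tumor_alpha
  if (config$estimate_ace) {
    core_idx <- which(wins$in_core)
    if (length(core_idx) >= 3 &&
        diff(range(wins$z_cm[core_idx])) >= 0.5) {
      # depth-bin the core windows and average normalized spectra per bin
      zc <- wins$z_cm[core_idx]
      bins <- cut(zc, breaks = max(3, min(8, length(unique(zc)))),
                  labels = FALSE)
      sp_bin <- list(); z_bin <- numeric(0)
      for (b in sort(unique(bins))) {
        members <- core_idx[bins == b]
        db_avg <- rowMeans(vapply(norm[members], `[[`,
                                  numeric(length(norm[[1]]$db)), "db"))
        sp_bin[[length(sp_bin) + 1]] <- structure(
          list(f_mhz = norm[[1]]$f_mhz, db = db_avg),
          class = "normalized_spectrum")
        z_bin <- c(z_bin, mean(wins$z_cm[members]))
      }
      if (length(sp_bin) >= 3 && diff(range(z_bin)) >= 0.5) {
        ace <- estimate_ace(sp_bin, z_bin, band, alpha_ref = cal$alpha)
        if (!ace$flagged) tumor_alpha <- ace$ACE
      }
    }
  }

  nr <- attr(wins, "grid_rows"); nc <- attr(wins, "grid_cols")
  maps <- lapply(stats::setNames(vector("list", 5),
                                 c("MBF", "SS", "SI", "ESD", "EAC")),
                 function(x) matrix(NA_real_, nr, nc))
  valid <- matrix(FALSE, nr, nc)
  for (i in seq_len(nrow(wins))) {
    w <- wins[i, ]
    # two-layer path: intervening tissue above the ROI top, tumor below;
    # differential attenuation relative to the reference phantom
    path_int <- min(w$z_cm, z_top_cm)
    path_tum <- max(0, w$z_cm - z_top_cm)
    layers <- data.frame(
      alpha = c(config$intervening_alpha - cal$alpha,
                tumor_alpha - cal$alpha),
      path_cm = c(path_int, path_tum))
    corr <- correct_attenuation(norm[[i]], layers)
    if (spectra[[i]]$flagged) next
    sf <- fit_spectral_params(corr, band)
    ff <- fit_gaussian_form_factor(estimate_bsc(corr, cal), band,
                                   speed_of_sound = cal$speed_of_sound,
                                   kappa = cal$kappa)
    if (ff$degenerate) next   # EAC undefined -> window masked invalid
    maps$MBF[w$row, w$col] <- sf$MBF
    maps$SS[w$row, w$col] <- sf$SS
    maps$SI[w$row, w$col] <- sf$SI
    maps$ESD[w$row, w$col] <- ff$ESD_um
    maps$EAC[w$row, w$col] <- ff$EAC_db
    valid[w$row, w$col] <- TRUE
  }
  structure(list(maps = maps, valid = valid, windows = wins, band = band,
                 ace = ace, tumor_alpha = tumor_alpha,
                 window_mm = config$window_mm, overlap = config$overlap),
            class = "parametric_maps")
}

#' @export
print.parametric_maps <- function(x, ...) {
  cat(sprintf("<parametric_maps> %d x %d window grid, %d valid windows, band %.2f-%.2f MHz\n",
              nrow(x$valid), ncol(x$valid), sum(x$valid),
              x$band[1], x$band[2]))
  invisible(x)
}

#' Interpolate a parametric map to the RF pixel grid for display
#'
#' The raw window-center grid is retained for statistics; this helper only
#' produces a smooth raster for overlay figures.
#'
#' @param pm A [build_parametric_maps()] result.
#' @param which_map One of `"MBF"`, `"SS"`, `"SI"`, `"ESD"`, `"EAC"`.
#' @param shape `c(rows, cols)` of the display raster.
#' @return A numeric matrix (NA-filled cells carried through as the map
#'   mean before interpolation).
#' @export
display_map <- function(pm, which_map = "MBF", shape) {
  m <- pm$maps[[which_map]]
  fill <- mean(m[pm$valid])
  m[!pm$valid] <- fill
  resize_bilinear(m, shape[1], shape[2])
}

#' Mean QUS values over an ROI region
#'
#' Arithmetic mean of each of the five maps over valid windows whose
#' centers fall in the requested region.
#'
#' @param pm A [build_parametric_maps()] result.
#' @param region `"core"`, `"margin"`, or `"both"`.
#' @return Named numeric vector of length 5 (MBF, SS, SI, ESD, EAC).
#' @export
mean_value_features <- function(pm, region = c("both", "core", "margin")) {
  region <- match.arg(region)
  keep <- switch(region,
                 core = pm$windows$in_core,
                 margin = !pm$windows$in_core,
                 both = rep(TRUE, nrow(pm$windows)))
  idx <- cbind(pm$windows$row, pm$windows$col)[keep, , drop = FALSE]
  ok <- pm$valid[idx]
  if (!any(ok)) stop("no valid windows in the requested region")
  vapply(pm$maps, function(m) mean(m[idx][ok]), numeric(1))
}
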