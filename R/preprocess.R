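#' Align a B-mode image to the RF grid
#'
#' Bilinear resize to the RF frame shape followed by a vertical flip (the
#' axis orthogonal to the scan lines) to undo the inversion applied by the
#' scanner display pipeline. The flip axis is exposed because display
#' conventions differ between systems.
#'
#' @param bmode A [bmode_image()] or numeric matrix.
#' @param target_shape `c(rows, cols)` of the RF frame.
#' @param flip_axis `"rows"` (default), `"cols"`, or `"none"`.
#' @return A matrix of shape `target_shape`.
#' @export
align_bmode <- function(bmode, target_shape, flip_axis = "rows") {
  mat <- if (inherits(bmode, "bmode_image")) bmode$pixels else as.matrix(bmode)
  if (length(mat) == 0) stop("empty B-mode image")
  if (any(target_shape <= 0)) stop("target shape must be positive")
  out <- resize_bilinear(mat, target_shape[1], target_shape[2])
  switch(flip_axis,
         rows = out[rev(seq_len(nrow(out))), , drop = FALSE],
         cols = out[, rev(seq_len(ncol(out))), drop = FALSE],
         none = out,
         stop("flip_axis must be 'rows', 'cols' or 'none'"))
}

#' Pad columns and crop rows to power-of-two dimensions
#'
#' Duplicates the first and last column in place (cols + 2) and drops the
#' last 32 rows (rows - 32), turning a 2080 x 510 array into 2048 x 512.
#' Any geometry satisfying the same rows - 32 / cols + 2 contract is
#' accepted when `expect_shape` is `NULL`.
#'
#' @param array Numeric matrix.
#' @param expect_shape Expected input shape, default `c(2080, 510)`; pass
#'   `NULL` to accept any input under the same contract.
#' @return Matrix with `nrow - 32` rows and `ncol + 2` columns.
#' @export
pad_crop_pow2 <- function(array, expect_shape = c(2080, 510)) {
  array <- as.matrix(array)
  if (!is.null(expect_shape) &&
      !identical(dim(array), as.integer(expect_shape)))
    stop(sprintf("expected a %d x %d input (use expect_shape = NULL to override)",
                 expect_shape[1], expect_shape[2]))
  if (nrow(array) <= 32) stop("input must have more than 32 rows")
  out <- cbind(array[, 1], array, array[, ncol(array)])
  out[seq_len(nrow(out) - 32), , drop = FALSE]
}

#' Global min-max normalization parameters
#'
#' Scaling parameters fitted once on the training split and then applied
#' globally, so that train/test normalization is identical (test values
#' beyond the training range are clipped).
#'
#' @param rf_min,rf_max Global RF range in linear units.
#' @param bmode_min,bmode_max Global B-mode pixel range.
#' @param source Identifier of the split the parameters came from.
#' @return An object of class `normalization_params`.
#' @export
normalization_params <- function(rf_min, rf_max, bmode_min = 0,
                                 bmode_max = 1, source = "training") {
  if (rf_max <= rf_min || bmode_max <= bmode_min)
    stop("degenerate normalization parameters (max must exceed min)")
  structure(list(rf_min = rf_min, rf_max = rf_max, bmode_min = bmode_min,
                 bmode_max = bmode_max, source = source),
            class = "normalization_params")
}

#' Fit normalization parameters from a set of training frames
#'
#' @param rf_list List of [rf_frame()]s (training split only).
#' @param bmode_list List of [bmode_image()]s or matrices.
#' @param source Label recorded in the result.
#' @return A [normalization_params()].
#' @export
fit_normalization_params <- function(rf_list, bmode_list,
                                     source = "training") {
  rf_rng <- range(vapply(rf_list, function(r) range(r$samples),
                         numeric(2)))
  bm <- lapply(bmode_list, function(b)
    if (inherits(b, "bmode_image")) b$pixels else b)
  bm_rng <- range(vapply(bm, range, numeric(2)))
  if (bm_rng[2] <= bm_rng[1]) bm_rng <- c(0, 1)
  normalization_params(rf_rng[1], rf_rng[2], bm_rng[1], bm_rng[2], source)
}

#' Min-max normalize to `[0, 1]` (and invert)
#'
#' `x' = (x - min) / (max - min)`, clipped to `[0, 1]` for values outside
#' the fitted range. `denormalize(normalize(x))` is the identity for
#' in-range values.
#'
#' @param x Numeric matrix or vector.
#' @param params A [normalization_params()].
#' @param channel `"rf"` or `"bmode"` — which parameter pair to use.
#' @return Normalized values in `[0, 1]`.
#' @export
minmax_normalize <- function(x, params, channel = c("rf", "bmode")) {
  channel <- match.arg(channel)
  lo <- params[[paste0(channel, "_min")]]
  hi <- params[[paste0(channel, "_max")]]
  pmin(pmax((x - lo) / (hi - lo), 0), 1)
}

#' @rdname minmax_normalize
#' @export
minmax_denormalize <- function(x, params, channel = c("rf", "bmode")) {
  channel <- match.arg(channel)
  lo <- params[[paste0(channel, "_min")]]
  hi <- params[[paste0(channel, "_max")]]
  x * (hi - lo) + lo
}

#' Serialize / read normalization parameters as JSON
#' @param params A [normalization_params()].
#' @param path File path.
#' @export
write_normalization_params <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_normalization_params
#' @export
read_normalization_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  normalization_params(p$rf_min, p$rf_max, p$bmode_min, p$bmode_max,
                       p$source)
}
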