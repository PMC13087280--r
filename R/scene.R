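#' Acoustic region of a phantom scene
#'
#' A region is a geometry (background, a horizontal layer, or an
#' axis-aligned ellipse) carrying the sub-resolution microstructure that
#' sets its backscatter spectrum: effective scatterer radius, number
#' density, amplitude variance, and one-way attenuation.
#'
#' @param geometry `"background"`, or `list(type = "layer", depth_mm =)`
#'   for a superficial layer occupying depths `[0, depth_mm]`, or
#'   `list(type = "ellipse", cx_mm =, cz_mm =, rx_mm =, rz_mm =)` for an
#'   axis-aligned ellipse (lateral center/radius `cx/rx`, axial `cz/rz`).
#' @param a_eff_um Effective scatterer radius in micrometres (> 0).
#' @param n_per_mm2 Scatterer number density per mm^2 (>= 0).
#' @param amplitude_variance Variance of the zero-mean per-scatterer
#'   reflectivity amplitudes.
#' @param alpha One-way attenuation coefficient in dB/MHz/cm (>= 0).
#' @return An object of class `acoustic_region`.
#' @export
acoustic_region <- function(geometry = "background", a_eff_um, n_per_mm2,
                            amplitude_variance = 1, alpha = 0) {
  stopifnot(a_eff_um > 0, n_per_mm2 >= 0, amplitude_variance >= 0, alpha >= 0)
  if (is.character(geometry)) {
    stopifnot(identical(geometry, "background"))
    geometry <- list(type = "background")
  }
  stopifnot(geometry$type %in% c("background", "layer", "ellipse"))
  if (geometry$type == "ellipse")
    stopifnot(geometry$rx_mm > 0, geometry$rz_mm > 0)
  if (geometry$type == "layer")
    stopifnot(geometry$depth_mm > 0)
  structure(list(geometry = geometry, a_eff_um = a_eff_um,
                 n_per_mm2 = n_per_mm2,
                 amplitude_variance = amplitude_variance, alpha = alpha),
            class = "acoustic_region")
}

#' Phantom scene with known microstructure
#'
#' An ordered list of acoustic regions (later regions override earlier ones
#' inside their geometry) plus a class label and a seed, giving every
#' downstream estimator a known ground truth. Exactly one background region
#' is required and any lesion ellipse must sit below the intervening layer
#' (if present) so that the vertical attenuation path stays piecewise
#' simple.
#'
#' @param regions List of [acoustic_region()]s in painting order
#'   (background first).
#' @param class_label `"benign"` or `"malignant"` (or `NA` for phantoms
#'   with no lesion semantics).
#' @param seed Integer seed making scatterer sampling reproducible.
#' @return An object of class `phantom_scene`.
#' @export
phantom_scene <- function(regions, class_label = NA_character_, seed = 1L) {
  types <- vapply(regions, function(r) r$geometry$type, character(1))
  if (sum(types == "background") != 1L)
    stop("phantom_scene requires exactly one background region")
  if (which(types == "background") != 1L)
    stop("the background region must come first")
  lay <- which(types == "layer")
  ell <- which(types == "ellipse")
  if (length(lay) > 1L) stop("at most one intervening layer is supported")
  if (length(lay) == 1L && length(ell) > 0L) {
    d <- regions[[lay]]$geometry$depth_mm
    for (i in ell) {
      g <- regions[[i]]$geometry
      if (g$cz_mm - g$rz_mm < d)
        stop("lesion ellipse must lie fully below the intervening layer")
    }
  }
  structure(list(regions = regions, class_label = class_label,
                 seed = as.integer(seed)),
            class = "phantom_scene")
}

# Is (x, z) inside the region geometry? Vectorized over points.
region_contains <- function(region, x_mm, z_mm) {
  g <- region$geometry
  switch(g$type,
         background = rep(TRUE, length(x_mm)),
         layer = z_mm <= g$depth_mm,
         ellipse = ((x_mm - g$cx_mm) / g$rx_mm)^2 +
                   ((z_mm - g$cz_mm) / g$rz_mm)^2 <= 1)
}

# Area of the region clipped to a rectangular field of view, in mm^2.
# The FOV is [0, width] x [0, depth]. Layers and ellipses are assumed to be
# placed inside the FOV (validated by the simulator).
region_area_mm2 <- function(region, width_mm, depth_mm) {
  g <- region$geometry
  switch(g$type,
         background = width_mm * depth_mm,
         layer = width_mm * min(g$depth_mm, depth_mm),
         ellipse = pi * g$rx_mm * g$rz_mm)
}

# One-way integrated attenuation path in dB/MHz for scatterers at
# (x_mm, z_mm): sum over painted regions of alpha_i [dB/MHz/cm] * path_i
# [cm] along the vertical ray from the transducer face (z = 0).
# Painting order: background, then optional layer, then ellipses (each
# ellipse overrides whatever lies beneath it along its vertical chord).
attenuation_path_db_per_mhz <- function(scene, x_mm, z_mm) {
  regs <- scene$regions
  alpha_bg <- regs[[1]]$alpha
  total <- alpha_bg * z_mm / 10          # mm -> cm
  if (length(regs) > 1) for (i in 2:length(regs)) {
    g <- regs[[i]]$geometry
    if (g$type == "layer") {
      len <- pmin(z_mm, g$depth_mm)
      total <- total + (regs[[i]]$alpha - alpha_bg) * len / 10
    } else if (g$type == "ellipse") {
      # vertical chord of the ellipse at lateral position x
      u2 <- 1 - ((x_mm - g$cx_mm) / g$rx_mm)^2
      half <- ifelse(u2 > 0, g$rz_mm * sqrt(pmax(u2, 0)), 0)
      z1 <- g$cz_mm - half
      z2 <- g$cz_mm + half
      len <- pmax(0, pmin(z_mm, z2) - z1)
      len[half == 0] <- 0
      total <- total + (regs[[i]]$alpha - alpha_bg) * len / 10
    }
  }
  total
}

#' Sample the sub-resolution scatterer field of a scene
#'
#' Draws the discrete scatterers that realize each region's microstructure:
#' counts are Poisson with mean `density x area`, positions are uniform in
#' the region (clipped to the field of view), amplitudes are zero-mean
#' Gaussian with the region's variance. Later regions override earlier ones,
#' so background scatterers falling inside a lesion are discarded.
#' Deterministic given the scene seed.
#'
#' @param scene A [phantom_scene()].
#' @param width_mm,depth_mm Field-of-view extents (must be positive).
#' @return A data.frame with columns `x_mm`, `z_mm`, `amp`, `region`
#'   (index into `scene$regions`).
#' @export
sample_scatterer_field <- function(scene, width_mm, depth_mm) {
  if (width_mm <= 0 || depth_mm <= 0) stop("empty field of view")
  regs <- scene$regions
  out <- vector("list", length(regs))
  set.seed(scene$seed)
  for (i in seq_along(regs)) {
    r <- regs[[i]]
    area <- region_area_mm2(r, width_mm, depth_mm)
    count <- stats::rpois(1, r$n_per_mm2 * area)
    if (count == 0) next
    g <- r$geometry
    if (g$type == "ellipse") {
      # uniform in the ellipse via the unit disc
      rad <- sqrt(stats::runif(count)); th <- stats::runif(count, 0, 2 * pi)
      x <- g$cx_mm + g$rx_mm * rad * cos(th)
      z <- g$cz_mm + g$rz_mm * rad * sin(th)
    } else {
      zmax <- if (g$type == "layer") min(g$depth_mm, depth_mm) else depth_mm
      x <- stats::runif(count, 0, width_mm)
      z <- stats::runif(count, 0, zmax)
    }
    amp <- stats::rnorm(count, 0, sqrt(r$amplitude_variance))
    keep <- x >= 0 & x <= width_mm & z >= 0 & z <= depth_mm
    out[[i]] <- data.frame(x_mm = x[keep], z_mm = z[keep], amp = amp[keep],
                           region = i)
  }
  field <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(field))
    return(data.frame(x_mm = numeric(0), z_mm = numeric(0),
                      amp = numeric(0), region = integer(0)))
  # later regions override earlier ones: drop points owned by a later region
  if (length(regs) > 1) {
    owner <- rep(1L, nrow(field))
    for (i in 2:length(regs)) {
      inside <- region_contains(regs[[i]], field$x_mm, field$z_mm)
      owner[inside] <- i
    }
    field <- field[owner == field$region, , drop = FALSE]
  }
  rownames(field) <- NULL
  field
}
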