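#' Quantize a parametric map to discrete gray levels
#'
#' The full value range over valid pixels is linearly scaled to
#' `[0, levels - 1]` with floor binning (the maximum maps to the top
#' level). A constant map quantizes to all zeros. Texture features are
#' therefore invariant to affine rescaling of the map.
#'
#' @param map Numeric matrix.
#' @param valid Logical matrix of valid pixels (default: finite entries).
#' @param levels Number of gray levels (default 16).
#' @return List of class `quantized_map`: `q` (integer matrix, NA outside
#'   the mask), `valid`, `levels`.
#' @export
quantize_map <- function(map, valid = NULL, levels = 16) {
  map <- as.matrix(map)
  levels <- as.integer(levels)
  if (is.null(valid)) valid <- is.finite(map)
  if (!any(valid)) stop("no valid pixels to quantize")
  v <- map[valid]
  rng <- range(v)
  q <- matrix(NA_integer_, nrow(map), ncol(map))
  if (rng[2] > rng[1]) {
    scaled <- (map[valid] - rng[1]) / (rng[2] - rng[1]) * levels
    q[valid] <- pmin(as.integer(floor(scaled)), levels - 1L)
  } else {
    q[valid] <- 0L
  }
  structure(list(q = q, valid = valid, levels = as.integer(levels)),
            class = "quantized_map")
}

# Offset (drow, dcol) for distance d at angle theta in degrees, using the
# usual GLCM convention (0 deg = horizontal neighbor, 90 deg = vertical).
glcm_offset <- function(d, theta) {
  switch(as.character(theta),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("theta must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurring level pairs at a pixel offset given by distance and
#' angle, restricted to pairs whose two pixels are both valid (mask-aware),
#' symmetrized by adding the transpose, and normalized to sum to one.
#'
#' @param qm A [quantize_map()] result.
#' @param d Inter-pixel distance in pixels.
#' @param theta Angle in degrees: 0, 45, 90, or 135.
#' @param symmetric Add the transpose before normalizing (default TRUE).
#' @return `levels x levels` probability matrix of class `glcm`.
#' @export
compute_glcm <- function(qm, d = 1, theta = 0, symmetric = TRUE) {
  off <- glcm_offset(as.integer(d), theta)
  q <- qm$q; L <- qm$levels
  nr <- nrow(q); nc <- ncol(q)
  r0 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  c0 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  if (length(r0) < 1 || length(c0) < 1) stop("offset larger than image")
  a <- q[r0, c0, drop = FALSE]
  b <- q[r0 + off[1], c0 + off[2], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no valid pixel pairs at this offset")
  counts <- matrix(0, L, L)
  tab <- table(factor(a[ok], levels = 0:(L - 1)),
               factor(b[ok], levels = 0:(L - 1)))
  counts <- counts + as.matrix(tab)
  if (symmetric) counts <- counts + t(counts)
  structure(counts / sum(counts), class = "glcm")
}

#' Haralick features of a GLCM
#'
#' Contrast `sum p(i,j) (i-j)^2`, correlation
#' `sum p(i,j)(i - mu_i)(j - mu_j) / (sigma_i sigma_j)`, energy
#' `sum p(i,j)^2`, and homogeneity `sum p(i,j) / (1 + |i-j|)`. A GLCM with
#' zero marginal variance (constant image) has correlation defined as 1
#' and is flagged.
#'
#' @param g A normalized [compute_glcm()] matrix.
#' @return Named numeric vector `c(CON, COR, ENE, HOM)` with attribute
#'   `flagged` when the correlation was degenerate.
#' @export
glcm_features <- function(g) {
  g <- unclass(g)
  if (abs(sum(g) - 1) > 1e-8) stop("GLCM must be normalized to sum 1")
  L <- nrow(g)
  i <- matrix(0:(L - 1), L, L)
  j <- t(i)
  con <- sum(g * (i - j)^2)
  ene <- sum(g^2)
  hom <- sum(g / (1 + abs(i - j)))
  pi_ <- rowSums(g); pj_ <- colSums(g)
  mu_i <- sum((0:(L - 1)) * pi_); mu_j <- sum((0:(L - 1)) * pj_)
  var_i <- sum((0:(L - 1) - mu_i)^2 * pi_)
  var_j <- sum((0:(L - 1) - mu_j)^2 * pj_)
  flagged <- FALSE
  if (var_i <= 0 || var_j <= 0) {
    cor <- 1; flagged <- TRUE   # constant image: maximally self-correlated
  } else {
    cor <- sum(g * (i - mu_i) * (j - mu_j)) / sqrt(var_i * var_j)
  }
  out <- c(CON = con, COR = cor, ENE = ene, HOM = hom)
  attr(out, "flagged") <- flagged
  out
}

#' Averaged texture features of one parametric map
#'
#' Computes symmetric GLCMs at distances 1..5 pixels and angles 0, 45, 90,
#' 135 degrees (20 matrices) on the quantized window-center grid and
#' averages each of the four Haralick features across them.
#'
#' @param map Numeric matrix (a parametric map on its raw grid).
#' @param valid Logical validity mask.
#' @param levels Gray levels for quantization.
#' @param distances Pixel distances (default 1:5).
#' @param angles Angles in degrees (default `c(0, 45, 90, 135)`).
#' @return Named vector `c(CON, COR, ENE, HOM)` averaged over all GLCMs;
#'   attribute `n_glcm` gives how many offsets contributed.
#' @export
texture_vector <- function(map, valid = NULL, levels = 16,
                           distances = 1:5, angles = c(0, 45, 90, 135)) {
  qm <- quantize_map(map, valid, levels)
  acc <- c(CON = 0, COR = 0, ENE = 0, HOM = 0)
  n <- 0L
  for (d in distances) for (th in angles) {
    feats <- tryCatch(glcm_features(compute_glcm(qm, d, th)),
                      error = function(e) NULL)
    if (is.null(feats)) next
    acc <- acc + feats
    n <- n + 1L
  }
  if (n == 0) stop("no computable GLCM at any offset")
  out <- acc / n
  attr(out, "n_glcm") <- n
  out
}

#' 25-feature QUS vector for one lesion
#'
#' Per plane, the five map means and the four texture features of each map
#' (5 + 20 values); each of the 25 named features is then averaged across
#' the planes spanning the lesion. Names follow the `MAP-FEAT` convention
#' (e.g. `MBF-MEAN`, `ESD-CON`).
#'
#' @param plane_maps List of [build_parametric_maps()] results, one per
#'   imaging plane of the lesion.
#' @param region Region over which map means are taken (`"both"`, the core
#'   plus margin, by default).
#' @param levels Gray levels for texture quantization.
#' @return Named numeric vector of length 25.
#' @export
lesion_feature_vector <- function(plane_maps, region = "both",
                                  levels = 16) {
  stopifnot(length(plane_maps) >= 1)
  map_names <- c("MBF", "SS", "SI", "ESD", "EAC")
  per_plane <- vapply(plane_maps, function(pm) {
    means <- mean_value_features(pm, region)
    tex <- unlist(lapply(map_names, function(nm) {
      m <- pm$maps[[nm]]
      texture_vector(m, pm$valid, levels)
    }))
    v <- c(means, tex)
    names(v) <- c(paste0(map_names, "-MEAN"),
                  as.vector(t(outer(map_names,
                                    c("CON", "COR", "ENE", "HOM"),
                                    paste, sep = "-"))))
    v
  }, numeric(25))
  rowMeans(per_plane)
}
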