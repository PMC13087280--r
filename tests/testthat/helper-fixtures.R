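# Shared fixtures, built in code. Expensive objects are created lazily and
# cached for the session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

default_pulse <- function() pulse_model()

# homogeneous phantom frame + matched zero-attenuation reference, used by
# several spectral tests
fix_homog_pair <- function() fixture("homog_pair", function() {
  p <- default_pulse()
  g <- fov_grid(512, 220)
  scene <- phantom_scene(list(
    acoustic_region("background", a_eff_um = 75, n_per_mm2 = 500,
                    alpha = 0)), seed = 2)
  list(pulse = p, grid = g,
       rf = simulate_rf_frame(scene, p, g),
       ref = simulate_reference_frame(p, g, alpha = 0, seed = 3))
})

# small lesion scene with ROI + parametric maps (uniform attenuation, so
# the two-layer prior compensation is exact)
fix_lesion_maps <- function() fixture("lesion_maps", function() {
  p <- default_pulse()
  g <- fov_grid(512, 128)
  geom <- list(type = "ellipse", cx_mm = 7.5, cz_mm = 4.9,
               rx_mm = 2.2, rz_mm = 1.7)
  scene <- phantom_scene(list(
    acoustic_region("background", a_eff_um = 100, n_per_mm2 = 400,
                    alpha = 1.0),
    acoustic_region(geom, a_eff_um = 50, n_per_mm2 = 700,
                    amplitude_variance = 2, alpha = 1.0)),
    class_label = "malignant", seed = 7)
  rf <- simulate_rf_frame(scene, p, g)
  ref <- simulate_reference_frame(p, g, seed = 8)
  roi <- make_roi_mask(geom, rf, margin_mm = 5)
  maps <- build_parametric_maps(rf, ref, roi, qus_config(overlap = 0.5))
  list(pulse = p, grid = g, geom = geom, rf = rf, ref = ref, roi = roi,
       maps = maps)
})

# brute-force GLCM feature oracle: explicit pair enumeration
glcm_oracle <- function(q, L, d, theta, valid = NULL) {
  if (is.null(valid)) valid <- !is.na(q)
  off <- switch(as.character(theta),
                "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0),
                "135" = c(-d, -d))
  counts <- matrix(0, L, L)
  for (i in seq_len(nrow(q))) for (j in seq_len(ncol(q))) {
    i2 <- i + off[1]; j2 <- j + off[2]
    if (i2 < 1 || i2 > nrow(q) || j2 < 1 || j2 > ncol(q)) next
    if (!valid[i, j] || !valid[i2, j2]) next
    counts[q[i, j] + 1, q[i2, j2] + 1] <-
      counts[q[i, j] + 1, q[i2, j2] + 1] + 1
  }
  counts <- counts + t(counts)
  p <- counts / sum(counts)
  lev <- 0:(L - 1)
  im <- matrix(lev, L, L); jm <- t(im)
  mu_i <- sum(lev * rowSums(p)); mu_j <- sum(lev * colSums(p))
  var_i <- sum((lev - mu_i)^2 * rowSums(p))
  var_j <- sum((lev - mu_j)^2 * colSums(p))
  cor <- if (var_i <= 0 || var_j <= 0) 1 else
    sum(p * (im - mu_i) * (jm - mu_j)) / sqrt(var_i * var_j)
  c(CON = sum(p * (im - jm)^2), COR = cor, ENE = sum(p^2),
    HOM = sum(p / (1 + abs(im - jm))))
}

# synthetic normalized spectra with exact exponential depth decay, for
# attenuation-estimator tests
make_decay_spectra <- function(alpha_sample, alpha_ref, depths_cm, f_mhz,
                               base_db = 0) {
  lapply(depths_cm, function(z) {
    structure(list(f_mhz = f_mhz,
                   db = base_db - 2 * (alpha_sample - alpha_ref) *
                     f_mhz * z),
              class = "normalized_spectrum")
  })
}
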