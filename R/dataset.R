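#' Configuration for the paired synthetic cohort
#'
#' Defines the study conditions the simulator emulates: per-class lesion
#' counts, the class-specific microstructure distributions (benign lesions:
#' larger scatterer radius, lower density, homogeneous; malignant lesions:
#' smaller radius, higher density, doubled amplitude variance with 15%
#' within-lesion parameter jitter across planes), the number of imaging
#' planes per lesion, and the frame geometry.
#'
#' @param n_per_class Lesions per class.
#' @param planes Imaging planes (cross-sections) per lesion.
#' @param pulse A [pulse_model()].
#' @param grid A [fov_grid()].
#' @param benign,malignant Per-class parameter lists with elements
#'   `a_eff_range_um` (uniform range for the effective radius),
#'   `n_per_mm2`, `amplitude_variance`, `jitter` (relative within-lesion
#'   SD applied per plane).
#' @param background Background tissue parameters (`a_eff_um`, `n_per_mm2`,
#'   `amplitude_variance`, `alpha`).
#' @param lesion_alpha One-way lesion attenuation in dB/MHz/cm.
#' @param rx_range_mm,rz_range_mm Uniform ranges for lesion semi-axes.
#' @param dynamic_range B-mode dynamic range in dB.
#' @param bmode_shape Optional display raster `c(rows, cols)` for the
#'   B-mode image (`NULL` keeps the RF grid).
#' @return A config list.
#' @export
dataset_config <- function(n_per_class = 2, planes = 4,
                           pulse = pulse_model(), grid = fov_grid(),
                           benign = list(a_eff_range_um = c(80, 110),
                                         n_per_mm2 = 350,
                                         amplitude_variance = 1,
                                         jitter = 0),
                           malignant = list(a_eff_range_um = c(40, 70),
                                            n_per_mm2 = 700,
                                            amplitude_variance = 2,
                                            jitter = 0.15),
                           background = list(a_eff_um = 60, n_per_mm2 = 500,
                                             amplitude_variance = 1,
                                             alpha = 1.0),
                           lesion_alpha = 1.0,
                           rx_range_mm = c(1.8, 2.6),
                           rz_range_mm = c(1.4, 2.0),
                           dynamic_range = 50,
                           bmode_shape = NULL) {
  if (n_per_class < 1) stop("n_lesions per class must be >= 1")
  stopifnot(planes >= 1)
  list(n_per_class = n_per_class, planes = planes, pulse = pulse,
       grid = grid, benign = benign, malignant = malignant,
       background = background, lesion_alpha = lesion_alpha,
       rx_range_mm = rx_range_mm, rz_range_mm = rz_range_mm,
       dynamic_range = dynamic_range, bmode_shape = bmode_shape)
}

#' Build a paired RF / B-mode cohort with ground truth
#'
#' For each lesion, draws class-conditional microstructure, then simulates
#' `planes` cross-sections with jittered lesion geometry (and, for classes
#' with `jitter > 0`, per-plane microstructure jitter emulating intra-lesion
#' heterogeneity). Every frame keeps its generating scene so downstream
#' estimators can be validated against the truth. Deterministic given
#' `seed`.
#'
#' @param config A [dataset_config()].
#' @param seed Integer seed.
#' @return A list with class `paired_dataset`: `frames` (one record per
#'   frame: `rf`, `bmode`, `lesion_geom`, `lesion_id`, `plane`,
#'   `class_label`, `truth`) and `config`.
#' @export
build_paired_dataset <- function(config = dataset_config(), seed = 1L) {
  set.seed(seed)
  ext <- grid_extent_mm(config$grid, config$pulse)
  labels <- rep(c("benign", "malignant"), each = config$n_per_class)
  frames <- list()
  for (li in seq_along(labels)) {
    cls <- labels[li]
    par <- config[[cls]]
    a_eff <- stats::runif(1, par$a_eff_range_um[1], par$a_eff_range_um[2])
    rx <- stats::runif(1, config$rx_range_mm[1], config$rx_range_mm[2])
    rz <- stats::runif(1, config$rz_range_mm[1], config$rz_range_mm[2])
    cx <- ext["width_mm"] / 2
    cz <- ext["depth_mm"] / 2
    for (pl in seq_len(config$planes)) {
      # each plane is a slightly different cross-section of the lesion
      shrink <- stats::runif(1, 0.85, 1.0)
      jit <- function(x) x * (1 + stats::rnorm(1, 0, par$jitter))
      a_pl <- max(jit(a_eff), 5)
      n_pl <- max(jit(par$n_per_mm2), 10)
      scene_seed <- sample.int(.Machine$integer.max %/% 2, 1)
      geom <- list(type = "ellipse", cx_mm = unname(cx), cz_mm = unname(cz),
                   rx_mm = rx * shrink, rz_mm = rz * shrink)
      scene <- phantom_scene(list(
        acoustic_region("background",
                        a_eff_um = config$background$a_eff_um,
                        n_per_mm2 = config$background$n_per_mm2,
                        amplitude_variance = config$background$amplitude_variance,
                        alpha = config$background$alpha),
        acoustic_region(geom, a_eff_um = a_pl, n_per_mm2 = n_pl,
                        amplitude_variance = par$amplitude_variance,
                        alpha = config$lesion_alpha)),
        class_label = cls, seed = scene_seed)
      rf <- simulate_rf_frame(scene, config$pulse, config$grid)
      bm <- form_bmode(rf, config$dynamic_range, config$bmode_shape)
      frames[[length(frames) + 1]] <- list(
        rf = rf, bmode = bm, lesion_geom = geom,
        lesion_id = li, plane = pl, class_label = cls,
        truth = list(a_eff_um = a_pl, n_per_mm2 = n_pl,
                     amplitude_variance = par$amplitude_variance,
                     scene = scene))
    }
  }
  structure(list(frames = frames, config = config), class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  lab <- vapply(x$frames, `[[`, character(1), "class_label")
  cat(sprintf("<paired_dataset> %d frames (%d lesions x %d planes); %s\n",
              length(x$frames),
              length(unique(vapply(x$frames, `[[`, numeric(1), "lesion_id"))),
              x$config$planes,
              paste(names(table(lab)), table(lab), sep = "=",
                    collapse = ", ")))
  invisible(x)
}
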