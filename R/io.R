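# RF container: float32 little-endian binary matrices with a JSON
# sidecar carrying geometry and provenance (a raw-binary dialect of the
# usual HDF5 layout: rf/bmode/roi arrays plus sampling_rate_mhz,
# speed_of_sound_mps, lateral_pitch_mm, provenance, class_label and the
# serialized scene ground truth as attributes).

write_f32 <- function(mat, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(mat), con, size = 4, endian = "little")
  invisible(path)
}

read_f32 <- function(path, nrow, ncol) {
  con <- file(path, "rb")
  on.exit(close(con))
  matrix(readBin(con, "numeric", n = nrow * ncol, size = 4,
                 endian = "little"), nrow, ncol)
}

#' Write / read an RF frame (binary + JSON sidecar)
#'
#' @param rf An [rf_frame()].
#' @param stem Path stem; writes `<stem>.rf.f32` and `<stem>.json`.
#' @return The stem, invisibly.
#' @export
write_rf_frame <- function(rf, stem) {
  write_f32(rf$samples, paste0(stem, ".rf.f32"))
  meta <- list(shape = dim(rf$samples),
               sampling_rate_mhz = rf$sampling_rate,
               speed_of_sound_mps = rf$speed_of_sound,
               lateral_pitch_mm = rf$lateral_pitch,
               provenance = rf$provenance,
               calibration = rf$calibration)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_rf_frame
#' @export
read_rf_frame <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"),
                              simplifyVector = TRUE)
  samples <- read_f32(paste0(stem, ".rf.f32"), meta$shape[1],
                      meta$shape[2])
  rf_frame(samples, meta$sampling_rate_mhz, meta$speed_of_sound_mps,
           meta$lateral_pitch_mm, provenance = meta$provenance,
           calibration = meta$calibration)
}

#' Write / read one paired dataset record
#'
#' Stores the RF frame, the B-mode raster (8-bit), and the lesion
#' geometry, label and ground truth in the JSON sidecar.
#'
#' @param record One element of `build_paired_dataset()$frames`.
#' @param stem Path stem.
#' @return The stem, invisibly.
#' @export
write_paired_record <- function(record, stem) {
  write_f32(record$rf$samples, paste0(stem, ".rf.f32"))
  bm <- record$bmode$pixels
  con <- file(paste0(stem, ".bmode.u8"), "wb")
  writeBin(as.integer(round(bm * 255)), con, size = 1)
  close(con)
  truth <- record$truth[c("a_eff_um", "n_per_mm2", "amplitude_variance")]
  meta <- list(shape = dim(record$rf$samples),
               bmode_shape = dim(bm),
               sampling_rate_mhz = record$rf$sampling_rate,
               speed_of_sound_mps = record$rf$speed_of_sound,
               lateral_pitch_mm = record$rf$lateral_pitch,
               provenance = record$rf$provenance,
               dynamic_range_db = record$bmode$dynamic_range,
               class_label = record$class_label,
               lesion_id = record$lesion_id, plane = record$plane,
               lesion_geom = record$lesion_geom,
               scene_ground_truth = truth)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_paired_record
#' @export
read_paired_record <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"),
                              simplifyVector = TRUE)
  rf <- rf_frame(read_f32(paste0(stem, ".rf.f32"), meta$shape[1],
                          meta$shape[2]),
                 meta$sampling_rate_mhz, meta$speed_of_sound_mps,
                 meta$lateral_pitch_mm, provenance = meta$provenance)
  con <- file(paste0(stem, ".bmode.u8"), "rb")
  raw8 <- readBin(con, "integer", n = prod(meta$bmode_shape), size = 1,
                  signed = FALSE)
  close(con)
  bm <- bmode_image(matrix(raw8 / 255, meta$bmode_shape[1],
                           meta$bmode_shape[2]),
                    meta$dynamic_range_db,
                    frame_extent_mm(rf))
  list(rf = rf, bmode = bm,
       lesion_geom = meta$lesion_geom, lesion_id = meta$lesion_id,
       plane = meta$plane, class_label = meta$class_label,
       truth = meta$scene_ground_truth)
}
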