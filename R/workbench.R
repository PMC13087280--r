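#' Per-lesion QUS feature table for a simulated cohort
#'
#' Runs the full spectral + texture pipeline for every frame of a paired
#' cohort and assembles the 25-feature vector per lesion (plane-averaged).
#' Synthetic RF frames can be substituted for the originals to compare
#' provenances on identical lesions.
#'
#' @param dataset A [build_paired_dataset()] result.
#' @param ref Reference [rf_frame()] matching the cohort geometry.
#' @param config A [qus_config()].
#' @param margin_mm ROI margin width.
#' @param region Region for map means (`"both"`, `"core"`, `"margin"`).
#' @param rf_override Optional list of [rf_frame()]s (same order as
#'   `dataset$frames`) analyzed in place of the originals.
#' @return List: `features` (lesions x 25 matrix), `labels` (factor),
#'   `lesion_ids`.
#' @export
qus_feature_table <- function(dataset, ref, config = qus_config(),
                              margin_mm = 5, region = "both",
                              rf_override = NULL) {
  frames <- dataset$frames
  ids <- vapply(frames, `[[`, numeric(1), "lesion_id")
  feats <- list(); labs <- character(0); uids <- sort(unique(ids))
  for (id in uids) {
    sel <- which(ids == id)
    plane_maps <- lapply(sel, function(i) {
      rf <- if (is.null(rf_override)) frames[[i]]$rf else rf_override[[i]]
      roi <- make_roi_mask(frames[[i]]$lesion_geom, rf, margin_mm)
      build_parametric_maps(rf, ref, roi, config)
    })
    feats[[length(feats) + 1]] <- lesion_feature_vector(plane_maps,
                                                        region)
    labs <- c(labs, frames[[sel[1]]]$class_label)
  }
  list(features = do.call(rbind, feats), labels = factor(labs),
       lesion_ids = uids)
}

#' Stratified lesion-level train/test split
#'
#' @param labels Per-lesion class labels.
#' @param test_fraction Fraction of lesions held out per class.
#' @param seed Seed.
#' @return List with `train` and `test` index vectors.
#' @export
lesion_split <- function(labels, test_fraction = 0.3, seed = 1L) {
  labels <- factor(labels)
  set.seed(seed)
  test <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    n_test <- max(1L, round(length(idx) * test_fraction))
    test <- c(test, sample(idx, n_test))
  }
  list(train = setdiff(seq_along(labels), test), test = sort(test))
}

#' Pipeline configuration
#'
#' Presets: `"desk"` runs every stage at desk scale (minutes on one CPU);
#' geometry, simulation, QUS, training and classification settings are
#' all overridable. The raw frame geometry is chosen so that the
#' power-of-two crop (rows - 32, cols + 2) yields the translator input
#' shape.
#'
#' @param scale `"desk"` or `"full"`.
#' @param translator `"identity"`, `"pix2pix"`, `"vit_shallow"`, or
#'   `"vit_deep"`.
#' @param stages Character vector of stages to run, in order.
#' @param seed Global seed.
#' @param ... Overrides for `dataset`, `qus`, `train`, `gen`, `disc`
#'   sub-configs.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(scale = c("desk", "full"),
                            translator = "identity",
                            stages = c("simulate", "preprocess", "train",
                                       "synthesize", "qus", "evaluate",
                                       "classify"),
                            seed = 1L, ...) {
  scale <- match.arg(scale)
  geom <- if (scale == "desk") {
    list(grid = fov_grid(288, 62), proc_shape = c(256, 64),
         n_per_class = 4, planes = 2,
         qus = qus_config(overlap = 0.5),
         gen_base = 4, gen_embed = 32, gen_heads = 4,
         disc_filters = c(8, 16, 32), disc_head = c(32, 1),
         n_levels = 5, epochs_main = 8, epochs_select = 2)
  } else {
    list(grid = fov_grid(2080, 510), proc_shape = c(2048, 512),
         n_per_class = 50, planes = 4,
         qus = qus_config(),
         gen_base = 64, gen_embed = 256, gen_heads = 8,
         disc_filters = c(64, 128, 256), disc_head = c(512, 1),
         n_levels = 7, epochs_main = 150, epochs_select = 10)
  }
  over <- list(...)
  cfg <- list(scale = scale, translator = translator, stages = stages,
              seed = as.integer(seed),
              dataset = dataset_config(n_per_class = geom$n_per_class,
                                       planes = geom$planes,
                                       grid = geom$grid),
              qus = geom$qus, geom = geom)
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Run the end-to-end pipeline
#'
#' Executes the requested stages in dependency order: simulate the paired
#' cohort, preprocess (align, power-of-two crop, global min-max
#' normalization from the training lesions), train the translator (or use
#' the identity map), synthesize RF from B-mode, run QUS + texture on both
#' provenances, compute sample-level metrics, and run the four-condition
#' classification experiment. A manifest (config hash, seed, per-artifact
#' checksums) is written when `out_dir` is given.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional artifact directory.
#' @param verbose Print stage progress.
#' @return List with the stage outputs that were produced (`dataset`,
#'   `norm_params`, `translator`, `synthetic`, `features`, `metrics`,
#'   `experiments`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  res <- list()
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(s) s %in% config$stages
  artifacts <- character(0)
  geom <- config$geom
  crop_shape <- c(geom$grid$n_axial - 32L, geom$grid$n_lines + 2L)

  if (!stage("simulate")) stop("pipeline requires the simulate stage")
  say("simulate: %d lesions x %d planes",
      2 * config$dataset$n_per_class, config$dataset$planes)
  dataset <- build_paired_dataset(config$dataset, seed = config$seed)
  ref <- simulate_reference_frame(config$dataset$pulse,
                                  config$dataset$grid,
                                  seed = config$seed + 1L)
  res$dataset <- dataset
  ids <- vapply(dataset$frames, `[[`, numeric(1), "lesion_id")
  labels_by_lesion <- vapply(split(
    vapply(dataset$frames, `[[`, character(1), "class_label"), ids),
    `[`, character(1), 1)
  split <- lesion_split(labels_by_lesion, seed = config$seed)
  res$split <- split

  proc <- NULL
  if (stage("preprocess")) {
    say("preprocess: crop to %d x %d and normalize",
        crop_shape[1], crop_shape[2])
    train_frames <- which(ids %in% split$train)
    rf_crop <- lapply(dataset$frames, function(fr)
      pad_crop_pow2(fr$rf$samples, expect_shape = NULL))
    bm_crop <- lapply(dataset$frames, function(fr)
      pad_crop_pow2(align_bmode(fr$bmode, dim(fr$rf$samples)),
                    expect_shape = NULL))
    np <- fit_normalization_params(
      lapply(rf_crop[train_frames], function(s)
        rf_frame(s, dataset$config$pulse$sampling_rate,
                 dataset$config$pulse$speed_of_sound,
                 dataset$config$grid$lateral_pitch)),
      bm_crop[train_frames])
    proc <- lapply(seq_along(dataset$frames), function(i)
      list(bmode = minmax_normalize(bm_crop[[i]], np, "bmode"),
           rf = minmax_normalize(rf_crop[[i]], np, "rf")))
    res$norm_params <- np
  }

  translator <- NULL
  if (stage("train") && config$translator != "identity") {
    if (is.null(proc)) stop("train stage needs preprocess outputs")
    say("train: %s translator", config$translator)
    gspec <- generator_spec(config$translator, crop_shape[1],
                            crop_shape[2],
                            base_filters = geom$gen_base,
                            n_levels = geom$n_levels,
                            filter_cap = 8 * geom$gen_base,
                            embed_dim = geom$gen_embed,
                            n_heads = geom$gen_heads,
                            decoder_filters = c(4 * geom$gen_base,
                                                2 * geom$gen_base,
                                                geom$gen_base),
                            skip_channels = geom$gen_base)
    dspec <- discriminator_spec(crop_shape[1], crop_shape[2],
                                down_filters = geom$disc_filters,
                                head_filters = geom$disc_head)
    val_lesions <- split$test[seq_len(max(1, length(split$test) %/% 2))]
    tr_pairs <- proc[ids %in% split$train]
    va_pairs <- proc[ids %in% val_lesions]
    translator <- train_cgan(tr_pairs, va_pairs, gspec, dspec,
                             config = train_config(
                               epochs_main = geom$epochs_main,
                               epochs_select = geom$epochs_select,
                               seed = config$seed))
    res$translator <- translator
  }

  synthetic <- NULL
  if (stage("synthesize")) {
    say("synthesize: %s", config$translator)
    pulse <- config$dataset$pulse
    if (config$translator == "identity") {
      synthetic <- lapply(dataset$frames, function(fr) {
        out <- fr$rf; out$provenance <- "synthetic"; out
      })
      analysis_set <- dataset
      ref_a <- ref
    } else {
      if (is.null(translator) || is.null(proc))
        stop("synthesize stage needs a trained translator")
      np <- res$norm_params
      synthetic <- lapply(proc, function(p) {
        syn <- minmax_denormalize(synthesize_rf(translator, p$bmode),
                                  np, "rf")
        rf_frame(syn, pulse$sampling_rate, pulse$speed_of_sound,
                 config$dataset$grid$lateral_pitch,
                 provenance = "synthetic")
      })
      # original frames cropped to the same geometry for fair comparison
      analysis_set <- dataset
      analysis_set$frames <- lapply(seq_along(dataset$frames),
                                    function(i) {
        fr <- dataset$frames[[i]]
        fr$rf <- rf_frame(minmax_denormalize(proc[[i]]$rf, np, "rf"),
                          pulse$sampling_rate, pulse$speed_of_sound,
                          config$dataset$grid$lateral_pitch)
        fr
      })
      ref_a <- ref
      ref_a$samples <- pad_crop_pow2(ref$samples, expect_shape = NULL)
    }
    res$synthetic <- synthetic
    res$analysis_set <- analysis_set
    res$analysis_ref <- ref_a
  }

  if (stage("qus")) {
    say("qus: parametric maps and 25-feature vectors")
    res$features_orig <- qus_feature_table(res$analysis_set,
                                           res$analysis_ref, config$qus)
    res$features_syn <- qus_feature_table(res$analysis_set,
                                          res$analysis_ref, config$qus,
                                          rf_override = res$synthetic)
  }

  if (stage("evaluate")) {
    say("evaluate: sample-level metrics")
    res$metrics <- sample_metrics(
      lapply(res$analysis_set$frames, `[[`, "rf"), res$synthetic)
  }

  if (stage("classify")) {
    say("classify: four-condition experiment matrix")
    res$experiments <- run_experiment_matrix(
      res$features_orig$features, res$features_syn$features,
      res$features_orig$labels, split$train, split$test,
      seed = config$seed)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(dataset$frames)) {
      stem <- file.path(out_dir, sprintf("frame_%03d", i))
      write_paired_record(dataset$frames[[i]], stem)
      artifacts <- c(artifacts, paste0(stem, c(".rf.f32", ".json")))
    }
    if (!is.null(res$features_orig)) {
      fo <- file.path(out_dir, "features_orig.csv")
      utils::write.csv(data.frame(lesion_id = res$features_orig$lesion_ids,
                                  label = res$features_orig$labels,
                                  res$features_orig$features,
                                  check.names = FALSE),
                       fo, row.names = FALSE)
      artifacts <- c(artifacts, fo)
    }
    manifest <- list(
      config_hash = unname(tools::md5sum(
        write_temp_json(config[c("scale", "translator", "stages",
                                 "seed")]))),
      seed = config$seed,
      stages = config$stages,
      artifacts = local({
        md5 <- tools::md5sum(artifacts)
        names(md5) <- basename(artifacts)
        as.list(md5)
      }),
      r_version = as.character(getRversion()))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    res$manifest <- manifest
  }
  res
}

write_temp_json <- function(x) {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA)
  f
}

#' End-to-end synthetic classification study
#'
#' Simulates a cohort of benign/malignant lesions (4 planes each), derives
#' per-lesion QUS feature vectors from the original RF, and runs the
#' four-condition experiment matrix with the synthetic provenance supplied
#' by a translator (`"identity"` reuses the original frames, isolating the
#' QUS-plus-classification chain from translation error).
#'
#' @param n_per_class Lesions per class.
#' @param planes Imaging planes per lesion.
#' @param seed Seed for simulation, splitting, CV, and bootstrap.
#' @param qus A [qus_config()]; the default uses a coarser 50% window
#'   overlap for desk-scale runtimes.
#' @param grid Frame geometry.
#' @param translator `"identity"` or a `trained_translator` whose geometry
#'   matches the frames.
#' @param n_boot Bootstrap resamples.
#' @return List: `experiments` (the [run_experiment_matrix()] result),
#'   `features_orig`, `features_syn`, `split`, `labels`.
#' @export
synthetic_classification_study <- function(n_per_class = 20, planes = 4,
                                           seed = 1L,
                                           qus = qus_config(overlap = 0.5),
                                           grid = fov_grid(512, 128),
                                           translator = "identity",
                                           n_boot = 1000) {
  ds <- build_paired_dataset(dataset_config(n_per_class = n_per_class,
                                            planes = planes,
                                            grid = grid), seed = seed)
  ref <- simulate_reference_frame(ds$config$pulse, grid, seed = seed + 1L)
  orig <- qus_feature_table(ds, ref, qus)
  if (!identical(translator, "identity"))
    stop("trained translators require preprocessed geometry; use ",
         "run_pipeline for that path")
  syn <- orig
  split <- lesion_split(orig$labels, seed = seed)
  exps <- run_experiment_matrix(orig$features, syn$features, orig$labels,
                                split$train, split$test, n_boot = n_boot,
                                seed = seed)
  list(experiments = exps, features_orig = orig, features_syn = syn,
       split = split, labels = orig$labels)
}
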