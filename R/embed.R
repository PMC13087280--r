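#' Compare original and synthetic QUS feature distributions in UMAP space
#'
#' The 25-dimensional QUS feature vectors are z-scored with the original
#' cohort's moments, a 2-D UMAP embedding is fitted on the original
#' vectors, the synthetic vectors are projected into the same embedding,
#' and the mean paired Euclidean distance between original and synthetic
#' embeddings (UMAP-MAE) is reported. The embedding is computed by the
#' `umap-learn` backend through the system `python` (fixed `random_state`,
#' `n_neighbors = 15`, `min_dist = 0.1`).
#'
#' @param original,synthetic Numeric matrices (lesions x features), paired
#'   by row, with identical dimensions.
#' @param seed Seed passed to the embedding backend.
#' @param n_neighbors,min_dist UMAP hyperparameters.
#' @return List of class `embedding_comparison`: `embedding_original`,
#'   `embedding_synthetic` (n x 2), `umap_mae`, `distances`, `seed`.
#' @export
compare_feature_embeddings <- function(original, synthetic, seed = 1L,
                                       n_neighbors = 15, min_dist = 0.1) {
  original <- as.matrix(original); synthetic <- as.matrix(synthetic)
  if (!identical(dim(original), dim(synthetic)))
    stop("original and synthetic feature sets must be paired (same shape)")
  mu <- colMeans(original)
  sdev <- apply(original, 2, stats::sd)
  sdev[sdev == 0] <- 1
  zo <- sweep(sweep(original, 2, mu), 2, sdev, `/`)
  zs <- sweep(sweep(synthetic, 2, mu), 2, sdev, `/`)
  emb <- run_umap_backend(zo, zs, seed, min(n_neighbors, nrow(zo) - 1),
                          min_dist)
  d <- sqrt(rowSums((emb$original - emb$synthetic)^2))
  structure(list(embedding_original = emb$original,
                 embedding_synthetic = emb$synthetic,
                 umap_mae = mean(d), distances = d, seed = seed),
            class = "embedding_comparison")
}

run_umap_backend <- function(zo, zs, seed, n_neighbors, min_dist) {
  py <- Sys.which("python")
  if (py == "") stop("python interpreter not found for the UMAP backend")
  dir <- tempfile("umap"); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  utils::write.table(zo, file.path(dir, "orig.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(zs, file.path(dir, "syn.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  script <- system.file("python", "umap_embed.py", package = "echogen")
  if (script == "") stop("umap_embed.py not found in the package")
  status <- system2(py, c(script, shQuote(dir), as.character(seed),
                          as.character(n_neighbors),
                          as.character(min_dist)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(file.path(dir, "emb_orig.csv")))
    stop("UMAP backend failed (exit status ", status, ")")
  list(original = as.matrix(utils::read.table(
         file.path(dir, "emb_orig.csv"), sep = ",")),
       synthetic = as.matrix(utils::read.table(
         file.path(dir, "emb_syn.csv"), sep = ",")))
}

#' Histograms with density overlays for QUS features
#'
#' Builds per-feature histogram/density comparison figures for the
#' original versus synthetic cohorts and a summary table of mean and SD
#' per provenance.
#'
#' @param original,synthetic Feature matrices (lesions x features) with
#'   column names.
#' @param features Feature names to plot (default: the five map means if
#'   present, otherwise all columns).
#' @return List with `summary` (data.frame: feature, provenance, mean,
#'   sd) and `plots` (named list of ggplot objects).
#' @export
feature_histograms <- function(original, synthetic, features = NULL) {
  original <- as.matrix(original); synthetic <- as.matrix(synthetic)
  if (nrow(original) < 5 || nrow(synthetic) < 5)
    stop("need at least 5 lesions per cohort")
  if (is.null(features)) {
    means <- grep("-MEAN$", colnames(original), value = TRUE)
    features <- if (length(means) > 0) means else colnames(original)
  }
  summary <- do.call(rbind, lapply(features, function(f) {
    data.frame(feature = f,
               provenance = c("original", "synthetic"),
               mean = c(mean(original[, f]), mean(synthetic[, f])),
               sd = c(stats::sd(original[, f]), stats::sd(synthetic[, f])))
  }))
  plots <- lapply(features, function(f) {
    df <- data.frame(
      value = c(original[, f], synthetic[, f]),
      provenance = rep(c("original", "synthetic"),
                       c(nrow(original), nrow(synthetic))))
    lab <- sprintf("%s: orig %.3g +/- %.3g, syn %.3g +/- %.3g", f,
                   mean(original[, f]), stats::sd(original[, f]),
                   mean(synthetic[, f]), stats::sd(synthetic[, f]))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$value,
                                     fill = .data$provenance)) +
      ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                              alpha = 0.4, bins = 15,
                              position = "identity") +
      ggplot2::geom_density(ggplot2::aes(color = .data$provenance),
                            fill = NA) +
      ggplot2::labs(title = lab, x = f) +
      ggplot2::theme_minimal()
  })
  names(plots) <- features
  list(summary = summary, plots = plots)
}
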