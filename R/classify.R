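# Benign/malignant classification protocol: two-step feature selection
# (mutual information -> elastic-net logistic wrapper), RBF SVC with
# stratified 5-fold grid search on CV AUC, and bootstrap test evaluation.

#' Rank features by mutual information with the class label
#'
#' Each continuous feature is discretized into equal-frequency bins and
#' the plug-in mutual information with the (binary) label is computed,
#' with a Miller-Madow bias correction so that features binned more
#' finely are not favoured by estimation bias; the top `k` features are
#' returned. Deterministic (ties broken by column order).
#'
#' @param features Numeric matrix (samples x features) with column names.
#' @param labels Two-level factor or character vector.
#' @param k Number of features to keep.
#' @param bins Maximum number of bins per feature.
#' @return Character vector of the top-k feature names, with the MI
#'   scores as the `mi` attribute.
#' @export
select_mi <- function(features, labels, k = 20, bins = 8) {
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("labels must contain two classes")
  if (k > ncol(features)) stop("k exceeds the number of features")
  mi <- vapply(seq_len(ncol(features)), function(j) {
    x <- features[, j]
    xb <- if (length(unique(x)) <= bins) factor(x) else {
      br <- unique(stats::quantile(x, seq(0, 1, length.out = bins + 1)))
      cut(x, breaks = br, include.lowest = TRUE)
    }
    tab <- table(xb, labels) / length(x)
    px <- rowSums(tab); py <- colSums(tab)
    pos <- tab > 0
    mi_raw <- sum(tab[pos] * log(tab[pos] / outer(px, py)[pos]))
    # Miller-Madow correction with occupied-cell counts
    bias <- (sum(px > 0) - 1) * (sum(py > 0) - 1) / (2 * length(x))
    max(mi_raw - bias, 0)
  }, numeric(1))
  ord <- order(-mi)
  out <- colnames(features)[ord[seq_len(k)]]
  attr(out, "mi") <- stats::setNames(mi, colnames(features))
  out
}

#' Elastic-net logistic wrapper selection
#'
#' Logistic regression with an elastic-net penalty (L1 weight 0.7, L2
#' weight 0.3) fitted on standardized features; features whose absolute
#' coefficient exceeds the mean absolute coefficient are retained.
#'
#' @param features Numeric matrix (standardized; samples x features).
#' @param labels Two-level factor.
#' @param alpha Elastic-net mixing (L1 fraction).
#' @param lambda Penalty strength; default `1 / n` mirrors a unit inverse
#'   regularization constant.
#' @return List of class `feature_selection`: `retained`, `coefficients`,
#'   `threshold`, `flagged_empty`.
#' @export
select_elasticnet <- function(features, labels, alpha = 0.7,
                              lambda = NULL) {
  features <- as.matrix(features)
  labels <- factor(labels)
  if (is.null(lambda)) lambda <- 1 / nrow(features)
  fit <- glmnet::glmnet(features, labels, family = "binomial",
                        alpha = alpha, lambda = lambda,
                        standardize = FALSE, maxit = 10000)
  co <- as.numeric(stats::coef(fit))[-1]
  names(co) <- colnames(features)
  thr <- mean(abs(co))
  retained <- names(co)[abs(co) > thr]
  flagged <- length(retained) == 0
  if (flagged) {
    warning("elastic net shrank all coefficients to the threshold; ",
            "keeping the full input set")
    retained <- colnames(features)
  }
  structure(list(retained = retained, coefficients = co, threshold = thr,
                 flagged_empty = flagged),
            class = "feature_selection")
}

#' Two-step feature selection (mutual information then elastic net)
#'
#' @param features Raw feature matrix (samples x features).
#' @param labels Two-level factor.
#' @param k Features kept by the MI step.
#' @param alpha Elastic-net mixing.
#' @return `feature_selection` list with the additional element
#'   `mi_top` (the intermediate MI ranking).
#' @export
select_features <- function(features, labels, k = 20, alpha = 0.7) {
  k <- min(k, ncol(features))
  zs <- fit_zscore(features)
  mi_top <- select_mi(features, labels, k)
  sel <- select_elasticnet(apply_zscore(features, zs)[, mi_top,
                                                     drop = FALSE],
                           labels, alpha)
  sel$mi_top <- as.character(mi_top)
  sel
}

fit_zscore <- function(x) {
  mu <- colMeans(x)
  sdev <- apply(x, 2, stats::sd)
  sdev[sdev == 0 | !is.finite(sdev)] <- 1
  list(mu = mu, sd = sdev)
}

apply_zscore <- function(x, zs) {
  sweep(sweep(as.matrix(x), 2, zs$mu), 2, zs$sd, `/`)
}

#' Train an RBF support-vector classifier with grid-searched C and gamma
#'
#' Stratified 5-fold cross-validation on the training set; the (C, gamma)
#' pair with the highest CV AUC (pooled out-of-fold malignancy scores) is
#' refit on the full training set.
#'
#' @param features Standardized training features (samples x features).
#' @param labels Two-level factor (`benign`/`malignant`).
#' @param C_grid,gamma_grid Log-spaced hyperparameter grids.
#' @param n_folds Cross-validation folds.
#' @param seed Seed for the fold assignment.
#' @return List of class `svc_model`: `model`, `C`, `gamma`, `cv_auc`,
#'   `levels`.
#' @export
train_svc <- function(features, labels, C_grid = 10^(-2:3),
                      gamma_grid = 10^(-4:1), n_folds = 5, seed = 1L) {
  features <- as.matrix(features)
  labels <- factor(labels)
  lev <- levels(labels)
  if (nlevels(droplevels(labels)) < 2)
    stop("training labels must contain both classes")
  if (min(table(labels)) < n_folds)
    stop("need at least ", n_folds, " lesions per class for stratified ",
         n_folds, "-fold CV")
  set.seed(seed)
  folds <- integer(length(labels))
  for (cl in lev) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  best <- list(auc = -Inf)
  for (C in C_grid) for (g in gamma_grid) {
    scores <- numeric(length(labels))
    ok <- TRUE
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      m <- tryCatch(
        e1071::svm(features[tr, , drop = FALSE], labels[tr],
                   kernel = "radial", cost = C, gamma = g,
                   probability = TRUE),
        error = function(e) NULL)
      if (is.null(m)) { ok <- FALSE; break }
      pr <- attr(stats::predict(m, features[!tr, , drop = FALSE],
                                probability = TRUE), "probabilities")
      scores[!tr] <- pr[, lev[2]]
    }
    if (!ok) next
    auc <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = lev,
                                          direction = "<",
                                          quiet = TRUE)))
    if (auc > best$auc) best <- list(auc = auc, C = C, gamma = g)
  }
  if (!is.finite(best$auc)) stop("SVC grid search failed on every cell")
  model <- e1071::svm(features, labels, kernel = "radial", cost = best$C,
                      gamma = best$gamma, probability = TRUE)
  structure(list(model = model, C = best$C, gamma = best$gamma,
                 cv_auc = best$auc, levels = lev),
            class = "svc_model")
}

#' Bootstrap evaluation on a held-out test set
#'
#' Predictions are computed once; `n` lesion-level resamples with
#' replacement then yield accuracy, sensitivity, specificity, and
#' precision (malignant = positive class), reported as mean and SD in
#' percent. Resamples in which a metric is undefined (a missing class or
#' no positive calls) are skipped for that metric and counted.
#'
#' @param svc A [train_svc()] result.
#' @param features Standardized test features.
#' @param labels Test labels.
#' @param n Number of bootstrap resamples.
#' @param seed Seed for resampling.
#' @return List of class `classifier_report`: `mean`, `sd` (named percent
#'   vectors), `skipped`, `predictions`, `n_test`, `C`, `gamma`.
#' @export
bootstrap_evaluate <- function(svc, features, labels, n = 1000,
                               seed = 1L) {
  features <- as.matrix(features)
  labels <- factor(labels, levels = svc$levels)
  if (nlevels(droplevels(labels)) < 2)
    stop("test set must contain both classes")
  pred <- stats::predict(svc$model, features)
  pos <- svc$levels[2]   # malignant
  set.seed(seed)
  mets <- matrix(NA_real_, n, 4,
                 dimnames = list(NULL, c("accuracy", "sensitivity",
                                         "specificity", "precision")))
  for (b in seq_len(n)) {
    idx <- sample.int(length(labels), replace = TRUE)
    y <- labels[idx]; p <- pred[idx]
    tp <- sum(p == pos & y == pos); tn <- sum(p != pos & y != pos)
    fp <- sum(p == pos & y != pos); fn <- sum(p != pos & y == pos)
    mets[b, "accuracy"] <- (tp + tn) / length(idx)
    if (tp + fn > 0) mets[b, "sensitivity"] <- tp / (tp + fn)
    if (tn + fp > 0) mets[b, "specificity"] <- tn / (tn + fp)
    if (tp + fp > 0) mets[b, "precision"] <- tp / (tp + fp)
  }
  structure(list(
    mean = 100 * colMeans(mets, na.rm = TRUE),
    sd = 100 * apply(mets, 2, stats::sd, na.rm = TRUE),
    skipped = colSums(is.na(mets)),
    predictions = pred, n_test = length(labels),
    C = svc$C, gamma = svc$gamma),
    class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("<classifier_report>\n")
  for (m in names(x$mean))
    cat(sprintf("  %-12s %3.0f +/- %2.0f %%\n", m, x$mean[m], x$sd[m]))
  cat(sprintf("  (C = %g, gamma = %g, n_test = %d)\n",
              x$C, x$gamma, x$n_test))
  invisible(x)
}

#' Four-condition original/synthetic experiment matrix
#'
#' Runs the full protocol under four dependency conditions sharing one
#' lesion-level split and one bootstrap seed:
#' 1. selection, training and testing on original-RF features;
#' 2. selection, training and testing on synthetic-RF features;
#' 3. training and testing on synthetic features using the features
#'    selected in condition 1;
#' 4. selection and training on original features, testing on synthetic
#'    features.
#' Standardization moments are always fitted on the training lesions of
#' the provenance being trained on.
#'
#' @param features_orig,features_syn Feature matrices (lesions x
#'   features), paired by row.
#' @param labels Lesion labels.
#' @param train_idx,test_idx Lesion-level split indices.
#' @param k Features kept by the MI step.
#' @param n_boot Bootstrap resamples.
#' @param seed Shared seed for CV folds and bootstrap.
#' @return List of class `experiment_matrix`: per-condition
#'   `classifier_report`s, selected feature sets, and the overlap of the
#'   synthetic selection with the original one.
#' @export
run_experiment_matrix <- function(features_orig, features_syn, labels,
                                  train_idx, test_idx, k = 20,
                                  n_boot = 1000, seed = 1L) {
  features_orig <- as.matrix(features_orig)
  features_syn <- as.matrix(features_syn)
  if (!identical(dim(features_orig), dim(features_syn)))
    stop("provenance pairing broken: feature matrices differ in shape")
  labels <- factor(labels)
  ytr <- labels[train_idx]; yte <- labels[test_idx]

  # condition 1: everything on original features
  sel1 <- select_features(features_orig[train_idx, , drop = FALSE], ytr,
                          k = k)
  zs1 <- fit_zscore(features_orig[train_idx, sel1$retained, drop = FALSE])
  svc1 <- train_svc(apply_zscore(
    features_orig[train_idx, sel1$retained, drop = FALSE], zs1), ytr,
    seed = seed)
  rep1 <- bootstrap_evaluate(svc1, apply_zscore(
    features_orig[test_idx, sel1$retained, drop = FALSE], zs1), yte,
    n = n_boot, seed = seed)

  # condition 2: everything on synthetic features
  sel2 <- select_features(features_syn[train_idx, , drop = FALSE], ytr,
                          k = k)
  zs2 <- fit_zscore(features_syn[train_idx, sel2$retained, drop = FALSE])
  svc2 <- train_svc(apply_zscore(
    features_syn[train_idx, sel2$retained, drop = FALSE], zs2), ytr,
    seed = seed)
  rep2 <- bootstrap_evaluate(svc2, apply_zscore(
    features_syn[test_idx, sel2$retained, drop = FALSE], zs2), yte,
    n = n_boot, seed = seed)

  # condition 3: original's selected features, synthetic train and test
  zs3 <- fit_zscore(features_syn[train_idx, sel1$retained, drop = FALSE])
  svc3 <- train_svc(apply_zscore(
    features_syn[train_idx, sel1$retained, drop = FALSE], zs3), ytr,
    seed = seed)
  rep3 <- bootstrap_evaluate(svc3, apply_zscore(
    features_syn[test_idx, sel1$retained, drop = FALSE], zs3), yte,
    n = n_boot, seed = seed)

  # condition 4: train on original, test on synthetic
  rep4 <- bootstrap_evaluate(svc1, apply_zscore(
    features_syn[test_idx, sel1$retained, drop = FALSE], zs1), yte,
    n = n_boot, seed = seed)

  structure(list(
    orig_to_orig = rep1, syn_own_selection = rep2,
    syn_orig_features = rep3, orig_to_syn = rep4,
    selected_original = sel1$retained,
    selected_synthetic = sel2$retained,
    selection_overlap = intersect(sel1$retained, sel2$retained)),
    class = "experiment_matrix")
}

#' @export
print.experiment_matrix <- function(x, ...) {
  conds <- c(orig_to_orig = "original -> original",
             syn_own_selection = "synthetic -> synthetic (own selection)",
             syn_orig_features = "synthetic -> synthetic (original's features)",
             orig_to_syn = "original -> synthetic")
  cat("<experiment_matrix>\n")
  for (nm in names(conds)) {
    r <- x[[nm]]
    cat(sprintf("  %-44s acc %3.0f +/- %2.0f %%\n", conds[nm],
                r$mean["accuracy"], r$sd["accuracy"]))
  }
  cat(sprintf("  selected (original): %s\n",
              paste(x$selected_original, collapse = ", ")))
  invisible(x)
}
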