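make_feature_set <- function(n = 40, p = 10, informative = 2, seed = 1,
                             sep = 3) {
  set.seed(seed)
  y <- factor(rep(c("benign", "malignant"), each = n / 2))
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("F", seq_len(p))))
  for (j in seq_len(informative))
    x[, j] <- x[, j] + sep * (as.integer(y) - 1.5)
  list(x = x, y = y)
}

test_that("mutual-information ranking puts informative features first", {
  fs <- make_feature_set(n = 60, p = 8, informative = 2, sep = 4)
  # a feature identical to the label has maximal MI and ranks first
  x <- cbind(fs$x, LABEL = as.numeric(fs$y))
  top <- select_mi(x, fs$y, k = 3)
  expect_identical(top[1], "LABEL")
  expect_true(all(c("F1", "F2") %in% top))

  # pure-noise features rank below the informative ones
  mi <- attr(select_mi(fs$x, fs$y, k = 8), "mi")
  expect_gt(min(mi[c("F1", "F2")]), max(mi[paste0("F", 3:8)]))

  # k = number of features returns the identity set
  all_ <- select_mi(fs$x, fs$y, k = 8)
  expect_setequal(as.character(all_), colnames(fs$x))
  expect_error(select_mi(fs$x, factor(rep("a", 60)), k = 2), "two classes")
  expect_error(select_mi(fs$x, fs$y, k = 99), "exceeds")
})

test_that("elastic-net wrapper retains the dominant feature", {
  fs <- make_feature_set(n = 60, p = 6, informative = 1, sep = 4)
  zs <- echogen:::fit_zscore(fs$x)
  sel <- select_elasticnet(echogen:::apply_zscore(fs$x, zs), fs$y)
  expect_true("F1" %in% sel$retained)
  expect_true(all(sel$retained %in% colnames(fs$x)))
  expect_true(all(abs(sel$coefficients[sel$retained]) > sel$threshold))

  # full two-step selection: retained is a subset of the MI top-k
  sel2 <- select_features(fs$x, fs$y, k = 4)
  expect_true(all(sel2$retained %in% sel2$mi_top))
})

test_that("SVC grid search: separable data reaches AUC 1, shuffled labels
           fall to chance", {
  fs <- make_feature_set(n = 40, p = 2, informative = 2, sep = 5)
  svc <- train_svc(fs$x, fs$y, seed = 3)
  expect_equal(svc$cv_auc, 1, tolerance = 0.02)
  expect_true(svc$C %in% 10^(-2:3) && svc$gamma %in% 10^(-4:1))

  set.seed(99)
  ysh <- sample(fs$y)
  svc_null <- train_svc(fs$x, ysh, seed = 3)
  expect_lt(svc_null$cv_auc, 0.8)   # chance + grid-max sampling error

  svc2 <- train_svc(fs$x, fs$y, seed = 3)
  expect_identical(c(svc2$C, svc2$gamma), c(svc$C, svc$gamma))
  few <- c(1:3, 21:23)   # three lesions per class
  expect_error(train_svc(fs$x[few, ], fs$y[few]), "per class")
})

test_that("bootstrap evaluation: perfect and degenerate predictors", {
  fs <- make_feature_set(n = 30, p = 2, informative = 2, sep = 6,
                         seed = 5)
  svc <- train_svc(fs$x, fs$y, seed = 1)
  te <- make_feature_set(n = 20, p = 2, informative = 2, sep = 6,
                         seed = 6)
  rep_ <- bootstrap_evaluate(svc, te$x, te$y, n = 200, seed = 2)
  expect_equal(unname(rep_$mean["accuracy"]), 100)
  expect_equal(unname(rep_$sd["accuracy"]), 0)

  # constant "malignant" predictor: sensitivity 100, specificity 0
  const <- svc
  const$model <- structure(list(), class = "constant_pred")
  pred_fun <- function(object, newdata, ...)
    factor(rep("malignant", nrow(newdata)),
           levels = c("benign", "malignant"))
  registerS3method("predict", "constant_pred", pred_fun,
                   envir = environment(print))
  repc <- bootstrap_evaluate(const, te$x, te$y, n = 200, seed = 2)
  expect_equal(unname(repc$mean["sensitivity"]), 100)
  expect_equal(unname(repc$mean["specificity"]), 0)

  # bootstrap SD shrinks roughly as 1/sqrt(n_test)
  mk_noisy <- function(n, seed) make_feature_set(n = n, p = 2,
                                                 informative = 1,
                                                 sep = 1, seed = seed)
  tr <- mk_noisy(40, 7)
  svc_n <- train_svc(tr$x, tr$y, seed = 1)
  sd_small <- bootstrap_evaluate(svc_n, mk_noisy(20, 8)$x,
                                 mk_noisy(20, 8)$y, n = 400,
                                 seed = 3)$sd["accuracy"]
  sd_big <- bootstrap_evaluate(svc_n, mk_noisy(200, 9)$x,
                               mk_noisy(200, 9)$y, n = 400,
                               seed = 3)$sd["accuracy"]
  expect_lt(sd_big, sd_small)
})

test_that("experiment matrix: identical provenances give identical
           reports and standardization is fitted on training lesions", {
  fs <- make_feature_set(n = 30, p = 6, informative = 2, sep = 4,
                         seed = 11)
  split <- lesion_split(fs$y, test_fraction = 0.3, seed = 2)
  em <- run_experiment_matrix(fs$x, fs$x, fs$y, split$train, split$test,
                              k = 6, n_boot = 200, seed = 4)
  for (m in c("accuracy", "sensitivity", "specificity", "precision")) {
    expect_equal(em$orig_to_orig$mean[m], em$syn_orig_features$mean[m])
    expect_equal(em$orig_to_orig$mean[m], em$orig_to_syn$mean[m])
  }
  expect_setequal(em$selection_overlap, em$selected_original)

  # leakage guard: moments come from the training rows only
  zs <- echogen:::fit_zscore(fs$x[split$train, ])
  expect_equal(zs$mu, colMeans(fs$x[split$train, ]))
  expect_false(isTRUE(all.equal(zs$mu, colMeans(fs$x))))

  expect_error(run_experiment_matrix(fs$x, fs$x[1:10, ], fs$y,
                                     split$train, split$test),
               "pairing")
})
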