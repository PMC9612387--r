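test_that("a perfectly separating feature reaches AUC 1 and reports are consistent", {
  tb <- noise_feature_table(n_patients = 16, n_features = 1, seed = 5)
  tb$feat01 <- ifelse(tb$voi_label == "tumor", 5, 0) +
    rnorm(nrow(tb), 0, 0.1)
  cfg <- classification_config(n_repeats = 3, n_folds = 5, seed = 9)
  cv <- nested_cv_auc(tb, "TTP", "all", cfg)
  expect_s3_class(cv, "cv_report")
  expect_equal(cv$mean, 1.0)
  expect_length(cv$fold_aucs, 15L)
  expect_equal(cv$mean, mean(cv$fold_aucs))
  expect_equal(cv$sd, sd(cv$fold_aucs))
  expect_true(all(cv$fold_aucs >= 0 & cv$fold_aucs <= 1))
})

test_that("nested CV is deterministic in the configured seed", {
  tb <- noise_feature_table(n_patients = 10, seed = 6)
  cfg <- classification_config(n_repeats = 2, n_folds = 5, seed = 13)
  a <- nested_cv_auc(tb, "TTP", "all", cfg)
  b <- nested_cv_auc(tb, "TTP", "all", cfg)
  expect_identical(a$fold_aucs, b$fold_aucs)
  expect_identical(a$chosen_C, b$chosen_C)
  c2 <- nested_cv_auc(tb, "TTP", "all",
                      classification_config(2, 5, seed = 14))
  expect_false(identical(a$fold_aucs, c2$fold_aucs))
})

test_that("stratified folds preserve the class ratio exactly", {
  y <- rep(c(1L, 0L), each = 25)
  for (s in 1:5) {
    fold <- fetradiomics:::.stratified_folds(y, 5, s)
    for (f in 1:5) {
      expect_equal(mean(y[fold == f]), 0.5)
    }
  }
})

test_that("the rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  for (i in 1:5) {
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    sc <- rnorm(40) + y
    ref <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(fetradiomics:::.auc(sc, y), ref, tolerance = 1e-12)
  }
})

test_that("an intentionally leaky pipeline inflates null AUC", {
  # null data: no real signal; proper nested CV stays near chance while
  # selecting the best feature on the full data (leak) inflates the score
  set.seed(8)
  reps <- 8
  proper <- numeric(reps); leaky <- numeric(reps)
  for (r in 1:reps) {
    n <- 60; nf <- 40
    x <- matrix(rnorm(n * nf), n)
    y <- sample(rep(c(1L, 0L), each = n / 2))
    aucs_p <- c(); aucs_l <- c()
    # leak: pick the most separating feature using ALL rows
    tstat <- abs(colMeans(x[y == 1, ]) - colMeans(x[y == 0, ])) /
      apply(x, 2, sd)
    leak_col <- which.max(tstat)
    fold <- fetradiomics:::.stratified_folds(y, 5, 100 + r)
    for (f in 1:5) {
      tr <- fold != f
      pipe <- fetradiomics:::.fit_pipeline(x[tr, , drop = FALSE], y[tr], 1)
      aucs_p <- c(aucs_p,
                  fetradiomics:::.auc(pipe$predict(x[!tr, , drop = FALSE], 1),
                                      y[!tr]))
      pl <- fetradiomics:::.fit_pipeline(x[tr, leak_col, drop = FALSE],
                                         y[tr], 1)
      aucs_l <- c(aucs_l,
                  fetradiomics:::.auc(pl$predict(x[!tr, leak_col,
                                                   drop = FALSE], 1),
                                      y[!tr]))
    }
    proper[r] <- mean(aucs_p); leaky[r] <- mean(aucs_l)
  }
  expect_gt(mean(leaky), mean(proper) + 0.1)
  expect_gt(mean(leaky), 0.6)
})

test_that("single-feature tables give identical results via both interfaces", {
  tb <- noise_feature_table(n_patients = 10, n_features = 1, seed = 9)
  cfg <- classification_config(n_repeats = 2, n_folds = 5, seed = 3)
  direct <- nested_cv_auc(tb, list(image_kind = "TTP", feature = "feat01"),
                          "all", cfg)
  uni <- univariate_auc(tb, "all", cfg, image_kind_filter = "TTP")
  expect_equal(nrow(uni), 1L)
  expect_equal(uni$mean_auc, direct$mean)
  expect_equal(attr(uni, "reports")[[1]]$fold_aucs, direct$fold_aucs)
})

test_that("grouped folds keep both VOIs of a patient together", {
  tb <- noise_feature_table(n_patients = 12, seed = 10)
  cfg <- classification_config(n_repeats = 2, n_folds = 4, seed = 21)
  cv <- nested_cv_auc(tb, "TTP", "all", cfg, group_by_patient = TRUE)
  expect_true(all(is.finite(cv$fold_aucs)))
})
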