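#' Nested cross-validation settings
#'
#' Defaults follow the standard repeated stratified design: 50 repeats of
#' 5-fold CV in the outer loop, an inner 5-fold loop tuning the inverse
#' regularization strength C of a balanced L2 logistic regression over 7
#' log-spaced candidates between 1e-3 and 1e3, scored by ROC AUC.
#'
#' @param n_repeats Outer-loop repeats (>= 1).
#' @param n_folds Folds for both loops (>= 2).
#' @param C_grid Positive inverse-regularization-strength candidates.
#' @param seed Master seed; all fold partitions derive from it.
#' @return An object of class `classification_config`.
#' @export
classification_config <- function(n_repeats = 50L, n_folds = 5L,
                                  C_grid = 10^seq(-3, 3, length.out = 7),
                                  seed = 1L) {
  stopifnot(n_repeats >= 1, n_folds >= 2, all(C_grid > 0))
  structure(list(n_repeats = as.integer(n_repeats),
                 n_folds = as.integer(n_folds),
                 C_grid = as.numeric(C_grid), stratified = TRUE,
                 class_weighting = "balanced", penalty = "L2",
                 scoring = "auc", seed = as.integer(seed)),
            class = "classification_config")
}

# rank-based (midrank) AUC of scores for labels y in {0,1}
.auc <- function(scores, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# seeded stratified fold assignment: within each class, shuffle and deal
# round-robin so every fold's class ratio matches the global ratio
.stratified_folds <- function(y, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# Fit the standardize -> drop-zero-variance -> ridge-logistic pipeline on a
# training set at each C of the grid, using only training rows; returns a
# scoring closure per C. glmnet's lambda maps to C as lambda = 1/(n * C).
.fit_pipeline <- function(x_train, y_train, C_grid) {
  mu <- colMeans(x_train)
  sd_ <- apply(x_train, 2, stats::sd)
  keep <- which(sd_ > 0)
  n <- nrow(x_train)
  w <- ifelse(y_train == 1, n / (2 * sum(y_train == 1)),
              n / (2 * sum(y_train == 0)))
  lam <- sort(1 / (n * C_grid), decreasing = TRUE)
  if (length(keep) == 0L) {
    return(list(predict = function(x_new, C) rep(0, nrow(x_new))))
  }
  xs <- scale(x_train[, keep, drop = FALSE], center = mu[keep],
              scale = sd_[keep])
  # glmnet needs >= 2 columns; pad univariate input with an all-zero dummy
  pad <- ncol(xs) == 1L
  if (pad) xs <- cbind(xs, 0)
  fit <- withCallingHandlers(
    glmnet::glmnet(xs, y_train, family = "binomial", alpha = 0,
                   lambda = lam, weights = w, standardize = FALSE),
    # glmnet flags binomial classes below 8 observations; inner folds of a
    # desk-scale nested CV are legitimately that small
    warning = function(w_) {
      if (grepl("fewer than 8", conditionMessage(w_))) {
        invokeRestart("muffleWarning")
      }
    })
  list(predict = function(x_new, C) {
    xn <- scale(x_new[, keep, drop = FALSE], center = mu[keep],
                scale = sd_[keep])
    if (pad) xn <- cbind(xn, 0)
    as.numeric(stats::predict(fit, xn, s = 1 / (n * C), exact = FALSE))
  })
}

#' Nested cross-validated AUC of the logistic-regression pipeline
#'
#' Discriminates tumor VOIs (label 1) from mirrored background VOIs
#' (label 0) with a balanced, L2-regularized logistic regression. For every
#' outer split the full pipeline -- feature standardization, removal of
#' zero-variance features, tuning of C by inner CV -- is fit on the outer
#' training part only, so no information from the outer test rows leaks
#' into scaler or hyperparameter. Samples are VOIs, two per patient, and
#' folds are stratified on the class label only, deliberately ignoring the
#' paired structure; `group_by_patient = TRUE` keeps both VOIs of a patient
#' in the same fold (the corrected design, off by default).
#'
#' @param table A `feature_table` from [extract_cohort()].
#' @param feature_set An image kind from [image_kinds()], `"All"` (the 279
#'   columns of all three kinds), or a list
#'   `list(image_kind =, feature =)` for a single-feature model.
#' @param subgroup `"all"`, `"isometabolic"` or `"photopenic"`.
#' @param config A [classification_config()].
#' @param group_by_patient Keep each patient's two VOIs in one fold.
#' @return An object of class `cv_report`: `feature_set` label, vector
#'   `fold_aucs` (`n_repeats * n_folds` values), `mean`, `sd`,
#'   `chosen_C` per outer fold, and the config.
#' @export
nested_cv_auc <- function(table, feature_set = "All",
                          subgroup = c("all", "isometabolic", "photopenic"),
                          config = classification_config(),
                          group_by_patient = FALSE) {
  subgroup <- match.arg(subgroup)
  stopifnot(inherits(config, "classification_config"))
  xy <- .design_matrix(table, feature_set, subgroup)
  x <- xy$x; y <- xy$y; pid <- xy$patient_id
  if (length(unique(y)) < 2L || min(table(y)) < 2L) {
    stop("need at least 2 samples per class")
  }
  if (!all(is.finite(x))) stop("non-finite feature values")
  n_out <- config$n_repeats * config$n_folds
  aucs <- numeric(n_out)
  chosen <- numeric(n_out)
  k <- 0L
  for (r in seq_len(config$n_repeats)) {
    fold_seed <- (config$seed + 104729L * r) %% .Machine$integer.max
    fold <- if (group_by_patient) {
      pf <- .stratified_folds(rep(1L, length(unique(pid))), config$n_folds,
                              fold_seed)
      pf[match(pid, unique(pid))]
    } else {
      .stratified_folds(y, config$n_folds, fold_seed)
    }
    for (f in seq_len(config$n_folds)) {
      tr <- fold != f
      x_tr <- x[tr, , drop = FALSE]; y_tr <- y[tr]
      # inner CV over the C grid
      inner_seed <- (fold_seed + 7919L * f) %% .Machine$integer.max
      inner <- .stratified_folds(y_tr, config$n_folds, inner_seed)
      inner_auc <- matrix(NA_real_, config$n_folds, length(config$C_grid))
      for (g in seq_len(config$n_folds)) {
        itr <- inner != g
        if (length(unique(y_tr[itr])) < 2L || !any(!itr)) next
        pipe <- .fit_pipeline(x_tr[itr, , drop = FALSE], y_tr[itr],
                              config$C_grid)
        for (ci in seq_along(config$C_grid)) {
          sc <- pipe$predict(x_tr[!itr, , drop = FALSE],
                             config$C_grid[ci])
          inner_auc[g, ci] <- .auc(sc, y_tr[!itr])
        }
      }
      mean_inner <- colMeans(inner_auc, na.rm = TRUE)
      best_C <- config$C_grid[which.max(mean_inner)]
      pipe <- .fit_pipeline(x_tr, y_tr, config$C_grid)
      sc <- pipe$predict(x[!tr, , drop = FALSE], best_C)
      k <- k + 1L
      aucs[k] <- .auc(sc, y[!tr])
      chosen[k] <- best_C
    }
  }
  structure(list(feature_set = xy$label, subgroup = subgroup,
                 fold_aucs = aucs, mean = mean(aucs),
                 sd = stats::sd(aucs), chosen_C = chosen, config = config,
                 n_samples = length(y)),
            class = "cv_report")
}

# assemble the design matrix for a feature set
.design_matrix <- function(table, feature_set, subgroup) {
  sub <- table
  if (subgroup != "all") sub <- sub[sub$phenotype == subgroup, ]
  feats <- feature_columns(table)
  if (is.list(feature_set)) {
    kind <- feature_set$image_kind
    fn <- feature_set$feature
    stopifnot(kind %in% image_kinds(), fn %in% feats)
    sub <- sub[sub$image_kind == kind, ]
    x <- as.matrix(sub[, fn, drop = FALSE])
    label <- paste(kind, fn, sep = ":")
  } else if (identical(feature_set, "All")) {
    wide <- NULL
    base <- NULL
    for (kind in image_kinds()) {
      sk <- sub[sub$image_kind == kind, ]
      sk <- sk[order(sk$patient_id, sk$voi_label), ]
      m <- as.matrix(sk[, feats])
      colnames(m) <- paste(kind, feats, sep = ":")
      wide <- if (is.null(wide)) m else cbind(wide, m)
      base <- sk
    }
    x <- wide
    sub <- base
    label <- "All"
  } else {
    stopifnot(feature_set %in% image_kinds())
    sub <- sub[sub$image_kind == feature_set, ]
    x <- as.matrix(sub[, feats])
    label <- feature_set
  }
  list(x = x, y = as.integer(sub$voi_label == "tumor"),
       patient_id = sub$patient_id, label = label)
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "cv_report [%s, %s]: AUC %.3f +/- %.3f (%d x %d-fold nested CV, n = %d)\n",
    x$feature_set, x$subgroup, x$mean, x$sd, x$config$n_repeats,
    x$config$n_folds, x$n_samples))
  invisible(x)
}

#' @export
summary.cv_report <- function(object, ...) {
  c(mean = object$mean, sd = object$sd,
    quantile(object$fold_aucs, c(0.025, 0.5, 0.975)))
}

#' Univariate per-feature nested-CV AUCs
#'
#' Applies the identical nested-CV procedure to every (image kind, feature)
#' singleton and ranks the reports by mean AUC (ties broken by feature
#' name).
#'
#' @inheritParams nested_cv_auc
#' @param image_kind_filter Optional subset of [image_kinds()] to scan.
#' @return Data frame sorted by decreasing mean AUC: `image_kind`,
#'   `feature`, `mean_auc`, `sd_auc`; full `cv_report`s in attribute
#'   `reports`.
#' @export
univariate_auc <- function(table, subgroup = c("all", "isometabolic",
                                               "photopenic"),
                           config = classification_config(),
                           image_kind_filter = image_kinds(),
                           group_by_patient = FALSE) {
  subgroup <- match.arg(subgroup)
  feats <- feature_columns(table)
  grid <- expand.grid(image_kind = image_kind_filter, feature = feats,
                      stringsAsFactors = FALSE)
  reports <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    reports[[i]] <- nested_cv_auc(
      table, list(image_kind = grid$image_kind[i],
                  feature = grid$feature[i]),
      subgroup, config, group_by_patient)
  }
  out <- data.frame(grid,
                    mean_auc = vapply(reports, `[[`, numeric(1), "mean"),
                    sd_auc = vapply(reports, `[[`, numeric(1), "sd"))
  ord <- order(-out$mean_auc, out$feature)
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "reports") <- reports[ord]
  out
}
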