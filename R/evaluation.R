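# One-versus-rest evaluation protocol: balanced accuracy, stratified
# splitting and cross-validation, and the six benchmark classifiers with
# pinned default configurations.

#' Confusion counts for one binary evaluation
#'
#' @param tp,fn,tn,fp non-negative integer counts.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fn, tn, fp) {
  v <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(v < 0) || sum(v) < 1)
    stop_specsel("counts must be non-negative and sum to >= 1", "specsel_param_error")
  structure(as.list(v), class = "confusion_counts")
}

#' Balanced accuracy
#'
#' Arithmetic mean of sensitivity and specificity:
#' `0.5 * (tp/(tp+fn) + tn/(tn+fp))`. Robust to class imbalance; 0.5 for a
#' constant predictor, 1 for a perfect one.
#'
#' @param c a `confusion_counts`.
#' @return balanced accuracy in \[0, 1\].
#' @export
balanced_accuracy <- function(c) {
  if ((c$tp + c$fn) < 1 || (c$tn + c$fp) < 1)
    stop_specsel("balanced accuracy undefined: empty positive or negative class",
                 "specsel_undefined_metric")
  0.5 * (c$tp / (c$tp + c$fn) + c$tn / (c$tn + c$fp))
}

# Balanced accuracy straight from 0/1 truth and prediction vectors.
bacc_from_pred <- function(y_true, y_pred) {
  balanced_accuracy(confusion_counts(
    tp = sum(y_true == 1 & y_pred == 1), fn = sum(y_true == 1 & y_pred == 0),
    tn = sum(y_true == 0 & y_pred == 0), fp = sum(y_true == 0 & y_pred == 1)))
}

#' Evaluation protocol
#'
#' @param holdout_frac stratified holdout fraction (default 0.2).
#' @param folds CV folds (default 10).
#' @param repeats CV repeats (default 10).
#' @param seed integer seed controlling splits and fold assignment.
#' @param classifier one of "LogReg", "LDA", "RF", "KNN", "GNB", "SVM".
#' @return object of class `eval_protocol`.
#' @export
eval_protocol <- function(holdout_frac = 0.2, folds = 10, repeats = 10,
                          seed = 1, classifier = "LDA") {
  if (holdout_frac <= 0 || holdout_frac >= 1)
    stop_specsel("holdout_frac must be in (0,1)", "specsel_param_error")
  if (folds < 2) stop_specsel("folds must be >= 2", "specsel_param_error")
  classifier <- match.arg(classifier, c("LogReg", "LDA", "RF", "KNN", "GNB", "SVM"))
  structure(list(holdout_frac = holdout_frac, folds = folds, repeats = repeats,
                 seed = seed, classifier = classifier),
            class = "eval_protocol")
}

#' One-versus-rest binary labels
#'
#' @param d a `spectral_dataset`.
#' @param positive_class label to treat as the positive (1) class.
#' @return integer vector of 0/1, one per row.
#' @export
make_ovr_labels <- function(d, positive_class) {
  if (!positive_class %in% d$labels)
    stop_specsel(sprintf("class '%s' not present in dataset", positive_class),
                 "specsel_unknown_class")
  as.integer(d$labels == positive_class)
}

#' Stratified train/holdout split
#'
#' Per class, `ceiling(frac * n_class)` rows go to the holdout; the split is
#' disjoint, exhaustive, and deterministic given the seed.
#'
#' @param d a `spectral_dataset`.
#' @param frac holdout fraction.
#' @param seed integer seed.
#' @return list with `train` and `holdout` datasets plus the index vectors
#'   `train_idx`, `holdout_idx`.
#' @export
stratified_split <- function(d, frac = 0.2, seed = 1) {
  tab <- table(d$labels)
  if (any(tab < 2))
    stop_specsel("every class needs >= 2 members for stratification",
                 "specsel_stratification_error")
  holdout_idx <- integer(0)
  with_seed(derive_seed(seed, "split"), {
    for (cl in names(tab)) {
      idx <- which(d$labels == cl)
      n_h <- min(ceiling(frac * length(idx)), length(idx) - 1L)
      holdout_idx <- c(holdout_idx, sample(idx, n_h))
    }
  })
  holdout_idx <- sort(holdout_idx)
  train_idx <- setdiff(seq_along(d$labels), holdout_idx)
  list(train = subset_dataset(d, rows = train_idx),
       holdout = subset_dataset(d, rows = holdout_idx),
       train_idx = train_idx, holdout_idx = holdout_idx)
}

# Stratified fold assignment: one fold id per row, classes spread evenly.
stratified_fold_ids <- function(y, folds, seed) {
  ids <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      ids[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  ids
}

# Fit one of the six pinned classifiers and predict 0/1 labels.
# Pinned defaults (library defaults drift across versions): LogReg = ridge-
# penalized logistic with lambda = 1/n (the C = 1 convention, well-defined
# when features outnumber samples), RF 100 trees, KNN k = 5, SVM RBF cost 1
# with variance-scaled gamma = 1/(p * var(X)), GNB gaussian, LDA plain.
# No feature standardisation (raw calibrated intensities). Score ties break
# toward the negative class (strict > 0.5 threshold).
fit_predict <- function(classifier, Xtr, ytr, Xte, seed = 1) {
  if (length(unique(ytr)) < 2)
    stop_specsel("training fold contains a single class", "specsel_stratification_error")
  ytr_f <- factor(ytr, levels = c(0, 1))
  switch(classifier,
    LogReg = {
      if (ncol(Xtr) < 2) {
        df <- data.frame(y = ytr, Xtr)
        fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                           family = stats::binomial()))
        p <- suppressWarnings(stats::predict(fit, newdata = data.frame(Xte),
                                             type = "response"))
      } else {
        fit <- glmnet::glmnet(Xtr, ytr_f, family = "binomial", alpha = 0,
                              lambda = 1 / length(ytr), standardize = FALSE)
        p <- stats::predict(fit, Xte, type = "response")[, 1]
      }
      as.integer(p > 0.5)
    },
    LDA = {
      ok <- apply(Xtr, 2, stats::sd) > 1e-12
      if (!any(ok)) return(rep(0L, nrow(Xte)))  # no usable feature: all-negative
      fit <- suppressWarnings(MASS::lda(Xtr[, ok, drop = FALSE], grouping = ytr_f))
      p <- stats::predict(fit, Xte[, ok, drop = FALSE])$posterior[, "1"]
      as.integer(p > 0.5)
    },
    RF = {
      colnames(Xtr) <- colnames(Xte) <- paste0("f", seq_len(ncol(Xtr)))
      fit <- ranger::ranger(y = ytr_f, x = as.data.frame(Xtr), num.trees = 100,
                            probability = TRUE, seed = seed, num.threads = 1)
      p <- stats::predict(fit, data = as.data.frame(Xte), num.threads = 1)$predictions[, "1"]
      as.integer(p > 0.5)
    },
    KNN = {
      pred <- with_seed(seed, class::knn(Xtr, Xte, cl = ytr_f, k = 5))
      as.integer(as.character(pred))
    },
    GNB = {
      fit <- e1071::naiveBayes(Xtr, ytr_f)
      p <- stats::predict(fit, Xte, type = "raw")[, "1"]
      as.integer(p > 0.5)
    },
    SVM = {
      g <- 1 / (ncol(Xtr) * max(mean(apply(Xtr, 2, stats::var)), 1e-12))
      fit <- e1071::svm(Xtr, ytr_f, kernel = "radial", cost = 1, gamma = g,
                        scale = FALSE, probability = FALSE)
      as.integer(as.character(stats::predict(fit, Xte)))
    },
    stop_specsel(sprintf("unknown classifier '%s'", classifier), "specsel_param_error"))
}

# Core repeated stratified CV on an explicit matrix; returns per-fold
# balanced accuracies. Fold assignment uses seed + (r - 1) per repeat.
cv_bacc_core <- function(X, y, classifier, folds, repeats, seed) {
  out <- numeric(0)
  for (r in seq_len(repeats)) {
    ids <- stratified_fold_ids(y, folds, seed + (r - 1L))
    for (f in seq_len(folds)) {
      te <- which(ids == f)
      if (length(unique(y[-te])) < 2)
        stop_specsel("fold with single-class training set", "specsel_stratification_error")
      pred <- fit_predict(classifier, X[-te, , drop = FALSE], y[-te],
                          X[te, , drop = FALSE], seed = seed + f)
      out <- c(out, bacc_from_pred(y[te], pred))
    }
  }
  out
}

#' Cross-validated balanced accuracy on a feature subset
#'
#' Repeated stratified k-fold CV using only the given feature columns.
#' Deterministic given `protocol$seed`.
#'
#' @param d a `spectral_dataset`; labels must be binary 0/1 unless
#'   `positive_class` is given, in which case OVR labels are built first.
#' @param feature_idx column indices of the features to use.
#' @param protocol an `eval_protocol`.
#' @param positive_class optional positive class for OVR conversion.
#' @return list with `mean` and `sd` of balanced accuracy over folds x repeats.
#' @export
cv_balanced_accuracy <- function(d, feature_idx, protocol, positive_class = NULL) {
  if (!length(feature_idx) || any(feature_idx < 1) ||
      any(feature_idx > ncol(d$intensities)))
    stop_specsel("feature_idx must be non-empty and within bounds", "specsel_param_error")
  y <- if (is.null(positive_class)) {
    if (!all(d$labels %in% c("0", "1")))
      stop_specsel("labels are not binary; supply positive_class", "specsel_param_error")
    as.integer(d$labels)
  } else make_ovr_labels(d, positive_class)
  scores <- cv_bacc_core(d$intensities[, feature_idx, drop = FALSE], y,
                         protocol$classifier, protocol$folds, protocol$repeats,
                         derive_seed(protocol$seed, "cv"))
  list(mean = mean(scores), sd = stats::sd(scores))
}

#' Benchmark the six reference classifiers
#'
#' Trains LogReg, LDA, RF, KNN, GNB and SVM with their pinned default
#' configurations under the protocol's repeated stratified CV and returns a
#' table sorted by mean balanced accuracy (descending).
#'
#' @param d a `spectral_dataset`.
#' @param positive_class positive class for the OVR task.
#' @param protocol an `eval_protocol`.
#' @param feature_idx optional feature subset (default: all features).
#' @return data.frame with columns `classifier`, `mean`, `sd`.
#' @export
benchmark_classifiers <- function(d, positive_class, protocol,
                                  feature_idx = seq_along(d$wavelengths)) {
  y <- make_ovr_labels(d, positive_class)
  X <- d$intensities[, feature_idx, drop = FALSE]
  res <- lapply(c("LogReg", "LDA", "RF", "KNN", "GNB", "SVM"), function(clf) {
    s <- cv_bacc_core(X, y, clf, protocol$folds, protocol$repeats,
                      derive_seed(protocol$seed, "cv"))
    data.frame(classifier = clf, mean = mean(s), sd = stats::sd(s))
  })
  out <- do.call(rbind, res)
  out[order(-out$mean, out$classifier), , drop = FALSE]
}

#' Holdout balanced accuracy on a feature subset
#'
#' Trains the protocol classifier on the training split and scores the
#' holdout split, using only the given feature columns.
#'
#' @param train,holdout `spectral_dataset` splits.
#' @param feature_idx feature column indices (shared axis).
#' @param protocol an `eval_protocol`.
#' @param positive_class positive class for the OVR task.
#' @return balanced accuracy on the holdout split.
#' @export
holdout_balanced_accuracy <- function(train, holdout, feature_idx, protocol,
                                      positive_class) {
  ytr <- make_ovr_labels(train, positive_class)
  yte <- make_ovr_labels(holdout, positive_class)
  pred <- fit_predict(protocol$classifier,
                      train$intensities[, feature_idx, drop = FALSE], ytr,
                      holdout$intensities[, feature_idx, drop = FALSE],
                      seed = derive_seed(protocol$seed, "holdout"))
  bacc_from_pred(yte, pred)
}
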