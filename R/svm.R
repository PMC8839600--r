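# Gaussian-kernel soft-margin SVM on gait-parameter features, with
# grid-search hyperparameter tuning on a held-out validation split.

.FEATURE_COLS <- c("v_m_mean", "v_u_mean", "v_u_std", "v_l_std")
.POSITIVE_CLASS <- "faller"

.check_feature_table <- function(features, cols = .FEATURE_COLS) {
  if (!is.data.frame(features)) stop("features must be a data.frame")
  missing_cols <- setdiff(cols, names(features))
  if (length(missing_cols)) {
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "))
  }
  invisible(features)
}

#' Stratified train/validation split
#'
#' Splits a labeled feature table into disjoint, exhaustive train and
#' validation sets, preserving class proportions (per-class rounding of
#' `train_fraction`).  Deterministic given the seed.
#'
#' @param features data.frame with a `label` column.
#' @param train_fraction fraction used for training (0 < f < 1).
#' @param rng_seed integer seed.
#' @return list with `train` and `validation` data.frames.
#' @export
split_train_validation <- function(features, train_fraction = 0.7,
                                   rng_seed = 1L) {
  if (!is.data.frame(features) || is.null(features$label)) {
    stop("features must be a data.frame with a label column")
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be strictly between 0 and 1")
  }
  counts <- table(features$label)
  if (any(counts < 2)) {
    stop("every class needs at least 2 samples to split")
  }
  idx_train <- integer(0)
  with_seed(rng_seed, {
    for (cl in names(counts)) {
      rows <- which(features$label == cl)
      n_tr <- round(train_fraction * length(rows))
      n_tr <- max(1, min(length(rows) - 1, n_tr))
      idx_train <- c(idx_train, sample(rows, n_tr))
    }
  })
  idx_train <- sort(idx_train)
  list(train = features[idx_train, , drop = FALSE],
       validation = features[-idx_train, , drop = FALSE])
}

.standardize_fit <- function(X) {
  mu <- colMeans(X)
  sigma <- apply(X, 2, sd)
  if (any(sigma <= 0)) {
    sigma[sigma <= 0] <- 1  # constant feature: leave it centered only
  }
  list(mean = mu, sd = sigma)
}

.standardize_apply <- function(X, std) {
  sweep(sweep(X, 2, std$mean, "-"), 2, std$sd, "/")
}

.fit_one_svm <- function(X, y01, C, gamma) {
  y <- ifelse(y01, 1, -1)
  fit <- svm_smo_cpp(X, y, C, gamma)
  list(alpha = as.numeric(fit$alpha), rho = as.numeric(fit$rho),
       y = y, X = X, C = C, gamma = gamma)
}

.decision_values <- function(fit, Xnew) {
  as.numeric(svm_decision_cpp(fit$X, fit$y, fit$alpha, fit$rho, fit$gamma,
                              Xnew))
}

#' Train the Gaussian-kernel SVM with grid search
#'
#' Standardizes features using training-set statistics only, fits a
#' soft-margin RBF-kernel SVM for every `(C, gamma)` grid point, scores
#' each fit on the validation set with the requested objective
#' (`"accuracy"` or `"sensitivity"`, fallers positive), and returns the
#' best model.  Ties prefer the smallest `C`, then the smallest kernel
#' width parameter `gamma` (smoother models).
#'
#' @param train,validation labeled feature tables (data.frames with the
#'   four gait-parameter columns and a `label` column; the training set
#'   must contain both classes).
#' @param objective tuning objective, `"accuracy"` or `"sensitivity"`.
#' @param grid list with numeric vectors `C` and `gamma`.
#' @return an `svm_gait_model` with the selected hyperparameters,
#'   standardization statistics, support data and validation metrics.
#' @export
train_svm <- function(train, validation,
                      objective = c("accuracy", "sensitivity"),
                      grid = list(C = 10^(-2:3), gamma = 10^(-3:2))) {
  objective <- match.arg(objective)
  .check_feature_table(train); .check_feature_table(validation)
  if (nrow(train) == 0 || nrow(validation) == 0) {
    stop("train and validation sets must be non-empty")
  }
  if (length(unique(train$label)) < 2) {
    stop("training set must contain both classes")
  }
  if (length(grid$C) == 0 || length(grid$gamma) == 0) {
    stop("empty hyperparameter grid")
  }
  Xtr_raw <- as.matrix(train[, .FEATURE_COLS])
  Xva_raw <- as.matrix(validation[, .FEATURE_COLS])
  std <- .standardize_fit(Xtr_raw)
  Xtr <- .standardize_apply(Xtr_raw, std)
  Xva <- .standardize_apply(Xva_raw, std)
  ytr <- train$label == .POSITIVE_CLASS
  yva <- validation$label == .POSITIVE_CLASS

  best <- NULL
  for (C in sort(grid$C)) {
    for (gamma in sort(grid$gamma)) {
      fit <- .fit_one_svm(Xtr, ytr, C, gamma)
      pred <- .decision_values(fit, Xva) > 0
      cm <- confusion_and_metrics(
        ifelse(yva, "faller", "non-faller"),
        ifelse(pred, "faller", "non-faller"))
      score <- cm$metrics[[objective]]
      if (is.null(best) || score > best$score) {
        best <- list(score = score, fit = fit, C = C, gamma = gamma,
                     validation = cm)
      }
    }
  }

  structure(
    list(C = best$C, gamma = best$gamma, objective = objective,
         standardization = std,
         alpha = best$fit$alpha, rho = best$fit$rho,
         support_x = best$fit$X, support_y = best$fit$y,
         feature_columns = .FEATURE_COLS,
         validation_metrics = best$validation$metrics,
         validation_confusion = best$validation$confusion,
         grid = grid),
    class = "svm_gait_model"
  )
}

#' @export
print.svm_gait_model <- function(x, ...) {
  cat(sprintf(
    "<svm_gait_model> RBF SVM tuned for %s: C = %g, gamma = %g (validation %s = %.3f)\n",
    x$objective, x$C, x$gamma, x$objective,
    x$validation_metrics[[x$objective]]))
  invisible(x)
}

#' Predict faller / non-faller labels
#'
#' @param object an `svm_gait_model`.
#' @param newdata data.frame with the model's feature columns.
#' @param decision_values return the decision function instead of labels.
#' @param ... unused.
#' @return character labels (or numeric decision values).
#' @export
predict.svm_gait_model <- function(object, newdata, decision_values = FALSE,
                                   ...) {
  .check_feature_table(newdata, object$feature_columns)
  X <- .standardize_apply(as.matrix(newdata[, object$feature_columns]),
                          object$standardization)
  fit <- list(X = object$support_x, y = object$support_y,
              alpha = object$alpha, rho = object$rho, gamma = object$gamma)
  dv <- .decision_values(fit, X)
  if (decision_values) return(dv)
  ifelse(dv > 0, "faller", "non-faller")
}

#' Confusion matrix and classification metrics
#'
#' Counts with fallers as the positive class, plus accuracy,
#' sensitivity (`tp / (tp + fn)`), specificity (`tn / (tn + fp)`) and
#' precision (`tp / (tp + fp)`).
#'
#' @param y_true,y_pred character vectors with values `"faller"` /
#'   `"non-faller"`, equal length.
#' @return list with `confusion` (tp, fn, fp, tn) and `metrics`
#'   (proportions in `[0, 1]`).
#' @examples
#' cm <- confusion_and_metrics(
#'   c(rep("faller", 14), rep("non-faller", 19)),
#'   c(rep("faller", 9), rep("non-faller", 5),
#'     rep("faller", 2), rep("non-faller", 17)))
#' round(100 * cm$metrics$accuracy, 1)
#' @export
confusion_and_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  valid <- c("faller", "non-faller")
  if (!all(y_true %in% valid) || !all(y_pred %in% valid)) {
    stop("labels must be 'faller' or 'non-faller'")
  }
  tp <- sum(y_true == "faller" & y_pred == "faller")
  fn <- sum(y_true == "faller" & y_pred == "non-faller")
  fp <- sum(y_true == "non-faller" & y_pred == "faller")
  tn <- sum(y_true == "non-faller" & y_pred == "non-faller")
  total <- tp + fn + fp + tn
  met <- list(
    accuracy = (tp + tn) / total,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_
  )
  list(confusion = list(tp = tp, fn = fn, fp = fp, tn = tn), metrics = met)
}
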