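# Stratified splitting, SVM training/prediction and confusion metrics.

test_that("stratified split: 480 samples at 70% give 336/144", {
  feats <- make_cluster_features(240)
  sp <- split_train_validation(feats, 0.7, rng_seed = 4)
  expect_equal(nrow(sp$train), 336)
  expect_equal(nrow(sp$validation), 144)
  expect_equal(sum(sp$train$label == "faller"), 168)  # stratified
  expect_setequal(c(sp$train$subject_id, sp$validation$subject_id),
                  feats$subject_id)
  expect_length(intersect(sp$train$subject_id, sp$validation$subject_id), 0)

  again <- split_train_validation(feats, 0.7, rng_seed = 4)
  expect_identical(sp$train$subject_id, again$train$subject_id)

  expect_error(split_train_validation(feats, 1.0), "between 0 and 1")
  expect_error(split_train_validation(feats[c(1, 241:260), ], 0.7),
               "at least 2")
})

test_that("separable clusters are classified perfectly", {
  feats <- make_cluster_features(40, sep = 5, seed = 2)
  sp <- split_train_validation(feats, 0.7, rng_seed = 1)
  model <- train_svm(sp$train, sp$validation,
                     grid = list(C = c(0.1, 1, 10), gamma = c(0.1, 1)))
  expect_equal(model$validation_metrics$accuracy, 1.0)
  # training labels recovered
  expect_identical(predict(model, sp$train), sp$train$label)
  # duplicated rows predict identically
  dup <- sp$validation[c(1, 1), ]
  expect_identical(predict(model, dup)[1], predict(model, dup)[2])
  # a point deep inside one cluster gets that cluster's label: the
  # decision-function sign is the oracle
  far <- sp$train[1, ]
  dv <- predict(model, far, decision_values = TRUE)
  expect_identical(predict(model, far),
                   if (dv > 0) "faller" else "non-faller")
  expect_error(predict(model, far[, -3]), "missing feature")
  expect_error(train_svm(sp$train[sp$train$label == "faller", ],
                         sp$validation), "both classes")
})

test_that("validation accuracy approaches the known Bayes rate", {
  # two isotropic Gaussian classes whose total class-mean distance D
  # satisfies Phi(-D/2) = 0.15: Bayes error 15%, Bayes accuracy 85%
  D <- 2 * qnorm(0.85)
  shift <- D / sqrt(2)  # split over two informative axes
  accs <- vapply(1:20, function(seed) {
    set.seed(seed)
    mk <- function(n) {
      lab <- rep(c("faller", "non-faller"), each = n)
      mu <- ifelse(lab == "faller", 0, shift)
      data.frame(label = lab,
                 v_m_mean = rnorm(2 * n, mu), v_u_mean = rnorm(2 * n, mu),
                 v_u_std = rnorm(2 * n, 0, 1), v_l_std = rnorm(2 * n, 0, 1))
    }
    tr <- mk(200); va <- mk(200)
    model <- train_svm(tr, va, grid = list(C = c(0.1, 1, 10),
                                           gamma = c(0.05, 0.2, 1)))
    model$validation_metrics$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.85), 0.05)
})

test_that("sensitivity tuning never loses to accuracy tuning on recall", {
  for (seed in 1:5) {
    set.seed(seed)
    n_f <- 30; n_nf <- 90  # imbalanced
    mk <- function() {
      lab <- c(rep("faller", n_f), rep("non-faller", n_nf))
      mu <- ifelse(lab == "faller", 0, 1.2)
      data.frame(label = lab,
                 v_m_mean = rnorm(length(lab), mu),
                 v_u_mean = rnorm(length(lab), mu),
                 v_u_std = rnorm(length(lab)), v_l_std = rnorm(length(lab)))
    }
    tr <- mk(); va <- mk()
    grid <- list(C = c(0.1, 1, 10), gamma = c(0.1, 0.5))
    m_acc <- train_svm(tr, va, objective = "accuracy", grid = grid)
    m_sen <- train_svm(tr, va, objective = "sensitivity", grid = grid)
    expect_gte(m_sen$validation_metrics$sensitivity,
               m_acc$validation_metrics$sensitivity)
  }
})

test_that("confusion metrics reproduce the published test tables", {
  # accuracy-tuned model: tp 9, fn 5, fp 2, tn 17
  y_true <- c(rep("faller", 14), rep("non-faller", 19))
  y_pred <- c(rep("faller", 9), rep("non-faller", 5),
              rep("faller", 2), rep("non-faller", 17))
  cm <- confusion_and_metrics(y_true, y_pred)
  expect_equal(cm$confusion, list(tp = 9L, fn = 5L, fp = 2L, tn = 17L))
  expect_equal(round(100 * cm$metrics$accuracy, 1), 78.8)   # 26/33
  expect_equal(round(100 * cm$metrics$sensitivity, 1), 64.3)  # 9/14
  # standard definitions (the printed specificity/precision pair is
  # transposed relative to these)
  expect_equal(round(100 * cm$metrics$specificity, 1), 89.5)  # 17/19
  expect_equal(round(100 * cm$metrics$precision, 1), 81.8)    # 9/11

  # sensitivity-tuned model: tp 10, fn 4, fp 5, tn 14
  y_pred2 <- c(rep("faller", 10), rep("non-faller", 4),
               rep("faller", 5), rep("non-faller", 14))
  cm2 <- confusion_and_metrics(y_true, y_pred2)
  expect_equal(round(100 * cm2$metrics$accuracy, 1), 72.7)   # 24/33
  expect_equal(round(100 * cm2$metrics$sensitivity, 1), 71.4)  # 10/14

  perfect <- confusion_and_metrics(y_true, y_true)
  expect_true(all(unlist(perfect$metrics) == 1))
})

test_that("metric identities and permutation safety hold", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    y_true <- sample(c("faller", "non-faller"), n, replace = TRUE,
                     prob = c(0.4, 0.6))
    if (length(unique(y_true)) < 2) next
    y_pred <- sample(c("faller", "non-faller"), n, replace = TRUE)
    cm <- confusion_and_metrics(y_true, y_pred)
    m <- cm$metrics
    expect_true(all(unlist(m) >= 0 & unlist(m) <= 1))
    prev <- mean(y_true == "faller")
    expect_equal(m$accuracy, m$sensitivity * prev + m$specificity * (1 - prev))
    perm <- sample(n)
    expect_identical(confusion_and_metrics(y_true[perm], y_pred[perm])$confusion,
                     cm$confusion)
  }
  expect_error(confusion_and_metrics(character(0), character(0)), "empty")
  expect_error(confusion_and_metrics("faller", c("faller", "faller")),
               "length")
  expect_error(confusion_and_metrics("faller", "maybe"), "labels")
})

test_that("standardization uses training statistics only", {
  feats <- make_cluster_features(30, sep = 3, seed = 9)
  sp <- split_train_validation(feats, 0.7, rng_seed = 2)
  # corrupt the validation scale wildly; the model must not notice at
  # training time
  va_wild <- sp$validation
  va_wild$v_m_mean <- va_wild$v_m_mean * 1000
  model <- train_svm(sp$train, va_wild,
                     grid = list(C = 1, gamma = 0.5))
  expect_equal(unname(model$standardization$mean),
               unname(colMeans(as.matrix(sp$train[, c("v_m_mean", "v_u_mean",
                                                      "v_u_std", "v_l_std")]))))
  expect_equal(unname(model$standardization$sd),
               unname(apply(as.matrix(sp$train[, c("v_m_mean", "v_u_mean",
                                                   "v_u_std", "v_l_std")]),
                            2, sd)))
})
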