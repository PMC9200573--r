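test_that("confusion counts equal elementwise cross-tabulation", {
  y <- c(0, 1, 1, 0, 1)
  expect_identical(unclass(confusion_counts(y, y))[c("fp", "fn")],
                   list(fp = 0L, fn = 0L))
  inv <- confusion_counts(1 - y, y)
  expect_identical(inv$tp + inv$tn, 0L)

  set.seed(22)
  pred <- rbinom(100, 1, 0.4)
  lab <- rbinom(100, 1, 0.6)
  cc <- confusion_counts(pred, lab)
  tp <- tn <- fp <- fn <- 0L
  for (i in 1:100) {
    if (pred[i] == 1 && lab[i] == 1) tp <- tp + 1L
    if (pred[i] == 0 && lab[i] == 0) tn <- tn + 1L
    if (pred[i] == 1 && lab[i] == 0) fp <- fp + 1L
    if (pred[i] == 0 && lab[i] == 1) fn <- fn + 1L
  }
  expect_identical(unclass(cc)[1:4], list(tp = tp, tn = tn, fp = fp, fn = fn))

  expect_error(confusion_counts(c(0, 1), c(0, 1, 1)), "length")
  expect_error(confusion_counts(c(0, 2), c(0, 1)), "0/1")
})

test_that("accuracy, sensitivity and specificity follow their formulas", {
  cc <- structure(list(tp = 9L, tn = 8L, fp = 1L, fn = 2L),
                  class = "confusion_counts")
  m <- classification_metrics(cc)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$sensitivity, 9 / 11)
  expect_equal(m$specificity, 8 / 9)

  # integer identity: accuracy * total = tp + tn exactly
  total <- with(cc, tp + tn + fp + fn)
  expect_identical(m$accuracy * total, with(cc, tp + tn) + 0)

  perfect <- classification_metrics(
    structure(list(tp = 5L, tn = 3L, fp = 0L, fn = 0L),
              class = "confusion_counts"))
  expect_equal(c(perfect$accuracy, perfect$sensitivity, perfect$specificity),
               c(1, 1, 1))

  # zero denominator flags the metric instead of erroring
  nopos <- classification_metrics(
    structure(list(tp = 0L, tn = 4L, fp = 1L, fn = 0L),
              class = "confusion_counts"))
  expect_true(is.na(nopos$sensitivity))
  expect_identical(nopos$undefined, "sensitivity")
})

test_that("ROC/AUC equals the pairwise Mann-Whitney oracle", {
  # perfectly separated scores
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  # all-tied scores: half credit
  expect_equal(roc_auc(rep(2, 10), rep(0:1, 5)), 0.5)

  set.seed(23)
  for (rep in 1:5) {
    n <- 200
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- 0:1
    scores <- round(rnorm(n) + labels, 1)    # rounding forces ties
    expect_equal(roc_auc(scores, labels), oracle_auc_pairs(scores, labels),
                 tolerance = 1e-12)
  }

  # curve endpoints and monotonicity
  rc <- roc_curve(rnorm(50), rbinom(50, 1, 0.5))
  expect_equal(c(rc$fpr[1], rc$tpr[1]), c(0, 0))
  expect_equal(c(rc$fpr[length(rc$fpr)], rc$tpr[length(rc$tpr)]), c(1, 1))
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))

  expect_error(roc_auc(1:5, rep(1, 5)), "positive and one negative")
})

test_that("trapezoidal AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(24)
  labels <- rbinom(150, 1, 0.4)
  if (length(unique(labels)) < 2) labels[1:2] <- 0:1
  scores <- rnorm(150) + 0.8 * labels
  ref <- suppressMessages(as.numeric(pROC::auc(labels, scores)))
  expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-10)
})

test_that("logistic regression recovers known coefficients", {
  # predicted probability at the zero coefficient vector is one half
  expect_equal(stats::plogis(0), 0.5)

  set.seed(25)
  n <- 5000
  X <- cbind(rnorm(n), rnorm(n))
  beta_true <- c(-1, 0.8, -0.5)
  p <- stats::plogis(beta_true[1] + X %*% beta_true[-1])
  y <- rbinom(n, 1, p)
  fit <- logistic_fit(X, y)
  expect_true(fit$converged)
  expect_true(all(abs(fit$coefficients - beta_true) < 3 * fit$se))
})

test_that("logistic fit matches grid search and glm", {
  set.seed(26)
  x <- rnorm(20)
  y <- rbinom(20, 1, stats::plogis(0.5 - 0.7 * x))
  if (length(unique(y)) < 2) y[1] <- 1 - y[1]
  fit <- logistic_fit(matrix(x, 20, 1), y)
  ref <- oracle_logistic_grid(x, y)
  expect_equal(unname(fit$coefficients), ref, tolerance = 1e-4)

  gfit <- stats::glm(y ~ x, family = stats::binomial())
  expect_equal(unname(fit$coefficients), unname(stats::coef(gfit)),
               tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(summary(gfit)$coefficients[, "Std. Error"]),
               tolerance = 1e-4)
  expect_gte(fit$log_likelihood, fit$null_log_likelihood)
})

test_that("coefficient estimates are unbiased over repeated simulation", {
  set.seed(27)
  n <- 1000
  beta_true <- c(-0.5, 0.6)
  est <- matrix(0, 200, 2)
  for (r in 1:200) {
    x <- rnorm(n)
    y <- rbinom(n, 1, stats::plogis(beta_true[1] + beta_true[2] * x))
    est[r, ] <- logistic_fit(matrix(x, n, 1), y)$coefficients
  }
  bias <- colMeans(est) - beta_true
  expect_true(all(abs(bias) < 0.05))
})

test_that("complete separation is flagged, not fatal", {
  x <- c(-3, -2, -1, 1, 2, 3)
  y <- c(0, 0, 0, 1, 1, 1)
  expect_warning(fit <- logistic_fit(matrix(x, 6, 1), y), "separation")
  expect_true(fit$separation)
})

test_that("pipeline evaluation composes prediction, counts and ROC", {
  set.seed(28)
  X <- matrix(c(-2, -1, 1, 2, -1.5, 2.5), 6, 1)
  y <- as.integer(X[, 1] > 0)
  m <- train_adaboost(X, y, rounds = 3)
  rep_ <- evaluate_pipeline(m, X, y)
  expect_equal(rep_$accuracy, 1)
  expect_equal(rep_$auc, 1)
  expect_true(all(c(rep_$accuracy, rep_$sensitivity, rep_$specificity,
                    rep_$auc) >= 0 &
                    c(rep_$accuracy, rep_$sensitivity, rep_$specificity,
                      rep_$auc) <= 1))

  # label inversion: accuracy + inverted accuracy = 1
  inv <- classification_metrics(confusion_counts(predict(m, X), 1L - y))
  expect_equal(rep_$accuracy + inv$accuracy, 1)
})
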