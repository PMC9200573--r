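#' Confusion counts for binary predictions
#'
#' Cross-tabulates 0/1 predictions against 0/1 labels with malignant = 1 as
#' the positive class.
#'
#' @param predictions,labels Equal-length 0/1 vectors.
#' @return Object of class `confusion_counts`: list `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(predictions, labels) {
  predictions <- as.integer(predictions)
  labels <- as.integer(labels)
  if (length(predictions) != length(labels)) {
    stop("validation error: predictions and labels differ in length",
         call. = FALSE)
  }
  if (!all(c(predictions, labels) %in% c(0L, 1L))) {
    stop("validation error: predictions and labels must be 0/1",
         call. = FALSE)
  }
  structure(
    list(tp = sum(predictions == 1L & labels == 1L),
         tn = sum(predictions == 0L & labels == 0L),
         fp = sum(predictions == 1L & labels == 0L),
         fn = sum(predictions == 0L & labels == 1L)),
    class = "confusion_counts"
  )
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `accuracy = (tp+tn)/(tp+tn+fp+fn)`, `sensitivity = tp/(tp+fn)` (the
#' true-positive rate among diseased cases), `specificity = tn/(tn+fp)`
#' (the true-negative rate among healthy cases). A metric whose denominator
#' is zero is reported as `NA` and named in the `undefined` field rather
#' than raising an error.
#'
#' @param counts A [confusion_counts()] object.
#' @return Object of class `metric_report`: list with `accuracy`,
#'   `sensitivity`, `specificity` (proportions), the same three as
#'   percentages (`*_pct`), and `undefined` (character vector).
#' @export
classification_metrics <- function(counts) {
  if (!inherits(counts, "confusion_counts")) {
    stop("validation error: 'counts' must be confusion_counts", call. = FALSE)
  }
  with(counts, {
    total <- tp + tn + fp + fn
    if (total < 1) stop("validation error: empty confusion table",
                        call. = FALSE)
    undefined <- character(0)
    sens <- if (tp + fn > 0) tp / (tp + fn) else {
      undefined <- c(undefined, "sensitivity"); NA_real_
    }
    spec <- if (tn + fp > 0) tn / (tn + fp) else {
      undefined <- c(undefined, "specificity"); NA_real_
    }
    structure(
      list(accuracy = (tp + tn) / total, sensitivity = sens,
           specificity = spec,
           accuracy_pct = 100 * (tp + tn) / total,
           sensitivity_pct = 100 * sens, specificity_pct = 100 * spec,
           undefined = undefined, counts = counts),
      class = "metric_report"
    )
  })
}

#' @export
print.metric_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", v)
  cat(sprintf("accuracy %s, sensitivity %s, specificity %s\n",
              fmt(x$accuracy_pct), fmt(x$sensitivity_pct),
              fmt(x$specificity_pct)))
  if (!is.null(x$auc)) cat(sprintf("AUC %.3f\n", x$auc))
  invisible(x)
}

#' ROC curve and area under the curve
#'
#' Threshold sweep over the unique scores (predict positive when
#' `score >= t`), yielding non-decreasing (fpr, tpr) sequences from (0,0)
#' to (1,1); the AUC is the trapezoidal area, which equals the
#' Mann--Whitney probability that a random positive case scores above a
#' random negative one, with half credit for ties.
#'
#' @param scores Numeric scores (larger = more malignant).
#' @param labels 0/1 vector with both classes present.
#' @return Object of class `roc_curve`: list with `thresholds`, `fpr`,
#'   `tpr`, `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    stop("validation error: scores and labels differ in length",
         call. = FALSE)
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos < 1 || n_neg < 1) {
    stop("validation error: ROC needs at least one positive and one negative",
         call. = FALSE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n_neg,
                numeric(1))
  fpr <- c(0, fpr)
  tpr <- c(0, tpr)
  if (fpr[length(fpr)] != 1 || tpr[length(tpr)] != 1) {
    fpr <- c(fpr, 1)
    tpr <- c(tpr, 1)
    thr <- c(thr, -Inf)
  }
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = c(Inf, thr), fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_curve")
}

#' @rdname roc_curve
#' @export
roc_auc <- function(scores, labels) roc_curve(scores, labels)$auc

#' Logistic multiple regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression with an intercept, for the
#' risk-factor analysis relating covariates to the malignant/benign
#' outcome. Convergence when the maximum absolute score (gradient of the
#' log-likelihood) falls below `tol` or after `max_iter` iterations; Wald
#' standard errors come from the inverse observed information. Complete or
#' quasi-complete separation (diverging coefficient norm) is flagged with a
#' warning, not an error.
#'
#' @param design n x d numeric matrix of covariates (no intercept column;
#'   one is added).
#' @param labels 0/1 outcome vector, `n > d + 1`.
#' @param max_iter Maximum IRLS iterations.
#' @param tol Score-norm convergence tolerance.
#' @return Object of class `logistic_fit`: `coefficients` (intercept
#'   first), `se`, `z`, `p_value`, `log_likelihood`, `null_log_likelihood`,
#'   `converged`, `separation`, `iterations`, `score_norm`.
#' @export
logistic_fit <- function(design, labels, max_iter = 100, tol = 1e-8) {
  if (!is.matrix(design)) design <- as.matrix(design)
  labels <- as.numeric(labels)
  n <- nrow(design)
  if (any(!is.finite(design)) || any(!is.finite(labels))) {
    stop("validation error: non-finite values in design or labels",
         call. = FALSE)
  }
  if (n <= ncol(design) + 1) {
    stop("validation error: need n > d + 1 observations", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, design)
  if (is.null(colnames(design))) {
    colnames(X) <- c("(Intercept)", sprintf("x%d", seq_len(ncol(design))))
  }
  d1 <- ncol(X)
  beta <- numeric(d1)
  separation <- FALSE
  iter <- 0L
  score_norm <- Inf
  for (iter in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    score <- crossprod(X, labels - mu)
    score_norm <- max(abs(score))
    if (score_norm < tol) break
    w <- pmax(mu * (1 - mu), 1e-12)
    info <- crossprod(X * w, X)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) { separation <- TRUE; break }
    beta <- beta + as.vector(step)
    if (max(abs(beta)) > 30) separation <- TRUE
  }
  eta <- as.vector(X %*% beta)
  mu <- stats::plogis(eta)
  # diverging coefficients or fully saturated fitted probabilities indicate
  # (quasi-)complete separation: the MLE is at infinity
  if (max(abs(beta)) > 15 || any(mu < 1e-10) || any(mu > 1 - 1e-10)) {
    separation <- TRUE
  }
  ll <- sum(labels * log(pmax(mu, 1e-300)) +
              (1 - labels) * log(pmax(1 - mu, 1e-300)))
  ll0 <- n * log(0.5)  # log-likelihood at the zero coefficient vector
  info <- crossprod(X * pmax(mu * (1 - mu), 1e-12), X)
  vcov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, d1, d1))
  se <- sqrt(diag(vcov))
  z <- beta / se
  converged <- score_norm < tol && !separation
  if (separation) {
    warning("possible complete separation: coefficient estimates diverge",
            call. = FALSE)
  }
  structure(
    list(coefficients = stats::setNames(beta, colnames(X)),
         se = stats::setNames(se, colnames(X)),
         z = stats::setNames(z, colnames(X)),
         p_value = stats::setNames(2 * stats::pnorm(-abs(z)), colnames(X)),
         log_likelihood = ll, null_log_likelihood = ll0,
         converged = converged, separation = separation,
         iterations = iter, score_norm = score_norm),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  tab <- data.frame(estimate = x$coefficients, se = x$se, z = x$z,
                    p = x$p_value)
  print(tab, digits = 4)
  cat(sprintf("log-likelihood %.4f (%s after %d iterations)\n",
              x$log_likelihood,
              if (x$converged) "converged" else "not converged",
              x$iterations))
  invisible(x)
}

#' Evaluate a trained ensemble on held-out data
#'
#' Composition of [predict.adaboost()] (class labels and margins),
#' [confusion_counts()], [classification_metrics()] and [roc_curve()] on
#' the margin scores.
#'
#' @param model A trained [train_adaboost()] model.
#' @param features n x d matrix of held-out feature vectors.
#' @param labels Held-out 0/1 labels.
#' @return A `metric_report` with an extra `auc` field and the `roc` curve
#'   attached.
#' @export
evaluate_pipeline <- function(model, features, labels) {
  pred <- predict(model, features, type = "both")
  report <- classification_metrics(confusion_counts(pred$class, labels))
  roc <- roc_curve(pred$margin, labels)
  report$auc <- roc$auc
  report$roc <- roc
  report
}
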