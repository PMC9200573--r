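check_training <- function(features, labels) {
  if (!is.matrix(features)) features <- as.matrix(features)
  if (any(!is.finite(features))) {
    stop("validation error: features contain non-finite values",
         call. = FALSE)
  }
  labels <- as.integer(labels)
  if (nrow(features) != length(labels)) {
    stop("validation error: nrow(features) must equal length(labels)",
         call. = FALSE)
  }
  if (!all(labels %in% c(0L, 1L))) {
    stop("validation error: labels must be 0/1", call. = FALSE)
  }
  list(features = features, labels = labels)
}

stump_predict <- function(stump, features) {
  x <- features[, stump$feature]
  if (stump$polarity == "le") as.integer(x <= stump$threshold)
  else as.integer(x > stump$threshold)
}

#' Fit the best decision stump under example weights
#'
#' Exhaustive search over every feature, every candidate threshold and both
#' polarities (`"le"`: predict 1 when `x <= t`; `"gt"`: predict 1 when
#' `x > t`), minimizing the weighted 0/1 error. The candidate thresholds of
#' a feature are the midpoints of its consecutive sorted unique values,
#' plus one threshold below the smallest value so that the two constant
#' classifiers are representable (as they are for a depth-1 tree whose
#' leaves may agree). Ties are broken by lowest feature index, then lowest
#' threshold, then `"le"` polarity first.
#'
#' @param features n x d numeric matrix.
#' @param labels 0/1 vector of length n.
#' @param weights Non-negative example weights summing to 1 (default
#'   uniform).
#' @return Object of class `stump`: list with `feature`, `threshold`,
#'   `polarity`, `error` (the weighted error). If no feature has two
#'   distinct values the stump is flagged `degenerate = TRUE` and predicts
#'   the weighted majority class.
#' @export
fit_stump <- function(features, labels, weights = NULL) {
  d0 <- check_training(features, labels)
  features <- d0$features
  labels <- d0$labels
  n <- nrow(features)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n || any(weights < 0)) {
    stop("validation error: weights must be n non-negative reals",
         call. = FALSE)
  }
  w1 <- sum(weights[labels == 1L])     # total weight of positives
  best <- NULL
  for (j in seq_len(ncol(features))) {
    x <- features[, j]
    u <- sort(unique(x))
    if (length(u) < 2) next
    # midpoints of consecutive unique values, plus one threshold below the
    # minimum so constant predictions are representable (a depth-1 tree can
    # put the same class in both leaves; without this, weighted-majority
    # votes of stumps provably cannot fit non-monotone 1-D patterns such as
    # an interval class)
    thr <- c(u[1] - (u[2] - u[1]) / 2, (u[-length(u)] + u[-1]) / 2)
    ord <- order(x)
    xo <- x[ord]
    # cum0[k+1], cum1[k+1]: class weight among the k smallest values
    cum0 <- c(0, cumsum(weights[ord] * (labels[ord] == 0L)))
    cum1 <- c(0, cumsum(weights[ord] * (labels[ord] == 1L)))
    # number of observations <= each threshold (0 for the below-min one)
    k <- findInterval(thr, xo) + 1L
    # polarity "le": predict 1 for x <= t -> errors = w0 below + w1 above
    err_le <- cum0[k] + (w1 - cum1[k])
    # polarity "gt": predict 1 for x > t
    err_gt <- cum1[k] + (sum(weights) - w1 - cum0[k])
    for (pol in c("le", "gt")) {
      errs <- if (pol == "le") err_le else err_gt
      i <- which.min(errs)  # lowest threshold among ties (thr is sorted)
      cand <- list(feature = j, threshold = thr[i], polarity = pol,
                   error = errs[i])
      if (is.null(best) ||
          cand$error < best$error - 1e-12 ||
          (abs(cand$error - best$error) <= 1e-12 &&
             (cand$feature < best$feature ||
                (cand$feature == best$feature &&
                   (cand$threshold < best$threshold - 1e-12 ||
                      (abs(cand$threshold - best$threshold) <= 1e-12 &&
                         pol == "le" && best$polarity == "gt")))))) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    maj <- as.integer(w1 >= sum(weights) / 2)
    best <- list(feature = 1L, threshold = Inf,
                 polarity = if (maj == 1L) "le" else "gt",
                 error = min(w1, sum(weights) - w1), degenerate = TRUE)
  }
  structure(best, class = "stump")
}

#' AdaBoost weight update after one round
#'
#' Correctly classified examples are multiplied by
#' `beta_t = eps_t / (1 - eps_t)` (shrinking their weight, since
#' `eps_t < 1/2`) and the vector is renormalized to sum 1, so misclassified
#' examples gain relative weight. After the update the total weight on the
#' previously misclassified examples is exactly 1/2.
#'
#' @param weights Current example weights (sum 1).
#' @param stump The fitted stump of this round (provides `error`).
#' @param predictions The stump's 0/1 predictions on the training examples.
#' @param labels True 0/1 labels.
#' @return Updated weights summing to 1.
#' @export
update_weights <- function(weights, stump, predictions, labels) {
  eps <- stump$error
  if (eps <= 0 || eps >= 0.5) {
    stop("validation error: update requires 0 < error < 0.5 (early stop handles the rest)",
         call. = FALSE)
  }
  beta <- eps / (1 - eps)
  correct <- as.integer(predictions) == as.integer(labels)
  w <- weights * ifelse(correct, beta, 1)
  w / sum(w)
}

#' Train an AdaBoost ensemble of decision stumps
#'
#' Classical discrete AdaBoost: starting from uniform example weights, each
#' round fits the best weighted stump, records `beta_t = eps_t/(1-eps_t)`,
#' and reweights examples toward the misclassified ones. A round with
#' `eps_t = 0` is retained with `beta_t` floored at `eps_floor` and training
#' stops; a round with `eps_t >= 0.5` is dropped and training stops. The
#' procedure is deterministic given the data ordering (`seed` is accepted
#' for interface symmetry with the stochastic stages but is not consumed).
#'
#' @param features n x d numeric matrix (rows = images).
#' @param labels 0/1 vector (1 = malignant = positive class).
#' @param rounds Maximum number of boosting rounds T.
#' @param feature_names Optional column names for the model record.
#' @param seed Ignored; training is deterministic.
#' @param eps_floor Value substituted for a zero weighted error.
#' @return Object of class `adaboost`: `stumps`, `beta` (the per-round
#'   `beta_t`, each in (0,1)), `rounds` (retained T), `history` (per-round
#'   error and weighted accuracy), `feature_names`.
#' @export
train_adaboost <- function(features, labels, rounds = 50,
                           feature_names = NULL, seed = NULL,
                           eps_floor = 1e-10) {
  d0 <- check_training(features, labels)
  features <- d0$features
  labels <- d0$labels
  if (rounds < 1) stop("validation error: 'rounds' must be >= 1",
                       call. = FALSE)
  if (length(unique(labels)) < 2) {
    stop("validation error: training data contains a single class",
         call. = FALSE)
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(features)
    if (is.null(feature_names)) {
      feature_names <- sprintf("f%d", seq_len(ncol(features)))
    }
  }
  n <- nrow(features)
  w <- rep(1 / n, n)
  stumps <- list()
  beta <- numeric(0)
  history <- data.frame(round = integer(0), error = numeric(0),
                        weighted_accuracy = numeric(0))
  for (t in seq_len(rounds)) {
    st <- fit_stump(features, labels, w)
    eps <- st$error
    if (eps >= 0.5) break                       # no better than chance: stop
    pred <- stump_predict(st, features)
    stumps[[length(stumps) + 1L]] <- st
    history <- rbind(history, data.frame(round = t, error = eps,
                                         weighted_accuracy = 1 - eps))
    if (eps <= 0) {                             # perfect round
      beta <- c(beta, eps_floor)
      break
    }
    beta <- c(beta, eps / (1 - eps))
    w <- update_weights(w, st, pred, labels)
  }
  if (length(stumps) == 0) {
    stop("validation error: no stump with weighted error below 0.5",
         call. = FALSE)
  }
  structure(
    list(stumps = stumps, beta = beta, rounds = length(stumps),
         history = history, feature_names = feature_names),
    class = "adaboost"
  )
}

#' Predict with an AdaBoost ensemble
#'
#' The strong-classifier weighted-majority rule: with round weights
#' `alpha_t = log(1/beta_t)`, predict 1 when
#' `sum_t alpha_t h_t(x) >= (1/2) sum_t alpha_t`. The margin
#' `sum_t alpha_t h_t(x) - (1/2) sum_t alpha_t` is the continuous score
#' used for ROC analysis.
#'
#' @param object A trained [train_adaboost()] model.
#' @param features A d-vector or n x d matrix.
#' @param type `"class"` (0/1), `"margin"`, or `"both"` (data frame).
#' @param ... Unused.
#' @return Per `type`: integer labels, numeric margins, or both.
#' @export
predict.adaboost <- function(object, features,
                             type = c("class", "margin", "both"), ...) {
  type <- match.arg(type)
  if (is.vector(features)) features <- matrix(features, nrow = 1)
  d <- max(vapply(object$stumps, function(s) s$feature, integer(1)))
  if (ncol(features) < d) {
    stop("validation error: feature dimension mismatch", call. = FALSE)
  }
  alpha <- log(1 / object$beta)
  votes <- vapply(object$stumps, stump_predict, integer(nrow(features)),
                  features = features)
  if (is.vector(votes)) votes <- matrix(votes, nrow = nrow(features))
  score <- as.vector(votes %*% alpha)
  margin <- score - sum(alpha) / 2
  class <- as.integer(margin >= 0)
  switch(type,
    class = class,
    margin = margin,
    both = data.frame(class = class, margin = margin)
  )
}

#' @export
print.adaboost <- function(x, ...) {
  cat(sprintf("adaboost ensemble: %d stump(s) over %d feature(s)\n",
              x$rounds, length(x$feature_names)))
  cat(sprintf("  final weighted error: %.4g\n",
              x$history$error[nrow(x$history)]))
  invisible(x)
}

#' Stratified train/test split
#'
#' Splits indices into train and test sets preserving the class balance,
#' deterministically for a given seed.
#'
#' @param labels 0/1 vector.
#' @param test_fraction Fraction of each class held out (default 0.3).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, test_fraction = 0.3, seed = 0L) {
  labels <- as.integer(labels)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("validation error: 'test_fraction' must be in (0, 1)", call. = FALSE)
  }
  with_seed(seed, {
    test <- integer(0)
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      n_test <- round(length(idx) * test_fraction)
      test <- c(test, sort(sample(idx, n_test)))
    }
    test <- sort(test)
    list(train = setdiff(seq_along(labels), test), test = test)
  })
}

#' Serialize an AdaBoost model to JSON
#'
#' @param model A [train_adaboost()] model.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  stumps <- lapply(model$stumps, function(s) {
    list(feature = s$feature, threshold = s$threshold,
         polarity = s$polarity, error = s$error)
  })
  jsonlite::write_json(
    list(type = "adaboost", rounds = model$rounds, beta = model$beta,
         stumps = stumps, feature_names = model$feature_names),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read an AdaBoost model from JSON
#'
#' @param path Path written by [write_model()].
#' @return An `adaboost` model.
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(j$type, "adaboost")) {
    stop("validation error: not an adaboost model file", call. = FALSE)
  }
  stumps <- lapply(j$stumps, function(s) {
    structure(list(feature = as.integer(s$feature), threshold = s$threshold,
                   polarity = s$polarity, error = s$error), class = "stump")
  })
  structure(
    list(stumps = stumps, beta = as.numeric(j$beta),
         rounds = as.integer(j$rounds), history = NULL,
         feature_names = as.character(j$feature_names)),
    class = "adaboost"
  )
}
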