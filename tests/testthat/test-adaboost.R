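test_that("stump fitting solves separable and non-separable 1-D cases", {
  # separable: zero weighted error, threshold between the classes
  X <- matrix(c(-2, -1, 1, 2), 4, 1)
  st <- fit_stump(X, c(0, 0, 1, 1))
  expect_equal(st$error, 0)
  expect_true(st$threshold > -1 && st$threshold < 1)

  # interval labels: best achievable weighted error is 0.25
  st2 <- fit_stump(matrix(1:4, 4, 1), c(0, 1, 1, 0))
  expect_equal(st2$error, 0.25)

  # degenerate: single distinct value per feature
  st3 <- fit_stump(matrix(1, 4, 1), c(0, 1, 1, 1))
  expect_true(isTRUE(st3$degenerate))
})

test_that("stump fitting equals exhaustive enumeration on random data", {
  set.seed(16)
  for (rep in 1:10) {
    n <- sample(5:20, 1)
    d <- sample(1:3, 1)
    X <- matrix(round(rnorm(n * d), 2), n, d)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1] <- 1 - y[1]
    w <- runif(n)
    w <- w / sum(w)
    got <- fit_stump(X, y, w)
    ref <- oracle_best_stump(X, y, w)
    expect_equal(got$error, ref$error, tolerance = 1e-12)
    expect_identical(got$feature, ref$feature)
    expect_equal(got$threshold, ref$threshold, tolerance = 1e-12)
    expect_identical(got$polarity, ref$polarity)
  }
})

test_that("weight update halves the mass of misclassified examples", {
  # eps = 0.25: after the update the previously misclassified examples carry
  # exactly half the total weight
  w <- rep(1 / 4, 4)
  labels <- c(0, 1, 1, 0)
  predictions <- c(0, 1, 1, 1)             # one error, weighted error 0.25
  st <- structure(list(error = 0.25), class = "stump")
  w2 <- update_weights(w, st, predictions, labels)
  expect_equal(sum(w2), 1, tolerance = 1e-12)
  expect_equal(sum(w2[predictions != labels]), 0.5, tolerance = 1e-12)

  # the identity holds for any eps in (0, 1/2)
  set.seed(17)
  for (rep in 1:5) {
    n <- 12
    y <- rbinom(n, 1, 0.5)
    pred <- y
    flip <- sample(n, 3)
    pred[flip] <- 1 - pred[flip]
    w <- runif(n)
    w <- w / sum(w)
    eps <- sum(w[pred != y])
    if (eps <= 0 || eps >= 0.5) next
    st <- structure(list(error = eps), class = "stump")
    w2 <- update_weights(w, st, pred, y)
    expect_equal(sum(w2[pred != y]), 0.5, tolerance = 1e-12)
  }

  expect_error(update_weights(w, structure(list(error = 0.6), class = "stump"),
                              predictions, labels), "error")
})

test_that("boosting drives training error to zero and keeps invariants", {
  # separable data: solved in one round
  Xs <- matrix(c(-2, -1, 1, 2), 4, 1)
  ms <- train_adaboost(Xs, c(0, 0, 1, 1), rounds = 5)
  expect_identical(ms$rounds, 1L)
  expect_identical(predict(ms, Xs), c(0L, 0L, 1L, 1L))

  # interval-labeled data: zero training error within 10 rounds
  Xi <- matrix(1:4, 4, 1)
  yi <- c(0L, 1L, 1L, 0L)
  mi <- train_adaboost(Xi, yi, rounds = 10)
  expect_identical(predict(mi, Xi), yi)

  # every retained round: eps < 0.5 and beta in (0, 1)
  expect_true(all(mi$history$error < 0.5))
  expect_true(all(mi$beta > 0 & mi$beta < 1))

  # the training-error bound prod 2 sqrt(eps (1 - eps)) is decreasing in T
  bound <- cumprod(2 * sqrt(mi$history$error * (1 - mi$history$error) +
                              1e-300))
  expect_true(all(diff(bound) <= 0))

  expect_error(train_adaboost(Xi, c(1, 1, 1, 1)), "single class")
})

test_that("example weights sum to one after every boosting round", {
  # replicate the training recurrence explicitly
  set.seed(18)
  n <- 30
  X <- cbind(rnorm(n), rnorm(n))
  y <- as.integer(X[, 1] + 0.8 * rnorm(n) > 0)
  if (length(unique(y)) < 2) y[1] <- 1 - y[1]
  w <- rep(1 / n, n)
  for (t in 1:8) {
    st <- fit_stump(X, y, w)
    if (st$error <= 0 || st$error >= 0.5) break
    pred <- if (st$polarity == "le") as.integer(X[, st$feature] <= st$threshold)
            else as.integer(X[, st$feature] > st$threshold)
    w <- update_weights(w, st, pred, y)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
  }
})

test_that("the strong-classifier rule matches its direct evaluation", {
  # every weak hypothesis voting 1 forces H = 1
  expect_identical(oracle_strong_classify(c(1, 1, 1), c(0.2, 0.3, 0.4)), 1L)

  # T = 1: ensemble equals its single stump
  X <- matrix(c(-2, -1, 1, 2), 4, 1)
  m1 <- train_adaboost(X, c(0, 0, 1, 1), rounds = 1)
  st <- m1$stumps[[1]]
  stump_pred <- if (st$polarity == "le") as.integer(X <= st$threshold)
                else as.integer(X > st$threshold)
  expect_identical(predict(m1, X), stump_pred)

  # random ensembles: prediction equals brute-force evaluation of the
  # weighted-majority rule over enumerated weak outputs
  set.seed(19)
  for (rep in 1:20) {
    T_ <- sample(1:6, 1)
    beta <- runif(T_, 0.05, 0.45)
    stumps <- lapply(seq_len(T_), function(t) {
      structure(list(feature = 1L, threshold = runif(1, -1, 1),
                     polarity = sample(c("le", "gt"), 1),
                     error = beta[t] / (1 + beta[t])), class = "stump")
    })
    model <- structure(list(stumps = stumps, beta = beta, rounds = T_,
                            feature_names = "f1"), class = "adaboost")
    x <- matrix(runif(1, -2, 2), 1, 1)
    weak <- vapply(stumps, function(s) {
      if (s$polarity == "le") as.integer(x[1] <= s$threshold)
      else as.integer(x[1] > s$threshold)
    }, integer(1))
    expect_identical(predict(model, x), oracle_strong_classify(weak, beta))
    # margin sign is consistent with the class
    pm <- predict(model, x, type = "both")
    expect_identical(pm$class, as.integer(pm$margin >= 0))
  }

  expect_error(predict(m1, matrix(0, 1, 0)), "dimension")
})

test_that("model JSON serialization round-trips predictions", {
  set.seed(20)
  X <- cbind(a = rnorm(20), b = rnorm(20))
  y <- as.integer(X[, 1] > 0.2)
  if (length(unique(y)) < 2) y[1] <- 1 - y[1]
  m <- train_adaboost(X, y, rounds = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  Xnew <- cbind(rnorm(10), rnorm(10))
  expect_identical(predict(m, Xnew), predict(m2, Xnew))
  expect_equal(m2$beta, m$beta, tolerance = 1e-15)
})

test_that("stratified splitting preserves class balance deterministically", {
  labels <- c(rep(0L, 40), rep(1L, 60))
  sp <- stratified_split(labels, 0.3, seed = 2)
  expect_identical(sp, stratified_split(labels, 0.3, seed = 2))
  expect_identical(length(intersect(sp$train, sp$test)), 0L)
  expect_identical(sort(c(sp$train, sp$test)), 1:100)
  expect_identical(sum(labels[sp$test] == 0L), 12L)
  expect_identical(sum(labels[sp$test] == 1L), 18L)
})
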