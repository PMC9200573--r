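# Orthonormal analysis filters. db2 is the 4-tap Daubechies filter; both
# satisfy sum(h^2) = 1 and orthogonality of even shifts, so the periodized
# transform is exactly orthogonal and conserves energy.
wavelet_filters <- function(wavelet = c("db2", "haar")) {
  wavelet <- match.arg(wavelet)
  h <- switch(wavelet,
    haar = c(1, 1) / sqrt(2),
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
  )
  n <- length(h)
  g <- rev(h) * (-1)^(seq_len(n) - 1)   # quadrature mirror high-pass
  list(low = h, high = g, length = n, name = wavelet)
}

# One periodized analysis step along the rows dimension (dim 1):
# returns rbind(approximation, detail), each with n/2 rows.
# a_k = sum_m h_m x_{(2k + m) mod n}.
dwt_step_rows <- function(x, filt) {
  n <- nrow(x)
  half <- n %/% 2L
  k2 <- 2L * (seq_len(half) - 1L)
  a <- matrix(0, half, ncol(x))
  d <- matrix(0, half, ncol(x))
  for (m in seq_len(filt$length) - 1L) {
    idx <- (k2 + m) %% n + 1L
    a <- a + filt$low[m + 1L] * x[idx, , drop = FALSE]
    d <- d + filt$high[m + 1L] * x[idx, , drop = FALSE]
  }
  rbind(a, d)
}

#' Multi-level separable 2-D discrete wavelet decomposition
#'
#' Periodized orthonormal filter-bank decomposition: at each level the
#' rows dimension and then the columns dimension are split into low- and
#' high-pass halves with downsampling, producing four subbands, and the
#' approximation `LL` is decomposed further. Subband naming (first letter =
#' filter along the row index, second = along the column index):
#' `LH` (row-low / col-high) carries vertical image features, `HL`
#' (row-high / col-low) carries horizontal features, and `HH` the diagonal
#' features. With periodization and an orthonormal wavelet the total
#' squared-coefficient mass equals the input squared-pixel mass.
#'
#' @param image Numeric matrix; both dimensions must be divisible by
#'   `2^levels` and at least the filter length at every level.
#' @param wavelet `"db2"` (default) or `"haar"`.
#' @param levels Number of decomposition levels, >= 1.
#' @return Object of class `dwt2`: list of per-level subband sets, each a
#'   list with `LL`, `LH`, `HL`, `HH`, `level`, `wavelet`.
#' @export
dwt2_decompose <- function(image, wavelet = "db2", levels = 1) {
  check_image(image)
  filt <- wavelet_filters(wavelet)
  if (levels < 1) stop("validation error: 'levels' must be >= 1",
                       call. = FALSE)
  out <- vector("list", levels)
  cur <- image
  for (lev in seq_len(levels)) {
    if (nrow(cur) %% 2L != 0L || ncol(cur) %% 2L != 0L ||
        nrow(cur) < filt$length || ncol(cur) < filt$length) {
      stop(sprintf(
        "validation error: too many levels for image size (level %d needs even dimensions >= %d, got %d x %d)",
        lev, filt$length, nrow(cur), ncol(cur)
      ), call. = FALSE)
    }
    tmp <- dwt_step_rows(cur, filt)                 # split rows dim
    tmp <- t(dwt_step_rows(t(tmp), filt))           # split cols dim
    hr <- nrow(cur) %/% 2L
    hc <- ncol(cur) %/% 2L
    out[[lev]] <- list(
      LL = tmp[1:hr, 1:hc, drop = FALSE],
      LH = tmp[1:hr, (hc + 1):(2 * hc), drop = FALSE],
      HL = tmp[(hr + 1):(2 * hr), 1:hc, drop = FALSE],
      HH = tmp[(hr + 1):(2 * hr), (hc + 1):(2 * hc), drop = FALSE],
      level = lev, wavelet = filt$name
    )
    cur <- out[[lev]]$LL
  }
  structure(out, class = "dwt2")
}

#' Normalized subband energy features
#'
#' Per decomposition level, the energy of each subband is the mean of its
#' squared coefficients, normalized so the four shares of that level sum
#' to 1.
#'
#' @param subbands A [dwt2_decompose()] result.
#' @return Named numeric vector `E_LL_l1, E_LH_l1, E_HL_l1, E_HH_l1, ...`
#'   (4 shares per level).
#' @export
wavelet_energy_features <- function(subbands) {
  if (!inherits(subbands, "dwt2") || length(subbands) < 1) {
    stop("validation error: 'subbands' must be a non-empty dwt2 decomposition",
         call. = FALSE)
  }
  feats <- numeric(0)
  for (sb in subbands) {
    e <- c(mean(sb$LL^2), mean(sb$LH^2), mean(sb$HL^2), mean(sb$HH^2))
    share <- e / sum(e)
    names(share) <- sprintf("E_%s_l%d", c("LL", "LH", "HL", "HH"), sb$level)
    feats <- c(feats, share)
  }
  feats
}

#' Wavelet subband energy features of an image
#'
#' Composition of [dwt2_decompose()] and [wavelet_energy_features()]; the
#' wavelet-transform half of the package's feature vector.
#'
#' @inheritParams dwt2_decompose
#' @return Named numeric vector of length `4 * levels`.
#' @export
extract_awt <- function(image, wavelet = "db2", levels = 1) {
  wavelet_energy_features(dwt2_decompose(image, wavelet, levels))
}

#' Select wavelet family and depth by cross-validated training accuracy
#'
#' Realizes the "adaptive" choice of the wavelet stage: each candidate
#' (family, levels) pair is scored by k-fold cross-validated accuracy of a
#' small boosted-stump classifier trained on the wavelet energy features
#' alone, using training data only.
#'
#' @param images List of numeric matrices (training images).
#' @param labels 0/1 labels.
#' @param wavelets Candidate families.
#' @param levels Candidate depths.
#' @param folds Number of CV folds.
#' @param rounds Boosting rounds per fold.
#' @param seed Integer seed for the fold assignment.
#' @return List `wavelet`, `levels`, `cv_accuracy` and the full score table.
#' @export
select_wavelet <- function(images, labels, wavelets = c("haar", "db2"),
                           levels = c(1, 2), folds = 5, rounds = 10,
                           seed = 0L) {
  labels <- as.integer(labels)
  n <- length(images)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  grid <- expand.grid(wavelet = wavelets, levels = levels,
                      stringsAsFactors = FALSE)
  grid$cv_accuracy <- NA_real_
  for (i in seq_len(nrow(grid))) {
    feats <- t(vapply(images, extract_awt, numeric(4 * grid$levels[i]),
                      wavelet = grid$wavelet[i], levels = grid$levels[i]))
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (length(unique(labels[tr])) < 2) next
      model <- train_adaboost(feats[tr, , drop = FALSE], labels[tr],
                              rounds = rounds)
      pred <- predict(model, feats[!tr, , drop = FALSE])
      correct <- correct + sum(pred == labels[!tr])
    }
    grid$cv_accuracy[i] <- correct / n
  }
  best <- which.max(grid$cv_accuracy)
  list(wavelet = grid$wavelet[best], levels = grid$levels[best],
       cv_accuracy = grid$cv_accuracy[best], scores = grid)
}
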