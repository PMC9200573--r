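# Independent brute-force oracles and fixture builders. Every oracle is a
# direct transcription of the defining formula (explicit loops, explicit
# matrices), deliberately sharing no code path with the implementation.

# --- images ---------------------------------------------------------------

# half-sample symmetric reflection of index t into 1..n
refl_idx <- function(t, n) {
  if (t < 1) return(1 - t)
  if (t > n) return(2 * n + 1 - t)
  t
}

# true 2-D convolution by quadruple loop, symmetric reflection boundary
oracle_conv <- function(image, kernel) {
  n <- nrow(image); m <- ncol(image)
  pr <- (nrow(kernel) - 1) / 2; pc <- (ncol(kernel) - 1) / 2
  out <- matrix(0, n, m)
  for (i in 1:n) for (j in 1:m) {
    acc <- 0
    for (a in -pr:pr) for (b in -pc:pc) {
      acc <- acc + kernel[a + pr + 1, b + pc + 1] *
        image[refl_idx(i - a, n), refl_idx(j - b, m)]
    }
    out[i, j] <- acc
  }
  out
}

# sinusoidal grating: intensity varies along direction theta
make_grating <- function(n, frequency, theta) {
  r <- matrix(rep(1:n, n), n, n)
  c_ <- t(r)
  cos(2 * pi * frequency * (r * cos(theta) + c_ * sin(theta)))
}

# horizontal stripes: constant within each row, alternating row to row
# (period 2, so the single-level high-pass sees the variation)
make_stripes_horizontal <- function(n) {
  matrix(rep(rep(c(0, 1), length.out = n), n), n, n)
}

# --- GLCM -----------------------------------------------------------------

# pair-count co-occurrence by double loop; de/dg in (row, col) displacement
oracle_glcm_counts <- function(qmat, L, de, dg) {
  counts <- matrix(0L, L, L)
  nr <- nrow(qmat); nc <- ncol(qmat)
  for (e in 1:nr) for (g in 1:nc) {
    e2 <- e + de; g2 <- g + dg
    if (e2 >= 1 && e2 <= nr && g2 >= 1 && g2 <= nc) {
      q <- qmat[e, g]; z <- qmat[e2, g2]
      counts[q + 1, z + 1] <- counts[q + 1, z + 1] + 1L
    }
  }
  counts
}

# the ten texture statistics by explicit double loops over P(q, z)
oracle_texture_features <- function(p) {
  L <- nrow(p)
  mu_e <- 0; mu_g <- 0
  for (q in 0:(L - 1)) for (z in 0:(L - 1)) {
    mu_e <- mu_e + q * p[q + 1, z + 1]
    mu_g <- mu_g + z * p[q + 1, z + 1]
  }
  s_e <- 0; s_g <- 0
  for (q in 0:(L - 1)) for (z in 0:(L - 1)) {
    s_e <- s_e + (q - mu_e)^2 * p[q + 1, z + 1]
    s_g <- s_g + (z - mu_g)^2 * p[q + 1, z + 1]
  }
  s_e <- sqrt(s_e); s_g <- sqrt(s_g)
  ac <- ct <- cr <- cp <- cs <- d <- en <- et <- h <- 0
  mp <- -Inf
  for (q in 0:(L - 1)) for (z in 0:(L - 1)) {
    pv <- p[q + 1, z + 1]
    ac <- ac + q * z * pv
    ct <- ct + (q - z)^2 * pv
    if (s_e * s_g > 0) cr <- cr + (q - mu_e) * (z - mu_g) * pv / (s_e * s_g)
    cp <- cp + (q + z - mu_e - mu_g)^4 * pv
    cs <- cs + (q + z - mu_e - mu_g)^3 * pv
    d <- d + abs(q - z) * pv
    en <- en + pv^2
    if (pv > 0) et <- et - pv * log2(pv)
    h <- h + pv / (1 + (q - z)^2)
    if (pv > mp) mp <- pv
  }
  c(AC = ac, CT = ct, CR = cr, CP = cp, CS = cs, D = d, EN = en, ET = et,
    H = h, MP = mp)
}

random_prob_matrix <- function(L) {
  p <- matrix(stats::runif(L * L), L, L)
  p / sum(p)
}

# --- wavelets -------------------------------------------------------------

# explicit orthogonal one-level periodized DWT matrix: rows 1..n/2 carry the
# low-pass filter at even shifts, rows n/2+1..n the quadrature high-pass
oracle_dwt_matrix <- function(n, wavelet) {
  h <- switch(wavelet,
    haar = c(1, 1) / sqrt(2),
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
  )
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  W <- matrix(0, n, n)
  for (k in 0:(n / 2 - 1)) {
    for (m in seq_along(h) - 1) {
      col <- (2 * k + m) %% n + 1
      W[k + 1, col] <- W[k + 1, col] + h[m + 1]
      W[n / 2 + k + 1, col] <- W[n / 2 + k + 1, col] + g[m + 1]
    }
  }
  W
}

# --- boosting -------------------------------------------------------------

# enumerate every stump (feature x threshold x polarity) with the documented
# candidate set (below-min threshold + interior midpoints) and tie-break
# (lowest error, feature, threshold, then "le" before "gt")
oracle_best_stump <- function(X, y, w = rep(1 / nrow(X), nrow(X))) {
  best <- NULL
  for (j in seq_len(ncol(X))) {
    u <- sort(unique(X[, j]))
    if (length(u) < 2) next
    thr <- c(u[1] - (u[2] - u[1]) / 2, (u[-length(u)] + u[-1]) / 2)
    for (t in thr) for (pol in c("le", "gt")) {
      pred <- if (pol == "le") as.integer(X[, j] <= t) else
        as.integer(X[, j] > t)
      err <- sum(w[pred != y])
      better <- is.null(best) || err < best$error - 1e-12 ||
        (abs(err - best$error) <= 1e-12 &&
           (j < best$feature ||
              (j == best$feature &&
                 (t < best$threshold - 1e-12 ||
                    (abs(t - best$threshold) <= 1e-12 && pol == "le" &&
                       best$polarity == "gt")))))
      if (better) best <- list(feature = j, threshold = t, polarity = pol,
                               error = err)
    }
  }
  best
}

# strong-classifier decision evaluated directly from the printed rule
oracle_strong_classify <- function(weak_outputs, beta) {
  lhs <- 0; rhs <- 0
  for (t in seq_along(beta)) {
    lhs <- lhs + log(1 / beta[t]) * weak_outputs[t]
    rhs <- rhs + log(1 / beta[t])
  }
  as.integer(lhs >= rhs / 2)
}

# --- evaluation -----------------------------------------------------------

# Mann-Whitney pair count with half credit for ties, O(n^2)
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# coarse-to-fine grid search of the logistic log-likelihood (d = 1)
oracle_logistic_grid <- function(x, y, lo = c(-6, -6), hi = c(6, 6),
                                 steps = 41, refinements = 8) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  for (r in seq_len(refinements)) {
    b0s <- seq(lo[1], hi[1], length.out = steps)
    b1s <- seq(lo[2], hi[2], length.out = steps)
    vals <- outer(b0s, b1s, Vectorize(ll))
    best <- arrayInd(which.max(vals), dim(vals))
    b0 <- b0s[best[1]]; b1 <- b1s[best[2]]
    span0 <- (hi[1] - lo[1]) / (steps - 1)
    span1 <- (hi[2] - lo[2]) / (steps - 1)
    lo <- c(b0 - span0, b1 - span1)
    hi <- c(b0 + span0, b1 + span1)
  }
  c(b0, b1)
}

# tiny fast synthetic config for pipeline tests
small_pipeline_config <- function(n_benign = 8, n_malignant = 12, seed = 0,
                                  rounds = 10) {
  pipeline_config(
    synthetic = synthetic_config(
      image_size = c(32, 32), n_benign = n_benign,
      n_malignant = n_malignant, seed = seed
    ),
    gabor_frequencies = c(0.1, 0.3), rounds = rounds, seed = seed
  )
}
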