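test_that("quantization bins match direct digitization", {
  # 0..255 at L = 256 is the identity
  img <- matrix(0:255, 16, 16)
  expect_equal(quantize_image(img, 256)$data, img)

  expect_equal(quantize_image(matrix(c(0, 255, 255, 0), 2, 2), 2)$data,
               matrix(c(0L, 1L, 1L, 0L), 2, 2))

  # brute-force equal-width binning oracle
  set.seed(4)
  img <- matrix(runif(64, -3, 9), 8, 8)
  for (L in c(2, 5, 32)) {
    q <- quantize_image(img, L)$data
    expect_true(all(q >= 0 & q <= L - 1))
    ref <- floor((img - min(img)) / (max(img) - min(img)) * L)
    ref[ref == L] <- L - 1
    expect_equal(q, matrix(as.integer(ref), 8, 8))
  }

  # constant image maps to level 0 everywhere
  expect_true(all(quantize_image(matrix(3, 4, 4), 8)$data == 0L))
  expect_error(quantize_image(matrix(1, 4, 4), 1), "levels")
})

test_that("co-occurrence counts equal exhaustive pair enumeration", {
  # hand-enumerated 2x2 case at the horizontal offset
  qi <- quantize_image(matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE), 2)
  g <- compute_glcm(qi, glcm_offset(0, 1), normalize = FALSE)
  expect_identical(g$counts, matrix(c(1L, 0L, 0L, 1L), 2, 2))

  # constant image: all mass in cell (0,0), count = number of valid pairs
  qc <- quantize_image(matrix(1, 5, 7), 4)
  gc_ <- compute_glcm(qc, glcm_offset(45, 2), normalize = FALSE)
  expect_identical(gc_$counts[1, 1], 3L * 5L)
  expect_identical(sum(gc_$counts), 3L * 5L)

  # random images, all four orientations, against the double-loop oracle
  set.seed(31)
  for (rep in 1:5) {
    img <- matrix(runif(64), 8, 8)
    qi <- quantize_image(img, 4)
    for (o in c(0, 45, 90, 135)) {
      off <- glcm_offset(o, 1)
      g <- compute_glcm(qi, off, normalize = TRUE)
      ref <- oracle_glcm_counts(qi$data, 4, off$displacement[1],
                                off$displacement[2])
      expect_identical(g$counts, ref)
      expect_equal(sum(g$probabilities), 1, tolerance = 1e-12)
    }
  }
  expect_error(compute_glcm(qi, glcm_offset(0, 10)), "extent")
})

test_that("marginal statistics match direct summation", {
  # symmetric GLCM: row and column marginals coincide
  set.seed(5)
  p <- random_prob_matrix(4)
  p_sym <- (p + t(p)) / 2
  m <- glcm_marginals(p_sym)
  expect_equal(m$mu_e, m$mu_g, tolerance = 1e-12)
  expect_equal(m$sigma_e, m$sigma_g, tolerance = 1e-12)

  # single cell P(2,3) = 1
  p1 <- matrix(0, 5, 5)
  p1[3, 4] <- 1
  m1 <- glcm_marginals(p1)
  expect_equal(c(m1$mu_e, m1$mu_g, m1$sigma_e, m1$sigma_g), c(2, 3, 0, 0))

  # random 4x4 against explicit sums
  p <- random_prob_matrix(4)
  m <- glcm_marginals(p)
  idx <- 0:3
  expect_equal(m$mu_e, sum(idx * rowSums(p)), tolerance = 1e-12)
  expect_equal(m$sigma_g, sqrt(sum((idx - sum(idx * colSums(p)))^2 *
                                     colSums(p))), tolerance = 1e-12)

  qi <- quantize_image(matrix(runif(16), 4, 4), 2)
  expect_error(glcm_marginals(compute_glcm(qi, normalize = FALSE)),
               "normalized")
})

test_that("the ten features match analytic values and the loop oracle", {
  # all mass on one diagonal cell
  p <- matrix(0, 4, 4)
  p[3, 3] <- 1
  f <- texture_features(p)
  expect_equal(f[["CT"]], 0)
  expect_equal(f[["D"]], 0)
  expect_equal(f[["H"]], 1)
  expect_equal(f[["EN"]], 1)
  expect_equal(f[["ET"]], 0)
  expect_equal(f[["MP"]], 1)
  expect_true(isTRUE(attr(f, "degenerate_marginal")))  # sigma_e = sigma_g = 0
  expect_equal(f[["CR"]], 0)

  # uniform distribution over 16 cells
  fu <- texture_features(matrix(1 / 16, 4, 4))
  expect_equal(fu[["ET"]], 4)
  expect_equal(fu[["EN"]], 1 / 16)
  expect_equal(fu[["MP"]], 1 / 16)

  set.seed(6)
  for (rep in 1:5) {
    p <- random_prob_matrix(8)
    expect_equal(texture_features(p), oracle_texture_features(p),
                 tolerance = 1e-10)
  }
})

test_that("feature bounds and the contrast-diagonal equivalence hold", {
  set.seed(7)
  for (rep in 1:10) {
    L <- sample(c(4, 8, 16), 1)
    p <- random_prob_matrix(L)
    f <- texture_features(p)
    expect_true(f[["EN"]] > 0 && f[["EN"]] <= 1)
    expect_true(f[["H"]] > 0 && f[["H"]] <= 1)
    expect_true(f[["MP"]] > 0 && f[["MP"]] <= 1)
    expect_true(f[["ET"]] >= 0 && f[["ET"]] <= 2 * log2(L))
    expect_true(f[["CT"]] >= 0 && f[["CT"]] <= (L - 1)^2)
    expect_true(f[["D"]] >= 0)
    # CT = 0 iff all probability mass on the main diagonal
    expect_identical(f[["CT"]] == 0, sum(diag(p)) == 1)
  }
  # force the diagonal case
  pd <- diag(runif(6))
  pd <- pd / sum(pd)
  expect_equal(texture_features(pd)[["CT"]], 0)
})

test_that("orientation-averaged features are constant-safe and rotation invariant", {
  f <- extract_fglcm(matrix(2, 16, 16), levels = 8)
  expect_equal(f[["CT"]], 0)
  expect_equal(f[["D"]], 0)
  expect_equal(f[["H"]], 1)
  expect_equal(f[["EN"]], 1)
  expect_equal(f[["MP"]], 1)
  expect_equal(f[["ET"]], 0)

  # checkerboard has strictly higher contrast than a constant image
  checker <- outer(1:8, 1:8, function(i, j) (i + j) %% 2) * 255
  expect_gt(extract_fglcm(checker, levels = 2)[["CT"]], 0)

  # the four-offset sweep makes the averaged vector invariant to 90-degree
  # rotation of the image
  set.seed(8)
  img <- matrix(runif(256), 16, 16)
  rot90 <- t(img)[16:1, ]
  expect_equal(extract_fglcm(img, levels = 8), extract_fglcm(rot90, levels = 8),
               tolerance = 1e-10)
})
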