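#' Quantize a grayscale image to L gray levels
#'
#' Linear min--max binning into `levels` equal-width bins; the maximum value
#' maps to level `levels - 1`. A constant image maps entirely to level 0
#' (documented behaviour, not an error).
#'
#' @param image Numeric matrix.
#' @param levels Number of gray levels L, >= 2.
#' @return An object of class `quantized_image`: a list with `data` (integer
#'   matrix in `[0, L-1]`), `levels`, and the quantization record
#'   `(min, max, levels)`.
#' @export
quantize_image <- function(image, levels = 32) {
  check_image(image)
  if (levels < 2) {
    stop("validation error: 'levels' must be >= 2", call. = FALSE)
  }
  lo <- min(image)
  hi <- max(image)
  if (hi > lo) {
    q <- floor((image - lo) / (hi - lo) * levels)
    q[q == levels] <- levels - 1
  } else {
    q <- matrix(0, nrow(image), ncol(image))
  }
  structure(
    list(data = matrix(as.integer(q), nrow(image), ncol(image)),
         levels = as.integer(levels),
         quantization = c(min = lo, max = hi, levels = levels)),
    class = "quantized_image"
  )
}

#' Co-occurrence offset for one orientation of the 180-degree sweep
#'
#' The four offsets at distance `delta` covering 180 degrees in (row, col)
#' displacement form: 0 degrees `(0, delta)` (horizontal pairs), 45 degrees
#' `(-delta, delta)` (right diagonal), 90 degrees `(-delta, 0)` (vertical),
#' 135 degrees `(-delta, -delta)` (left diagonal).
#'
#' @param orientation One of 0, 45, 90, 135 (degrees).
#' @param delta Pair distance in pixels, >= 1.
#' @return An object of class `offset_spec` with fields `orientation`,
#'   `delta` and the signed displacement `displacement = (d_row, d_col)`.
#' @export
glcm_offset <- function(orientation = c(0, 45, 90, 135), delta = 1) {
  orientation <- match.arg(as.character(orientation[1]),
                           c("0", "45", "90", "135"))
  if (delta < 1) stop("validation error: 'delta' must be >= 1", call. = FALSE)
  delta <- as.integer(delta)
  disp <- switch(orientation,
    "0"   = c(0L, delta),
    "45"  = c(-delta, delta),
    "90"  = c(-delta, 0L),
    "135" = c(-delta, -delta)
  )
  structure(list(orientation = as.numeric(orientation), delta = delta,
                 displacement = disp),
            class = "offset_spec")
}

#' Gray-level co-occurrence matrix at one offset
#'
#' Counts, over every pixel position `(e, g)` for which the displaced
#' position `(e + d_row, g + d_col)` falls inside the image, the pairs of
#' quantized values `(q, z) = (Q(e,g), Q(e+d_row, g+d_col))`. Accumulation
#' is asymmetric (no transpose-symmetrization); rotational coverage is
#' achieved by the four-offset sweep in [extract_fglcm()]. Set
#' `symmetric = TRUE` to add the transpose.
#'
#' @param q_image A [quantize_image()] result.
#' @param offset An [glcm_offset()].
#' @param normalize Divide counts by the total pair count (default `TRUE`).
#' @param symmetric Add the transposed counts before normalizing.
#' @return An object of class `glcm`: list with `counts` (L x L), and when
#'   normalized `probabilities` (L x L summing to 1), plus `offset`,
#'   `levels`, `normalized`.
#' @export
compute_glcm <- function(q_image, offset = glcm_offset(0), normalize = TRUE,
                         symmetric = FALSE) {
  if (!inherits(q_image, "quantized_image")) {
    stop("validation error: 'q_image' must be a quantized_image",
         call. = FALSE)
  }
  if (!inherits(offset, "offset_spec")) {
    stop("validation error: 'offset' must be an offset_spec", call. = FALSE)
  }
  qm <- q_image$data
  L <- q_image$levels
  de <- offset$displacement[1]
  dg <- offset$displacement[2]
  nr <- nrow(qm)
  nc <- ncol(qm)
  if (abs(de) >= nr || abs(dg) >= nc) {
    stop("validation error: offset displacement exceeds image extent",
         call. = FALSE)
  }
  src_r <- max(1L, 1L - de):min(nr, nr - de)
  src_c <- max(1L, 1L - dg):min(nc, nc - dg)
  q <- qm[src_r, src_c, drop = FALSE]
  z <- qm[src_r + de, src_c + dg, drop = FALSE]
  counts <- matrix(
    tabulate(as.vector(q) * L + as.vector(z) + 1L, nbins = L * L),
    L, L, byrow = TRUE
  )
  if (symmetric) counts <- counts + t(counts)
  out <- list(counts = counts, offset = offset, levels = L,
              normalized = isTRUE(normalize))
  if (normalize) out$probabilities <- counts / sum(counts)
  structure(out, class = "glcm")
}

#' Marginal index statistics of a normalized GLCM
#'
#' Means and standard deviations of the row (`mu_e`, `sigma_e`) and column
#' (`mu_g`, `sigma_g`) marginal distributions of the 0-based gray-level
#' index, used by the correlation and cluster features.
#'
#' @param glcm A normalized [compute_glcm()] result.
#' @return List with `mu_e`, `mu_g`, `sigma_e`, `sigma_g`.
#' @export
glcm_marginals <- function(glcm) {
  p <- glcm_probs(glcm)
  L <- nrow(p)
  idx <- 0:(L - 1)
  pe <- rowSums(p)
  pg <- colSums(p)
  mu_e <- sum(idx * pe)
  mu_g <- sum(idx * pg)
  list(mu_e = mu_e, mu_g = mu_g,
       sigma_e = sqrt(sum((idx - mu_e)^2 * pe)),
       sigma_g = sqrt(sum((idx - mu_g)^2 * pg)))
}

glcm_probs <- function(glcm) {
  if (inherits(glcm, "glcm")) {
    if (!isTRUE(glcm$normalized)) {
      stop("validation error: GLCM must be normalized", call. = FALSE)
    }
    return(glcm$probabilities)
  }
  if (is.matrix(glcm) && is.numeric(glcm)) {
    if (abs(sum(glcm) - 1) > 1e-8) {
      stop("validation error: probability matrix must sum to 1",
           call. = FALSE)
    }
    return(glcm)
  }
  stop("validation error: expected a normalized glcm or probability matrix",
       call. = FALSE)
}

#' The ten GLCM texture features
#'
#' Second-order texture statistics of a normalized co-occurrence matrix
#' `P(q, z)` over 0-based gray levels `q, z`:
#' autocorrelation `AC = sum q z P`;
#' contrast `CT = sum (q-z)^2 P`;
#' correlation `CR = sum (q-mu_e)(z-mu_g) P / (sigma_e sigma_g)`;
#' cluster prominence `CP = sum (q+z-mu_e-mu_g)^4 P`;
#' cluster shade `CS = sum (q+z-mu_e-mu_g)^3 P`;
#' dissimilarity `D = sum |q-z| P`;
#' energy `EN = sum P^2`;
#' entropy `ET = -sum P log2 P` (bits, with `0 log 0 = 0`);
#' homogeneity `H = sum P / (1 + (q-z)^2)`;
#' maximum probability `MP = max P`.
#' When `sigma_e sigma_g = 0` (all mass in one row/column) `CR` is reported
#' as 0 and the result carries attribute `degenerate_marginal = TRUE`.
#'
#' @param glcm A normalized [compute_glcm()] result or an L x L probability
#'   matrix summing to 1.
#' @return Named numeric vector
#'   `c(AC, CT, CR, CP, CS, D, EN, ET, H, MP)`.
#' @export
texture_features <- function(glcm) {
  p <- glcm_probs(glcm)
  L <- nrow(p)
  q <- matrix(rep(0:(L - 1), L), L, L)       # row index
  z <- t(q)                                   # col index
  m <- glcm_marginals(p)
  diffs <- q - z
  clus <- q + z - m$mu_e - m$mu_g
  degenerate <- m$sigma_e * m$sigma_g == 0
  cr <- if (degenerate) 0 else {
    sum((q - m$mu_e) * (z - m$mu_g) * p) / (m$sigma_e * m$sigma_g)
  }
  nz <- p > 0
  out <- c(
    AC = sum(q * z * p),
    CT = sum(diffs^2 * p),
    CR = cr,
    CP = sum(clus^4 * p),
    CS = sum(clus^3 * p),
    D  = sum(abs(diffs) * p),
    EN = sum(p^2),
    ET = -sum(p[nz] * log2(p[nz])),
    H  = sum(p / (1 + diffs^2)),
    MP = max(p)
  )
  if (degenerate) attr(out, "degenerate_marginal") <- TRUE
  out
}

#' GLCM texture features with the four-orientation offset sweep
#'
#' Quantizes the image, computes the co-occurrence matrix at the four
#' offsets (0, 45, 90, 135 degrees) at distance `delta`, extracts the ten
#' texture features at each orientation and returns their arithmetic mean,
#' giving an extent of rotational invariance (the averaged vector is exactly
#' invariant to 90-degree image rotations).
#'
#' @param image Numeric matrix.
#' @param levels Number of quantization levels (default 32).
#' @param delta Offset distance in pixels (default 1).
#' @param symmetric Use transpose-symmetrized matrices (default `FALSE`).
#' @return Named numeric vector of the ten averaged features.
#' @export
extract_fglcm <- function(image, levels = 32, delta = 1, symmetric = FALSE) {
  qi <- quantize_image(image, levels)
  feats <- vapply(
    c(0, 45, 90, 135),
    function(o) {
      g <- compute_glcm(qi, glcm_offset(o, delta), normalize = TRUE,
                        symmetric = symmetric)
      texture_features(g)
    },
    numeric(10)
  )
  rowMeans(feats)
}
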