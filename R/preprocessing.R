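#' 2-D Gaussian smoothing kernel
#'
#' Evaluates `A * exp(-((f - f0)^2 / (2 sigma_f^2) + (g - g0)^2 /
#' (2 sigma_g^2)))` on a `size x size` grid of (row, col) offsets. By default
#' the center `(f0, g0)` is the kernel midpoint and `amplitude = NULL`
#' requests the normalizing constant making the entries sum to 1.
#'
#' @param size Odd kernel side length, >= 3.
#' @param sigma_f,sigma_g Standard deviations (pixels) along rows / columns.
#' @param amplitude Scalar `A`, or `NULL` to normalize to unit sum.
#' @param center Optional `(f0, g0)` in 0-based kernel coordinates; defaults
#'   to the midpoint `((size-1)/2, (size-1)/2)`.
#' @return A `size x size` numeric kernel.
#' @export
gaussian_kernel <- function(size = 3, sigma_f = 0.5, sigma_g = sigma_f,
                            amplitude = NULL, center = NULL) {
  if (size < 3 || !is_odd(size)) {
    stop("validation error: kernel 'size' must be odd and >= 3", call. = FALSE)
  }
  if (sigma_f <= 0 || sigma_g <= 0) {
    stop("validation error: sigma_f and sigma_g must be > 0", call. = FALSE)
  }
  if (is.null(center)) center <- c((size - 1) / 2, (size - 1) / 2)
  f <- matrix(rep(0:(size - 1), size), size, size)
  g <- t(f)
  k <- exp(-((f - center[1])^2 / (2 * sigma_f^2) +
               (g - center[2])^2 / (2 * sigma_g^2)))
  if (is.null(amplitude)) k / sum(k) else amplitude * k
}

# Symmetric (half-sample) reflection padding by (pr, pc) on each side.
reflect_pad <- function(image, pr, pc) {
  n <- nrow(image)
  m <- ncol(image)
  ri <- c(if (pr > 0) pr:1, 1:n, if (pr > 0) n:(n - pr + 1))
  ci <- c(if (pc > 0) pc:1, 1:m, if (pc > 0) m:(m - pc + 1))
  image[ri, ci, drop = FALSE]
}

#' Same-size 2-D convolution with reflected boundaries
#'
#' True convolution (the kernel is flipped in both dimensions) of an image
#' with an odd-sized kernel, boundary handled by symmetric reflection, output
#' the same size as the input. Linear in the image:
#' `conv(aX + bY, K) = a conv(X, K) + b conv(Y, K)`.
#'
#' @param image Numeric matrix.
#' @param kernel Numeric matrix with odd dimensions, no larger than the
#'   image in either dimension.
#' @return Numeric matrix of the same size as `image`.
#' @export
convolve2d <- function(image, kernel) {
  check_image(image)
  if (!is.matrix(kernel) || !is.numeric(kernel)) {
    stop("validation error: 'kernel' must be a numeric matrix", call. = FALSE)
  }
  kr <- nrow(kernel)
  kc <- ncol(kernel)
  if (!is_odd(kr) || !is_odd(kc)) {
    stop("validation error: kernel dimensions must be odd", call. = FALSE)
  }
  if (kr > nrow(image) || kc > ncol(image)) {
    stop("validation error: kernel larger than image", call. = FALSE)
  }
  pr <- (kr - 1L) %/% 2L
  pc <- (kc - 1L) %/% 2L
  pad <- reflect_pad(image, pr, pc)
  n <- nrow(image)
  m <- ncol(image)
  out <- matrix(0, n, m)
  # convolution: out[i,j] = sum_{u,v} kernel[u,v] * image[i - (u-c), j - (v-c)]
  for (u in seq_len(kr)) {
    du <- pr - (u - 1L)           # row shift contributed by kernel row u
    for (v in seq_len(kc)) {
      w <- kernel[u, v]
      if (w == 0) next
      dv <- pc - (v - 1L)
      out <- out + w * pad[(pr + 1L + du):(pr + n + du),
                           (pc + 1L + dv):(pc + m + dv), drop = FALSE]
    }
  }
  out
}

#' Local-statistics Wiener denoiser
#'
#' Adaptive minimum-mean-square-error filter: in a `window x window`
#' neighborhood of every pixel the local mean `mu` and variance `s2` are
#' estimated, and the output is
#' `mu + max(s2 - nv, 0) / max(s2, eps) * (x - mu)` where `nv` is the noise
#' variance. When `noise_variance` is `NULL` it is estimated as the mean of
#' the local variances, the standard data-driven choice for this filter.
#'
#' @param image Numeric matrix.
#' @param window Odd window side length, >= 3.
#' @param noise_variance Optional known noise variance (gray levels squared).
#' @return Denoised matrix of the same size.
#' @export
wiener_filter <- function(image, window = 3, noise_variance = NULL) {
  check_image(image)
  if (window < 3 || !is_odd(window)) {
    stop("validation error: 'window' must be odd and >= 3", call. = FALSE)
  }
  box <- matrix(1 / window^2, window, window)
  mu <- convolve2d(image, box)
  s2 <- pmax(convolve2d(image^2, box) - mu^2, 0)
  nv <- if (is.null(noise_variance)) mean(s2) else noise_variance
  gain <- pmax(s2 - nv, 0) / pmax(s2, .Machine$double.eps)
  mu + gain * (image - mu)
}

#' Complex Gabor kernel
#'
#' A Gaussian envelope `exp(-0.5 (z1^2/sigma1^2 + z2^2/sigma2^2))` modulated
#' by the complex carrier `exp(i (2 pi F z1 + phase))`, where `(z1, z2)` are
#' the (row, col) offsets rotated into the (theta, theta + pi/2) frame:
#' `z1 = f cos(theta) + g sin(theta)`, `z2 = -f sin(theta) + g cos(theta)`.
#' The kernel is an orientation- and frequency-selective band-pass filter;
#' its magnitude is identical at `theta` and `theta + pi`.
#'
#' @param frequency Carrier frequency F in cycles/pixel, `0 <= F <= 0.5`
#'   (Nyquist).
#' @param theta Orientation in radians.
#' @param sigma1,sigma2 Envelope standard deviations (pixels) along and
#'   across the carrier direction.
#' @param size Odd kernel side length.
#' @param amplitude Scalar gain `A`.
#' @param phase Carrier phase offset in radians.
#' @return A `size x size` complex matrix.
#' @export
gabor_kernel <- function(frequency, theta = 0, sigma1 = 2, sigma2 = sigma1,
                         size = 9, amplitude = 1, phase = 0) {
  if (frequency < 0 || frequency > 0.5) {
    stop("validation error: 'frequency' must lie in [0, 0.5] (Nyquist)",
         call. = FALSE)
  }
  if (sigma1 <= 0 || sigma2 <= 0) {
    stop("validation error: sigma1 and sigma2 must be > 0", call. = FALSE)
  }
  if (!is_odd(size)) {
    stop("validation error: 'size' must be odd", call. = FALSE)
  }
  half <- (size - 1L) / 2
  f <- matrix(rep(-half:half, size), size, size)
  g <- t(f)
  z1 <- f * cos(theta) + g * sin(theta)
  z2 <- -f * sin(theta) + g * cos(theta)
  env <- exp(-0.5 * (z1^2 / sigma1^2 + z2^2 / sigma2^2))
  amplitude * env * exp(1i * (2 * pi * frequency * z1 + phase))
}

#' Gabor filter bank
#'
#' The cross-product of carrier frequencies and orientations, with a
#' per-pixel rule for combining response magnitudes across kernels.
#'
#' @param frequencies Carrier frequencies in cycles/pixel.
#' @param orientations Orientations in radians, within `[0, pi)`.
#' @param sigma Envelope standard deviation (pixels), shared by both axes.
#' @param size Odd kernel side length.
#' @param combine `"max"` (default) or `"mean"` magnitude across kernels.
#' @return An object of class `gabor_bank`.
#' @export
gabor_bank <- function(frequencies = c(0.1, 0.2, 0.3, 0.4),
                       orientations = c(0, pi / 4, pi / 2, 3 * pi / 4),
                       sigma = 2, size = 9,
                       combine = c("max", "mean")) {
  combine <- match.arg(combine)
  if (length(frequencies) < 1 || length(orientations) < 1) {
    stop("validation error: bank needs >= 1 frequency and orientation",
         call. = FALSE)
  }
  if (any(orientations < 0 | orientations >= pi)) {
    stop("validation error: orientations must lie in [0, pi)", call. = FALSE)
  }
  specs <- list()
  for (f in frequencies) {
    for (th in orientations) {
      specs[[length(specs) + 1L]] <-
        list(frequency = f, theta = th, sigma1 = sigma, sigma2 = sigma,
             size = size)
    }
  }
  structure(list(specs = specs, combine = combine), class = "gabor_bank")
}

# Magnitude of the complex Gabor response (two real convolutions).
gabor_response <- function(image, spec) {
  k <- gabor_kernel(spec$frequency, spec$theta, spec$sigma1, spec$sigma2,
                    spec$size)
  re <- convolve2d(image, Re(k))
  im <- convolve2d(image, Im(k))
  sqrt(re^2 + im^2)
}

#' Hybrid Wiener--Gabor preprocessing
#'
#' The package's preprocessing stage: Wiener denoising to suppress
#' acquisition noise, followed by a Gabor filter bank to enhance texture.
#' The per-pixel combination (max or mean magnitude over the bank) is
#' min-max rescaled to `[0, 1]`; an image with no dynamic range maps to all
#' zeros. Deterministic.
#'
#' @param image Numeric matrix.
#' @param wiener_window Odd Wiener window size (default 3).
#' @param bank A [gabor_bank()].
#' @return Enhanced image with values in `[0, 1]`.
#' @export
hwgf_preprocess <- function(image, wiener_window = 3, bank = gabor_bank()) {
  if (!inherits(bank, "gabor_bank")) {
    stop("validation error: 'bank' must be a gabor_bank", call. = FALSE)
  }
  den <- wiener_filter(image, window = wiener_window)
  acc <- NULL
  for (spec in bank$specs) {
    r <- gabor_response(den, spec)
    acc <- if (is.null(acc)) {
      r
    } else if (bank$combine == "max") {
      pmax(acc, r)
    } else {
      acc + r
    }
  }
  if (bank$combine == "mean") acc <- acc / length(bank$specs)
  rng <- range(acc)
  if (rng[2] - rng[1] <= .Machine$double.eps * max(1, abs(rng[2]))) {
    return(matrix(0, nrow(acc), ncol(acc)))
  }
  (acc - rng[1]) / (rng[2] - rng[1])
}
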