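#' Texture specification for one nodule class
#'
#' Describes the second-order statistics of a synthetic ultrasound texture
#' class: a latent Gaussian random field smoothed at `correlation_length`
#' (standardised to unit variance), scaled by `contrast_amplitude` gray
#' levels, and offset by `base_intensity`. When `orientation_deg` is set the
#' smoothing kernel is elongated along that direction, producing anisotropic
#' (striated) texture.
#'
#' @param base_intensity Mean echo intensity in gray levels.
#' @param correlation_length Gaussian smoothing scale of the latent field,
#'   in pixels. Must be positive.
#' @param contrast_amplitude Standard deviation of the texture component in
#'   gray-level units. Must be non-negative.
#' @param orientation_deg Optional anisotropy direction in degrees; `NULL`
#'   (default) gives isotropic texture.
#' @return An object of class `texture_spec`.
#' @export
texture_spec <- function(base_intensity = 120, correlation_length = 3,
                         contrast_amplitude = 20, orientation_deg = NULL) {
  if (!is.numeric(correlation_length) || correlation_length <= 0) {
    stop_config("correlation_length", "must be > 0")
  }
  if (!is.numeric(contrast_amplitude) || contrast_amplitude < 0) {
    stop_config("contrast_amplitude", "must be >= 0")
  }
  structure(
    list(
      base_intensity = base_intensity,
      correlation_length = correlation_length,
      contrast_amplitude = contrast_amplitude,
      orientation_deg = orientation_deg
    ),
    class = "texture_spec"
  )
}

#' Configuration for the synthetic two-class ultrasound texture generator
#'
#' The defaults emulate the clinical setting the package targets: 450
#' thyroid-nodule images with a 322 malignant / 128 benign imbalance, with
#' the malignant class showing shorter-range, higher-contrast texture than
#' the benign class, multiplicative Gamma speckle and additive Gaussian
#' acquisition noise.
#'
#' @param image_size Integer vector `(rows, cols)`; each must be >= 16.
#' @param n_benign,n_malignant Class counts; non-negative, at least one
#'   image in total.
#' @param benign_texture,malignant_texture [texture_spec()] objects.
#' @param speckle_shape Gamma shape of the unit-mean multiplicative speckle
#'   (scale = 1/shape). Larger values mean weaker speckle. Must be > 0.
#' @param gaussian_noise_sd Additive acquisition-noise standard deviation in
#'   gray levels; >= 0.
#' @param speckle Logical; `FALSE` disables speckle entirely (the
#'   `speckle_shape -> Inf` limit).
#' @param seed Integer seed; together with the config it fully determines
#'   the generated pixels.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(image_size = c(64, 64),
                             n_benign = 128, n_malignant = 322,
                             benign_texture = texture_spec(
                               base_intensity = 120, correlation_length = 5,
                               contrast_amplitude = 18
                             ),
                             malignant_texture = texture_spec(
                               base_intensity = 110, correlation_length = 2.5,
                               contrast_amplitude = 36
                             ),
                             speckle_shape = 3, gaussian_noise_sd = 8,
                             speckle = TRUE, seed = 0L) {
  if (length(image_size) != 2 || any(image_size < 16)) {
    stop_config("image_size", "must be (rows, cols) with both >= 16")
  }
  if (n_benign < 0) stop_config("n_benign", "must be >= 0")
  if (n_malignant < 0) stop_config("n_malignant", "must be >= 0")
  if (n_benign + n_malignant < 1) {
    stop_config("n_benign + n_malignant", "must be >= 1")
  }
  if (!inherits(benign_texture, "texture_spec")) {
    stop_config("benign_texture", "must be a texture_spec")
  }
  if (!inherits(malignant_texture, "texture_spec")) {
    stop_config("malignant_texture", "must be a texture_spec")
  }
  if (!is.numeric(speckle_shape) || speckle_shape <= 0) {
    stop_config("speckle_shape", "must be > 0")
  }
  if (!is.numeric(gaussian_noise_sd) || gaussian_noise_sd < 0) {
    stop_config("gaussian_noise_sd", "must be >= 0")
  }
  structure(
    list(
      image_size = as.integer(image_size),
      n_benign = as.integer(n_benign), n_malignant = as.integer(n_malignant),
      benign_texture = benign_texture, malignant_texture = malignant_texture,
      speckle_shape = speckle_shape, gaussian_noise_sd = gaussian_noise_sd,
      speckle = isTRUE(speckle), seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# Smooth a field with a Gaussian of scale `sigma`; separable when isotropic,
# full 2-D rotated anisotropic kernel otherwise.
gaussian_blur <- function(field, sigma, orientation_deg = NULL) {
  half <- max(1L, ceiling(3 * sigma))
  # kernel must fit inside the image for convolve2d
  half <- min(half, (nrow(field) - 1L) %/% 2L, (ncol(field) - 1L) %/% 2L)
  size <- 2L * half + 1L
  if (is.null(orientation_deg)) {
    k1 <- exp(-((-half:half)^2) / (2 * sigma^2))
    k1 <- k1 / sum(k1)
    out <- convolve2d(field, matrix(k1, nrow = size, ncol = 1))
    return(convolve2d(out, matrix(k1, nrow = 1, ncol = size)))
  }
  th <- orientation_deg * pi / 180
  s_major <- sigma
  s_minor <- max(sigma / 4, 0.5)
  f <- matrix(rep(-half:half, size), size, size)       # row offsets
  g <- t(f)                                            # col offsets
  u <- f * cos(th) + g * sin(th)
  v <- -f * sin(th) + g * cos(th)
  k <- exp(-0.5 * (u^2 / s_major^2 + v^2 / s_minor^2))
  convolve2d(field, k / sum(k))
}

# One synthetic image: echo intensity (base + contrast * unit-variance
# smoothed Gaussian field) times unit-mean Gamma speckle, plus additive
# Gaussian noise, clipped to non-negative gray levels.
simulate_image <- function(spec, rows, cols, speckle_shape, noise_sd, speckle) {
  latent <- matrix(stats::rnorm(rows * cols), rows, cols)
  smooth <- gaussian_blur(latent, spec$correlation_length, spec$orientation_deg)
  s <- stats::sd(smooth)
  if (s > 0) smooth <- smooth / s
  intensity <- spec$base_intensity + spec$contrast_amplitude * smooth
  if (speckle) {
    intensity <- intensity *
      matrix(stats::rgamma(rows * cols, shape = speckle_shape,
                           scale = 1 / speckle_shape), rows, cols)
  }
  if (noise_sd > 0) {
    intensity <- intensity + matrix(stats::rnorm(rows * cols, sd = noise_sd),
                                    rows, cols)
  }
  pmax(intensity, 0)
}

#' Generate a labeled synthetic ultrasound texture dataset
#'
#' Draws `n_benign` images (label 0) followed by `n_malignant` images
#' (label 1) from the two texture classes in `config`. The generator is a
#' pure function of the config (including its seed): identical inputs give
#' bit-identical pixels.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `labeled_image_set`: a list with `images`
#'   (list of numeric matrices), `labels` (integer vector of 0/1) and
#'   `meta` (provenance record holding the config).
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop_config("config", "must be a synthetic_config")
  }
  rows <- config$image_size[1]
  cols <- config$image_size[2]
  with_seed(config$seed, {
    images <- vector("list", config$n_benign + config$n_malignant)
    labels <- integer(length(images))
    for (i in seq_len(config$n_benign)) {
      images[[i]] <- simulate_image(config$benign_texture, rows, cols,
                                    config$speckle_shape,
                                    config$gaussian_noise_sd, config$speckle)
      labels[i] <- 0L
    }
    for (j in seq_len(config$n_malignant)) {
      i <- config$n_benign + j
      images[[i]] <- simulate_image(config$malignant_texture, rows, cols,
                                    config$speckle_shape,
                                    config$gaussian_noise_sd, config$speckle)
      labels[i] <- 1L
    }
    labeled_image_set(images, labels, meta = list(config = config))
  })
}

#' Construct a labeled image set
#'
#' @param images List of numeric matrices (finite, non-negative gray levels).
#' @param labels Vector of class labels, 0 = benign, 1 = malignant.
#' @param meta Optional free-form provenance record.
#' @return An object of class `labeled_image_set`.
#' @export
labeled_image_set <- function(images, labels, meta = list()) {
  if (length(images) != length(labels)) {
    stop("length(images) must equal length(labels)", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (length(labels) && !all(labels %in% c(0L, 1L))) {
    stop("every label must be 0 (benign) or 1 (malignant)", call. = FALSE)
  }
  for (im in images) check_image(im)
  structure(list(images = images, labels = labels, meta = meta),
            class = "labeled_image_set")
}

#' @export
print.labeled_image_set <- function(x, ...) {
  cat(sprintf("labeled_image_set: %d images (%d benign, %d malignant)\n",
              length(x$images), sum(x$labels == 0L), sum(x$labels == 1L)))
  if (length(x$images)) {
    d <- dim(x$images[[1]])
    cat(sprintf("  image size: %d x %d\n", d[1], d[2]))
  }
  invisible(x)
}

# 16-bit gray quantization applied at save time.
quantize_gray16 <- function(image) round(pmin(pmax(image, 0), 65535))

#' Save a labeled image set to disk
#'
#' Writes one 16-bit grayscale TIFF per image plus a CSV manifest
#' (`filename,label`) and, when the set carries a generator config, a JSON
#' dump of it for provenance. Pixels are clipped to `[0, 65535]` and rounded
#' to integers at save time (16-bit quantization); loading returns exactly
#' those quantized values.
#'
#' @param set A [labeled_image_set()].
#' @param directory Output directory; created if absent.
#' @return Invisibly, the manifest path.
#' @export
save_dataset <- function(set, directory) {
  if (!inherits(set, "labeled_image_set")) {
    stop("'set' must be a labeled_image_set", call. = FALSE)
  }
  if (!is.character(directory) || length(directory) != 1 || !nzchar(directory)) {
    stop("I/O error: 'directory' must be a non-empty path", call. = FALSE)
  }
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("I/O error: cannot create directory '%s'", directory),
                  call. = FALSE)
  }
  n <- length(set$images)
  filenames <- sprintf("img_%04d.tif", seq_len(n) - 1L)
  for (i in seq_len(n)) {
    q <- quantize_gray16(set$images[[i]])
    tiff::writeTIFF(q / 65535, file.path(directory, filenames[i]),
                    bits.per.sample = 16, compression = "none")
  }
  manifest <- file.path(directory, "manifest.csv")
  utils::write.csv(data.frame(filename = filenames, label = set$labels),
                   manifest, row.names = FALSE, quote = FALSE)
  if (!is.null(set$meta$config)) {
    jsonlite::write_json(unclass_recursive(set$meta$config),
                         file.path(directory, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(manifest)
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else x
}

#' Load a labeled image set from a manifest
#'
#' Reads the CSV manifest written by [save_dataset()] (columns
#' `filename,label`) and the image files it references (16-bit TIFF or PNG),
#' returning pixel values on the integer 0--65535 gray scale in manifest row
#' order.
#'
#' @param manifest Path to the manifest CSV.
#' @return A [labeled_image_set()].
#' @export
load_dataset <- function(manifest) {
  if (!file.exists(manifest)) {
    stop(sprintf("I/O error: manifest '%s' does not exist", manifest),
         call. = FALSE)
  }
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("filename", "label") %in% names(tab))) {
    stop("manifest must have columns 'filename' and 'label'", call. = FALSE)
  }
  labels <- suppressWarnings(as.integer(tab$label))
  if (any(is.na(labels)) || !all(labels %in% c(0L, 1L))) {
    stop("validation error: every manifest label must be 0 or 1",
         call. = FALSE)
  }
  base <- dirname(manifest)
  images <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    path <- file.path(base, tab$filename[i])
    if (!file.exists(path)) {
      stop(sprintf("I/O error: image file '%s' does not exist", path),
           call. = FALSE)
    }
    raw <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
      png::readPNG(path)
    } else {
      tiff::readTIFF(path)
    }
    if (length(dim(raw)) == 3) raw <- raw[, , 1]
    images[[i]] <- round(raw * 65535)
  }
  labeled_image_set(images, labels, meta = list(manifest = manifest))
}
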