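# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop(sprintf("'%s' must be a numeric matrix", arg), call. = FALSE)
  }
  if (any(!is.finite(image))) {
    stop(sprintf("'%s' contains non-finite values", arg), call. = FALSE)
  }
  invisible(image)
}

is_odd <- function(x) x %% 2 == 1

# Deterministic numeric formatting for text artifacts (byte-reproducibility).
fmt_num <- function(x) sprintf("%.12g", x)
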