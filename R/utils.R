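# Internal helpers: argument checks and seed derivation.

.check_prob <- function(p, what = "p") {
  if (!is.numeric(p) || length(p) == 0) {
    stop(sprintf("'%s' must be a non-empty numeric vector", what), call. = FALSE)
  }
  if (anyNA(p)) stop(sprintf("'%s' contains NA", what), call. = FALSE)
  if (any(p <= 0) || any(p > 1)) {
    stop(sprintf("'%s' must lie in (0, 1]; got values outside", what),
         call. = FALSE)
  }
  invisible(p)
}

.check_count <- function(x, what, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", what, min),
         call. = FALSE)
  }
  as.integer(x)
}

#' Derive a named sub-seed from a master seed
#'
#' Deterministically maps a master seed and a string key to a sub-seed, so
#' each generator draws from its own stream and adding one generator does
#' not perturb the others. The result stays below 2^31 - 1.
#'
#' @param seed Non-negative integer master seed.
#' @param key Character label of the stream.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, key) {
  seed <- .check_count(seed, "seed", min = 0L)
  h <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(key)) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

# Run code with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
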