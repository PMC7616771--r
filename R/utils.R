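# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the previous
#' RNG state, so generators are pure functions of their spec and seed and never
#' perturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_rng_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-generator seed from the user seed and a stream name, so the
# simulators draw from distinct but reproducible streams. Kept below 2^31.
stream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                    integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single non-missing number", name),
         call. = FALSE)
  }
  if (x < min || x > max) {
    stop(sprintf("'%s' must be in [%s, %s], got %s", name,
                 format(min), format(max), format(x)), call. = FALSE)
  }
  if (integer && x != round(x)) {
    stop(sprintf("'%s' must be an integer, got %s", name, format(x)),
         call. = FALSE)
  }
  invisible(x)
}

# unit-normalize a 3-vector
unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}
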