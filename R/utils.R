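#' Derive a reproducible sub-seed from a global seed and a stream label
#'
#' A single integer seed drives several independent random streams
#' (annotation, latent factors, noise, permutations, ...). Each stream gets a
#' deterministic sub-seed so that, e.g., the annotation is reproducible
#' without replaying the factor draws.
#'
#' @param seed Integer master seed.
#' @param label Character stream label.
#' @return A positive integer seed below 2^31.
#' @export
sub_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(label))
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes)) %% 99991L
  as.integer((abs(as.integer(seed)) %% 1000003L) * 1009L + h + 1L)
}

#' Evaluate code with a temporary RNG state
#'
#' Sets the seed for the duration of `code` and restores the caller's
#' `.Random.seed` afterwards, so seeded operations do not disturb the global
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

# Internal: stop with a prefixed message
.ec_stop <- function(...) stop(sprintf(...), call. = FALSE)

# Internal: canonical unordered pair key for edge-set arithmetic
.pair_key <- function(i, j) {
  paste(pmin(i, j), pmax(i, j), sep = "\r")
}
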