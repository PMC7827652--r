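# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Pin every RNG kind so that seeded output is identical across platforms and
# R sessions regardless of the caller's RNG settings.
with_seed <- function(seed, code) {
  if (!is.null(old <- get0(".Random.seed", envir = globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

# Deterministic sub-seeds (< 2^31) spawned from one master seed, so each
# animal gets an independent, logged stream.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(min), format(max)),
          class = "checkfish_config_error")
  }
  invisible(x)
}

stopifnot_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min),
          class = "checkfish_config_error")
  }
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
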