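# Internal validation and RNG helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("`%s` must be in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x)), call. = FALSE)
  if (!allow_zero && x == 0)
    stop(sprintf("`%s` must be nonzero", name), call. = FALSE)
  invisible(x)
}

assert_count <- function(x, name, lower = 0) {
  assert_number(x, name, lower = lower)
  if (x != floor(x))
    stop(sprintf("`%s` must be an integer count", name), call. = FALSE)
  invisible(as.integer(x))
}

#' Derive a reproducible child seed from a base seed and string tokens
#'
#' All randomness in the simulator flows from one explicit base seed;
#' per-well (and per-stage) substreams are derived deterministically from
#' `(seed, tokens...)` with a small string-folding hash, so that wells can
#' be simulated in any order with identical results. The returned value is
#' always a valid 32-bit integer seed.
#'
#' @param seed Integer base seed.
#' @param ... Character or numeric tokens (e.g. a well id, a stage name).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "A01", "render")
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime; double arithmetic stays exact
  h <- as.numeric(seed) %% m
  for (tok in list(...)) {
    for (code in utf8ToInt(paste(as.character(tok), collapse = "|"))) {
      h <- (h * 31 + code) %% m
    }
  }
  as.integer(h)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is restored afterwards. If seed is NULL the current
# stream is used (and advanced).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# lognormal multiplier with mean 1 and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}
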