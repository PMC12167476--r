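#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded at `seed`,
#' then restores the caller's RNG state, so seeded package functions never
#' disturb the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# n seeds derived deterministically from one master seed, all < 2^31
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_ <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)
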