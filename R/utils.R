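# Internal helpers shared across modules.

#' @noRd
clamp <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)

# Run `code` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards.  All stochastic operations in the
# package funnel through this so no function touches global RNG state.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' @noRd
is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 1 && x == floor(x)

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @noRd
check_odd_kernel <- function(k, what) {
  if (!is_count(k) || k %% 2L != 1L)
    stopf("%s kernel must be an odd positive integer, got %s", what,
          paste(k, collapse = ","))
  as.integer(k)
}
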