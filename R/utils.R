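#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are reproducible without clobbering the global
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# deterministic per-observation seed derived from a master seed; kept within
# the 32-bit integer range set.seed() accepts
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 10007) %% 2147483629)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Trapezoid-rule integral of y over x
#' @keywords internal
#' @noRd
trapz_integral <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

stop_domain <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
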