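#' @keywords internal
"_PACKAGE"

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators are deterministic without clobbering the
# session stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed), seed >= 0)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation; keeps results < 2^31 so they remain
# valid R integer seeds.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483629)
}

stop_acl <- function(...) stop(..., call. = FALSE)

check_simplex <- function(x, what = "vector", tol = 1e-6) {
  if (any(!is.finite(x)) || any(x < -tol)) {
    stop_acl(sprintf("%s has non-finite or negative entries", what))
  }
  if (abs(sum(x) - 1) > tol) {
    stop_acl(sprintf("%s sums to %.8f, expected 1 (tolerance %g)",
                     what, sum(x), tol))
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
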