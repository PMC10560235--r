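#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run `expr` under a local RNG state seeded with `seed`, restoring the
## caller's RNG afterwards. All stochastic operations in the package go
## through this so results are reproducible given (inputs, seed) and do not
## disturb user RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Deterministically derive a child seed from a parent seed and an index.
## Keeps all derived seeds inside the 32-bit integer range. Used by the
## surrogate / permutation loops so that iteration i is reproducible in
## isolation and results are invariant to execution order.
derive_seed <- function(seed, i) {
  s <- (as.double(seed) * 48271 + as.double(i) * 69621) %% 2147483561
  as.integer(s) + 1L
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

#' Named frequency band sets
#'
#' A band set is a named list of `c(low, high)` frequency intervals in Hz,
#' ordered and non-overlapping. `cgc_bands()` returns the four bands used to
#' aggregate conditional Granger causality spectra (theta 4-8, alpha 9-12,
#' beta 13-30, gamma 31-50 Hz). `ersp_bands()` returns the five bands used
#' for event-related spectral perturbation summaries (theta, alpha, beta,
#' low gamma 31-70, high gamma 70-150 Hz).
#'
#' @param bands named list of numeric length-2 vectors `c(low, high)` in Hz.
#' @return An object of class `band_set`.
#' @examples
#' cgc_bands()
#' band_set(list(slow = c(1, 4), fast = c(30, 80)))
#' @export
band_set <- function(bands) {
  if (is.null(names(bands)) || any(!nzchar(names(bands)))) {
    stopf("bands must be a named list")
  }
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (!is.numeric(b) || length(b) != 2L || b[1] >= b[2]) {
      stopf("band '%s' must be c(low, high) with low < high", nm)
    }
  }
  lows <- vapply(bands, `[`, numeric(1), 1L)
  highs <- vapply(bands, `[`, numeric(1), 2L)
  o <- order(lows)
  bands <- bands[o]
  lows <- lows[o]; highs <- highs[o]
  if (length(bands) > 1L && any(lows[-1L] < highs[-length(highs)])) {
    stopf("bands overlap")
  }
  structure(bands, class = "band_set")
}

#' @rdname band_set
#' @export
cgc_bands <- function() {
  band_set(list(theta = c(4, 8), alpha = c(9, 12),
                beta = c(13, 30), gamma = c(31, 50)))
}

#' @rdname band_set
#' @export
ersp_bands <- function() {
  band_set(list(theta = c(4, 8), alpha = c(9, 12), beta = c(13, 30),
                low_gamma = c(31, 70), high_gamma = c(70, 150)))
}

#' @export
print.band_set <- function(x, ...) {
  cat("Frequency band set:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-10s %g-%g Hz\n", nm, x[[nm]][1], x[[nm]][2]))
  }
  invisible(x)
}
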