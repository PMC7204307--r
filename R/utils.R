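# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library functions do not perturb user-level streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
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
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-unit sub-seed derived from a master seed; kept below
# 2^31 so it is always a valid R integer.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 7919) %% 2147483587)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stopf("`%s` must be TRUE or FALSE", name)
  }
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    stopf("`%s` must be a single integer >= %s", name, min)
  }
  invisible(as.integer(x))
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stopf("`%s` must be a single number in [%s, %s]", name, min, max)
  }
  invisible(as.double(x))
}

# Row medians of a numeric matrix without per-row R calls: sort all values
# by (row, value) in one order() pass, then read the middle order
# statistics. O(n log n) overall; used in the permutation null of the
# integrative DEG test where apply(x, 1, median) dominates runtime.
row_medians <- function(x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  g <- nrow(x)
  if (n == 1L) return(as.vector(x))
  o <- order(row(x), x)
  xs <- matrix(x[o], nrow = g, byrow = TRUE)
  if (n %% 2L == 1L) {
    xs[, (n + 1L) %/% 2L]
  } else {
    (xs[, n %/% 2L] + xs[, n %/% 2L + 1L]) / 2
  }
}
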