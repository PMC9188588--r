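# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded simulations do not
#' perturb the global random stream. A NULL seed evaluates the expression
#' under the current stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a user seed; keeps values well
# inside 32-bit integer range.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 37L + as.integer(k) * 1009L) %% 2147483583L
}

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)

check_map <- function(x, shape, name) {
  if (!is.matrix(x) || !all(dim(x) == shape)) {
    stop_arg("'%s' must be a %d x %d matrix", name, shape[1], shape[2])
  }
  if (!all(is.finite(x))) stop_arg("'%s' contains non-finite values", name)
  invisible(x)
}

# Unbiased streaming mean/variance over columns-of-pixels chunks.
# Accumulators: n, sum, sum of squares (values are O(100) ADU so the naive
# sums are numerically safe for the frame counts used here).
stat_accumulator <- function(npix) {
  list(n = 0, s = numeric(npix), ss = numeric(npix))
}

stat_update <- function(acc, chunk) {
  # chunk: npix x F matrix
  acc$n <- acc$n + ncol(chunk)
  acc$s <- acc$s + rowSums(chunk)
  acc$ss <- acc$ss + rowSums(chunk * chunk)
  acc
}

stat_finalize <- function(acc) {
  n <- acc$n
  if (n < 2) stop_arg("need at least 2 frames for variance")
  m <- acc$s / n
  v <- pmax(0, (acc$ss - n * m * m) / (n - 1))
  list(mean = m, variance = v, n = n)
}
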