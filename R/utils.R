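## Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_field(field, "must be a single probability in [0, 1]")
  x
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x))
    stop_field(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_square <- function(A, name = deparse(substitute(A))) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop(sprintf("'%s' must be a square matrix", name), call. = FALSE)
  invisible(A)
}

## Derive a bounded sub-seed from a base seed and a stream index; keeps
## every seed handed to set.seed() inside the 32-bit integer range.
sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(stream)) %% 2147483647)
}

## Strictly-upper-triangle vectorization (column-major), shared by the
## similarity machinery so both matrices use identical element order.
upper_vec <- function(M) M[upper.tri(M)]

## Pearson correlation by direct formula on two vectors (used in a few
## places where NA-flagged entries must propagate predictably).
safe_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}
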