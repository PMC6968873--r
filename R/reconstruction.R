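#' First-difference a time series
#'
#' Differencing (`x[t+1] - x[t]`) reduces the strong serial autocorrelation
#' of slow calcium-indicator fluorescence and makes the series approximately
#' stationary before Pearson correlation.
#'
#' @param x numeric vector of length `T >= 2`.
#' @return numeric vector of length `T - 1`.
#' @export
difference_series <- function(x) {
  if (length(x) < 2L)
    stop("series too short to difference (need length >= 2)", call. = FALSE)
  diff(x)
}

## Row-wise differencing of a cells x frames matrix.
difference_rows <- function(traces) {
  if (ncol(traces) < 2L)
    stop("traces too short to difference", call. = FALSE)
  traces[, -1L, drop = FALSE] - traces[, -ncol(traces), drop = FALSE]
}

#' Pearson correlation matrix of differenced traces
#'
#' @param traces cells x frames numeric matrix (at least 3 frames).
#' @return Symmetric correlation matrix of the row-wise differenced traces,
#'   unit diagonal. Cells whose differenced trace has zero variance are
#'   flagged with a warning and their entries set to `NA`.
#' @export
correlation_matrix <- function(traces) {
  if (ncol(traces) < 3L)
    stop("need at least 3 frames", call. = FALSE)
  D <- difference_rows(traces)
  flat <- apply(D, 1L, sd) == 0
  R <- suppressWarnings(cor(t(D)))
  if (any(flat)) {
    warning(sum(flat), " cell(s) with zero-variance differenced trace; ",
            "entries set to NA", call. = FALSE)
    R[flat, ] <- NA_real_
    R[, flat] <- NA_real_
  }
  dimnames(R) <- list(rownames(traces), rownames(traces))
  R
}

## Number of admissible jitter start indices: the random start index lies
## within the first 2 seconds of the recording.
jitter_p_max <- function(sampling_rate_hz) as.integer(round(2 * sampling_rate_hz))

#' Jittered surrogate of a fluorescence trace
#'
#' Draws a random start index `p` uniformly from the first two seconds of
#' the recording (`{0, ..., 60}` at 30 Hz) and retains the centered segment
#' `x[(p+1):(T-p)]`, of length `T - 2p`. Applied independently to the two
#' members of a cell pair, this destroys their fine temporal alignment while
#' preserving each trace's marginal statistics, giving a null for the
#' significance of observed correlations. The surrogate is differenced
#' downstream exactly like the original traces.
#'
#' @param x numeric vector.
#' @param sampling_rate_hz sampling rate (default 30).
#' @param p optional fixed start index (mainly for testing); drawn uniformly
#'   when `NULL`.
#' @return numeric vector of length `length(x) - 2 * p`.
#' @export
jitter_surrogate <- function(x, sampling_rate_hz = 30, p = NULL) {
  T_len <- length(x)
  p_max <- jitter_p_max(sampling_rate_hz)
  if (T_len <= 2L * p_max)
    stop("series too short for jittering (need length > ", 2L * p_max, ")",
         call. = FALSE)
  if (is.null(p)) p <- sample.int(p_max + 1L, 1L) - 1L
  stopifnot(p >= 0L, p <= p_max)
  x[(p + 1L):(T_len - p)]
}

#' Jitter-null significance of all pairwise correlations
#'
#' For each of `n_jitter` repetitions, every cell's trace is independently
#' jittered ([jitter_surrogate()]); within a repetition all surrogates are
#' truncated to their common (minimum) length, differenced, and correlated,
#' so each pair's null correlation is computed on the overlapping differenced
#' segment. The empirical two-sided p-value uses a +1 pseudocount, and the
#' jitter z-score standardizes the observed correlation against the null
#' correlations.
#'
#' @param traces cells x frames matrix.
#' @param n_jitter number of jitter repetitions (>= 100; the analysis
#'   default is 1000).
#' @param alpha significance level for binary edges (default 0.05).
#' @param sampling_rate_hz sampling rate of the traces.
#' @return list with `W` (jitter z-scored correlations), `R_raw` (observed
#'   differenced-trace correlations), `P` (empirical p-values) and `A`
#'   (binary adjacency, `P < alpha`, zero diagonal).
#' @export
edge_significance <- function(traces, n_jitter = 1000L, alpha = 0.05,
                              sampling_rate_hz = 30) {
  stopifnot(is.matrix(traces))
  n_jitter <- check_count(n_jitter, "n_jitter", min = 100L)
  n <- nrow(traces)
  T_len <- ncol(traces)
  p_max <- jitter_p_max(sampling_rate_hz)
  if (T_len <= 2L * p_max + 2L)
    stop("traces too short for the jitter null", call. = FALSE)

  R_raw <- correlation_matrix(traces)
  abs_obs <- abs(R_raw)

  count <- matrix(0, n, n)
  s1 <- matrix(0, n, n)
  s2 <- matrix(0, n, n)
  for (h in seq_len(n_jitter)) {
    p <- sample.int(p_max + 1L, n, replace = TRUE) - 1L
    L_h <- T_len - 2L * max(p)
    X <- vapply(seq_len(n), function(i) traces[i, (p[i] + 1L):(p[i] + L_h)],
                numeric(L_h))
    D <- X[-1L, , drop = FALSE] - X[-L_h, , drop = FALSE]
    r_h <- suppressWarnings(cor(D))
    count <- count + (abs(r_h) >= abs_obs)
    s1 <- s1 + r_h
    s2 <- s2 + r_h * r_h
  }

  P <- (1 + count) / (1 + n_jitter)
  mu <- s1 / n_jitter
  sigma <- s2 / n_jitter - mu^2
  sigma[sigma < 0] <- 0
  sigma <- sqrt(sigma * n_jitter / (n_jitter - 1))
  W <- (R_raw - mu) / sigma
  degenerate <- sigma == 0
  diag(degenerate) <- FALSE
  if (any(degenerate, na.rm = TRUE)) {
    warning(sum(degenerate, na.rm = TRUE),
            " pair(s) with zero jitter-null sd; W set to NA", call. = FALSE)
    W[degenerate] <- NA_real_
  }
  diag(P) <- NA_real_
  diag(W) <- NA_real_
  A <- (P < alpha) * 1
  A[is.na(A)] <- 0
  diag(A) <- 0
  dimnames(P) <- dimnames(W) <- dimnames(A) <- dimnames(R_raw)
  list(W = W, R_raw = R_raw, P = P, A = A)
}

#' Build a session's correlation network
#'
#' Composes differencing, Pearson correlation, and the jitter-null edge
#' test into a `correlation_network`: the signed, weighted, jitter z-scored
#' matrix `W` feeds the day-to-day similarity analyses, while the sparse
#' binary adjacency `A` (edges with `P < alpha`) feeds module and
#' core-periphery detection.
#'
#' @param session a `fluorescence_session`.
#' @param n_jitter,alpha,sampling_rate_hz see [edge_significance()].
#' @return An object of class `correlation_network`.
#' @export
build_network <- function(session, n_jitter = 1000L, alpha = 0.05,
                          sampling_rate_hz = 30) {
  stopifnot(inherits(session, "fluorescence_session"))
  es <- edge_significance(session$traces, n_jitter = n_jitter,
                          alpha = alpha,
                          sampling_rate_hz = sampling_rate_hz)
  structure(list(session_id = session$session_id,
                 day_offset = session$day_offset,
                 cell_ids = session$cell_ids,
                 positions = session$positions,
                 W = es$W, R_raw = es$R_raw, P = es$P, A = es$A,
                 n_jitter = as.integer(n_jitter), alpha = alpha),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  n <- length(x$cell_ids)
  dens <- mean(x$A[upper.tri(x$A)])
  cat(sprintf(
    "<correlation_network> %s (day %d): %d cells, edge density %.3f (alpha %g, %d jitters)\n",
    x$session_id %||% "?", x$day_offset %||% NA_integer_, n, dens,
    x$alpha, x$n_jitter))
  invisible(x)
}
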