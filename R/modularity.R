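#' Modularity of a partition
#'
#' Evaluates the quality function
#' `Q(gamma) = sum_ij [A_ij - gamma k_i k_j / 2m] delta(g_i, g_j)` over all
#' ordered node pairs, including `i = j` in the degree-null term (with
#' `A_ii = 0`). No `1/2m` prefactor is applied; positive scaling does not
#' change which partition maximizes Q, and under this convention the
#' one-module partition has exactly `Q = 0` at `gamma = 1`.
#'
#' @param A binary symmetric adjacency matrix with zero diagonal.
#' @param labels integer/character module assignment per node.
#' @param gamma resolution parameter; larger values favour smaller modules.
#' @return numeric Q.
#' @export
modularity_q <- function(A, labels, gamma = 1) {
  check_square(A)
  stopifnot(length(labels) == nrow(A))
  k <- rowSums(A)
  two_m <- sum(k)
  if (two_m < 2) stop("empty graph: modularity undefined", call. = FALSE)
  q <- 0
  for (mod in unique(labels)) {
    idx <- which(labels == mod)
    q <- q + sum(A[idx, idx]) - gamma * sum(k[idx])^2 / two_m
  }
  q
}

## Modularity matrix under the package's convention (diagonal carries the
## i = j null term, so the Louvain objective equals modularity_q exactly).
modularity_matrix <- function(A, gamma) {
  k <- rowSums(A)
  two_m <- sum(k)
  if (two_m < 2) stop("empty graph: modularity undefined", call. = FALSE)
  A - gamma * outer(k, k) / two_m
}

## Louvain-style maximization on a dense (symmetric) modularity-type matrix.
## Best of n_runs randomized node orders; also compared against the
## all-singletons and one-module partitions so the returned objective never
## falls below either.
louvain_best <- function(B, n_runs) {
  n <- nrow(B)
  best <- NULL
  for (r in seq_len(n_runs)) {
    res <- louvain_dense(B, sample.int(n))
    if (is.null(best) || res$Q > best$Q) best <- res
  }
  q_single <- sum(diag(B))
  q_whole <- sum(B)
  if (q_single > best$Q)
    best <- list(membership = seq_len(n), Q = q_single)
  if (q_whole > best$Q)
    best <- list(membership = rep(1L, n), Q = q_whole)
  best$membership <- match(best$membership, unique(best$membership))
  best
}

#' Maximize modularity of a single-session network
#'
#' Greedy Louvain-style local moving with agglomeration on the dense
#' modularity matrix, repeated over `n_runs` random node orders; the best
#' partition is returned.
#'
#' @param A binary symmetric adjacency, zero diagonal.
#' @param gamma resolution parameter.
#' @param n_runs number of randomized restarts (default 100).
#' @return integer module labels (1-based, consecutively numbered) with
#'   attributes `Q` and `gamma`.
#' @export
maximize_modularity <- function(A, gamma = 1, n_runs = 100L) {
  check_square(A)
  best <- louvain_best(modularity_matrix(A, gamma), n_runs)
  structure(best$membership, Q = best$Q, gamma = gamma,
            names = rownames(A))
}

#' Module co-assignment matrix
#'
#' `C_ij` is the fraction of the supplied partitions in which nodes `i` and
#' `j` share a module.
#'
#' @param partitions a list of equal-length label vectors, or a node x
#'   partition matrix.
#' @return An object of class `coassignment_matrix` with elements `C`
#'   (symmetric, unit diagonal, values in `[0, 1]`) and `n_partitions`.
#' @export
coassignment <- function(partitions) {
  if (is.list(partitions)) {
    lens <- lengths(partitions)
    if (length(partitions) < 1L) stop("need at least one partition")
    if (length(unique(lens)) != 1L)
      stop("partitions have inconsistent node sets", call. = FALSE)
    nms <- lapply(partitions, names)
    if (!is.null(nms[[1L]]) &&
        !all(vapply(nms, identical, logical(1L), nms[[1L]])))
      stop("partitions have inconsistent node sets", call. = FALSE)
    partitions <- do.call(cbind, partitions)
  }
  n <- nrow(partitions)
  H <- ncol(partitions)
  C <- matrix(0, n, n)
  for (h in seq_len(H)) {
    g <- partitions[, h]
    C <- C + outer(g, g, "==")
  }
  C <- C / H
  dimnames(C) <- list(rownames(partitions), rownames(partitions))
  structure(list(C = C, n_partitions = H), class = "coassignment_matrix")
}

#' @export
print.coassignment_matrix <- function(x, ...) {
  cat(sprintf("<coassignment_matrix> %d nodes, %d partitions\n",
              nrow(x$C), x$n_partitions))
  invisible(x)
}

#' Sample single-layer partitions across resolutions
#'
#' Draws `n_partitions` resolutions uniformly from `gamma_range` and runs
#' one randomized modularity maximization at each; the resulting ensemble
#' feeds the co-assignment consensus (the analysis default ensemble size is
#' 10000; tests use far fewer).
#'
#' @param A binary symmetric adjacency.
#' @param n_partitions ensemble size.
#' @param gamma_range range of resolutions sampled.
#' @return node x partition integer matrix.
#' @export
sample_partitions <- function(A, n_partitions = 10000L,
                              gamma_range = c(0.5, 3)) {
  check_square(A)
  n_partitions <- check_count(n_partitions, "n_partitions")
  gammas <- runif(n_partitions, gamma_range[1L], gamma_range[2L])
  out <- vapply(gammas, function(g)
    as.integer(maximize_modularity(A, g, n_runs = 1L)), integer(nrow(A)))
  rownames(out) <- rownames(A)
  out
}
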