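## Independent brute-force oracles.  These re-derive the package's
## quantities from their definitions with naive loops/enumeration and are
## kept free of package internals.

## Modularity by direct double loop over ordered pairs, i = j included in
## the degree-null term, no prefactor.
brute_modularity <- function(A, labels, gamma = 1) {
  n <- nrow(A)
  k <- rowSums(A)
  two_m <- sum(k)
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (labels[i] == labels[j])
        q <- q + A[i, j] - gamma * k[i] * k[j] / two_m
    }
  }
  q
}

## Multilayer modularity by direct quadruple loop.
brute_multilayer_q <- function(layers, labels, gamma, omega) {
  layers <- lapply(layers, unname)
  n <- nrow(labels)
  T_n <- ncol(labels)
  q <- 0
  for (u in seq_len(T_n)) {
    A <- layers[[u]]
    k <- rowSums(A)
    two_m <- sum(k)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (labels[i, u] == labels[j, u]) {
          null <- if (two_m > 0) gamma * k[i] * k[j] / two_m else 0
          q <- q + A[i, j] - null
        }
      }
    }
  }
  for (i in seq_len(n)) {
    for (u in seq_len(T_n)) {
      for (v in seq_len(T_n)) {
        if (abs(u - v) == 1L && labels[i, u] == labels[i, v])
          q <- q + omega
      }
    }
  }
  q
}

## All set partitions of n elements as membership vectors (restricted
## growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, k) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(k + 1L)) rec(c(prefix, v), max(k, v))
  }
  rec(integer(0), 0L)
  out
}

## Exhaustive maximum of brute modularity over all partitions.
brute_best_q <- function(A, gamma = 1) {
  max(vapply(all_partitions(nrow(A)), function(g)
    brute_modularity(A, g, gamma), numeric(1L)))
}

## All permutations of 1..n as a matrix (rows).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, 0L, n)
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)
    if (pos < n) {
      tmp <- block[, c(seq_len(pos - 1L), n, pos:(n - 1L)), drop = FALSE]
      block <- tmp
    }
    out <- rbind(out, block)
  }
  out
}

## Exhaustive maximum of R = c' G c over all assignments of the template.
brute_best_R <- function(G, tmpl) {
  P <- all_perms(length(tmpl))
  C <- matrix(tmpl[P], nrow(P), ncol(P))
  max(rowSums((C %*% G) * C))
}

## Random symmetric graphs/matrices used by the oracle suites.
random_graph <- function(n, p) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- as.numeric(runif(n * (n - 1) / 2) < p)
  A + t(A)
}

planted_two_block <- function(n, p_in, p_out) {
  half <- n / 2
  labels <- rep(1:2, each = half)
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p <- if (labels[i] == labels[j]) p_in else p_out
      A[i, j] <- A[j, i] <- as.numeric(runif(1) < p)
    }
  }
  list(A = A, labels = labels)
}

two_cliques_bridge <- function(k) {
  n <- 2L * k
  A <- matrix(0, n, n)
  A[seq_len(k), seq_len(k)] <- 1
  A[(k + 1L):n, (k + 1L):n] <- 1
  diag(A) <- 0
  A[k, k + 1L] <- A[k + 1L, k] <- 1
  A
}

random_symmetric_weights <- function(n) {
  G <- matrix(0, n, n)
  G[upper.tri(G)] <- runif(n * (n - 1) / 2)
  G + t(G)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
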