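#' Assemble sessions into a multilayer network
#'
#' The node set is the intersection of the cells present in the chosen
#' sessions (the analysis uses the first five sessions by default); each
#' layer is the session's binary jitter-thresholded adjacency restricted to
#' that common node set, in a fixed shared ordering.
#'
#' @param networks list of `correlation_network`s (>= 2).
#' @param max_layers number of leading sessions to use (default 5).
#' @return An object of class `multilayer_network` with `node_ids`,
#'   `layers` (list of binary adjacencies), `day_offsets` and `T`.
#' @export
build_multilayer <- function(networks, max_layers = 5L) {
  stopifnot(length(networks) >= 2L)
  networks <- networks[seq_len(min(max_layers, length(networks)))]
  ids <- Reduce(intersect, lapply(networks, `[[`, "cell_ids"))
  if (length(ids) == 0L)
    stop("no cells shared by all layers", call. = FALSE)
  layers <- lapply(networks, function(net) {
    idx <- match(ids, net$cell_ids)
    A <- net$A[idx, idx, drop = FALSE]
    dimnames(A) <- list(ids, ids)
    A
  })
  structure(list(node_ids = ids, layers = layers,
                 day_offsets = vapply(networks, `[[`, integer(1L),
                                      "day_offset"),
                 T = length(layers)),
            class = "multilayer_network")
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat(sprintf("<multilayer_network> %d cells x %d layers (days %s)\n",
              length(x$node_ids), x$T,
              paste(x$day_offsets, collapse = ", ")))
  invisible(x)
}

## Per-layer modularity matrix; empty layers get a zero null term.
layer_modularity_matrix <- function(A, gamma) {
  k <- rowSums(A)
  two_m <- sum(k)
  if (two_m == 0) return(A)
  A - gamma * outer(k, k) / two_m
}

#' Multilayer modularity of a node x layer labeling
#'
#' Intra-layer terms follow the single-layer convention (per-layer degree
#' null, ordered pairs including `i = j`); the inter-layer term adds
#' `omega` for every node and every ordered pair of adjacent layers in
#' which the node keeps its label, so a labeling constant across layers
#' contributes `2 * omega * N * (T - 1)`.
#'
#' @param ml a `multilayer_network`.
#' @param labels node x layer label matrix.
#' @param gamma intra-layer resolution.
#' @param omega inter-layer coupling.
#' @return numeric Q.
#' @export
multilayer_modularity <- function(ml, labels, gamma = 1, omega = 1) {
  stopifnot(inherits(ml, "multilayer_network"),
            nrow(labels) == length(ml$node_ids),
            ncol(labels) == ml$T)
  q <- 0
  for (u in seq_len(ml$T)) {
    B <- layer_modularity_matrix(ml$layers[[u]], gamma)
    g <- labels[, u]
    same <- outer(g, g, "==")
    q <- q + sum(B[same])
  }
  for (u in seq_len(ml$T - 1L))
    q <- q + 2 * omega * sum(labels[, u] == labels[, u + 1L])
  q
}

## Supra-modularity matrix: block-diagonal per-layer modularity matrices
## plus omega * I coupling between adjacent layers (ordinal coupling).
supra_matrix <- function(ml, gamma, omega, all_pairs = FALSE) {
  n <- length(ml$node_ids)
  T_n <- ml$T
  B <- matrix(0, n * T_n, n * T_n)
  for (u in seq_len(T_n)) {
    idx <- (u - 1L) * n + seq_len(n)
    B[idx, idx] <- layer_modularity_matrix(ml$layers[[u]], gamma)
  }
  couple <- function(u, v) {
    iu <- (u - 1L) * n + seq_len(n)
    iv <- (v - 1L) * n + seq_len(n)
    B[cbind(iu, iv)] <<- B[cbind(iu, iv)] + omega
    B[cbind(iv, iu)] <<- B[cbind(iv, iu)] + omega
  }
  if (all_pairs) {
    for (u in seq_len(T_n - 1L))
      for (v in (u + 1L):T_n) couple(u, v)
  } else {
    for (u in seq_len(T_n - 1L)) couple(u, u + 1L)
  }
  B
}

#' Maximize multilayer modularity
#'
#' Louvain-style maximization on the supra-graph whose nodes are
#' (cell, layer) pairs: intra-layer weights from each layer's modularity
#' matrix and inter-layer weight `omega` linking each cell to itself in
#' adjacent layers. Community labels share one namespace across layers, so
#' assignments are directly comparable between sessions.
#'
#' @param ml a `multilayer_network`.
#' @param gamma,omega resolution and coupling parameters.
#' @param n_runs randomized restarts (default 10).
#' @param all_pairs couple all layer pairs instead of adjacent layers only.
#' @return An object of class `multilayer_partition`: `labels` (node x
#'   layer), `gamma`, `omega`, `Q`.
#' @export
maximize_multilayer <- function(ml, gamma = 1, omega = 1, n_runs = 10L,
                                all_pairs = FALSE) {
  stopifnot(inherits(ml, "multilayer_network"))
  n <- length(ml$node_ids)
  best <- louvain_best(supra_matrix(ml, gamma, omega, all_pairs), n_runs)
  labels <- matrix(best$membership, n, ml$T,
                   dimnames = list(ml$node_ids, NULL))
  structure(list(labels = labels, gamma = gamma, omega = omega,
                 Q = best$Q), class = "multilayer_partition")
}

#' @export
print.multilayer_partition <- function(x, ...) {
  cat(sprintf(
    "<multilayer_partition> %d cells x %d layers, %d communities (gamma %.3g, omega %.3g, Q %.3f)\n",
    nrow(x$labels), ncol(x$labels), length(unique(as.vector(x$labels))),
    x$gamma, x$omega, x$Q))
  invisible(x)
}

#' Node flexibility of a multilayer partition
#'
#' `f_i = 1 - (1/(T-1)) * sum_u delta(g_{i,u}, g_{i,u+1})`: the fraction of
#' adjacent-layer transitions at which node `i` changes community. 0 means
#' the node keeps one community across all layers; 1 means it changes at
#' every transition.
#'
#' @param labels node x layer label matrix, or a `multilayer_partition`.
#' @return numeric vector of per-node flexibilities in `[0, 1]`.
#' @export
flexibility <- function(labels) {
  if (inherits(labels, "multilayer_partition")) labels <- labels$labels
  stopifnot(is.matrix(labels), ncol(labels) >= 2L)
  T_n <- ncol(labels)
  same <- labels[, -1L, drop = FALSE] == labels[, -T_n, drop = FALSE]
  1 - rowSums(same) / (T_n - 1L)
}

## Partition statistics used by the parameter-space bounding.
partition_stats <- function(ml, gamma, omega, n_runs = 1L) {
  part <- maximize_multilayer(ml, gamma, omega, n_runs)
  list(K = length(unique(as.vector(part$labels))),
       f = mean(flexibility(part)))
}

bounds_feasible <- function(st, n_total) {
  st$K > 1L && st$K < n_total && st$f > 0 && st$f < 1
}

#' Bound the feasible (gamma, omega) parameter space
#'
#' Finds an axis-aligned box of `{gamma, omega}` values for which multilayer
#' modularity maximization yields informative community structure: more
#' than one community but fewer than `N * T`, and mean flexibility strictly
#' between 0 (uniform across layers) and 1 (maximally dissimilar). A coarse
#' probe grid locates a feasible interior point; each axis is then bisected
#' (the other held at its reference value) to the boundary of feasibility,
#' and the box is shrunk until all four corners satisfy the conditions.
#'
#' @param ml a `multilayer_network`.
#' @param n_runs Louvain restarts per evaluation (default 1; the bounding
#'   only needs representative partitions).
#' @param n_eval repeated evaluations per feasibility decision; a point is
#'   feasible when the majority of evaluations satisfies the conditions,
#'   which keeps single stray partitions from extending the box into
#'   regimes that are only degenerately feasible.
#' @param max_shrink maximum corner-repair shrink iterations.
#' @return list of class `parameter_bounds` with `gamma_range` and
#'   `omega_range`.
#' @export
estimate_parameter_bounds <- function(ml, n_runs = 1L, n_eval = 3L,
                                      max_shrink = 20L) {
  n_total <- length(ml$node_ids) * ml$T
  probe_g <- c(0.25, 0.5, 1, 2, 4)
  probe_w <- c(0.05, 0.1, 0.25, 0.5, 1, 2)
  ## reference point: the feasible probe point whose mean flexibility sits
  ## farthest from the degenerate boundaries 0 and 1
  best_margin <- -1
  g0 <- w0 <- NULL
  for (g in probe_g) {
    for (w in probe_w) {
      st <- partition_stats(ml, g, w, n_runs)
      if (bounds_feasible(st, n_total) &&
          min(st$f, 1 - st$f) > best_margin) {
        best_margin <- min(st$f, 1 - st$f)
        g0 <- g; w0 <- w
      }
    }
  }
  if (is.null(g0))
    stop("no feasible {gamma, omega} region found on the probe grid; ",
         "the layers may be empty or fully connected", call. = FALSE)

  feasible_at <- function(g, w) {
    ok <- vapply(seq_len(n_eval), function(i)
      bounds_feasible(partition_stats(ml, g, w, n_runs), n_total),
      logical(1L))
    sum(ok) > n_eval / 2
  }

  bisect_edge <- function(lo, hi, fn, lo_feasible, iters = 10L) {
    ## fn(x) feasibility; exactly one of lo/hi is feasible
    for (i in seq_len(iters)) {
      mid <- (lo + hi) / 2
      if (fn(mid) == lo_feasible) lo <- mid else hi <- mid
    }
    if (lo_feasible) lo else hi
  }

  expand_up <- function(x0, fn, cap = 64) {
    hi <- x0
    while (hi < cap && fn(hi * 2)) hi <- hi * 2
    min(hi * 2, cap)
  }

  ## gamma axis at omega = w0
  g_lo <- bisect_edge(0, g0, function(g) feasible_at(g, w0),
                      lo_feasible = FALSE)
  g_hi_out <- expand_up(g0, function(g) feasible_at(g, w0))
  g_hi <- bisect_edge(g0, g_hi_out, function(g) feasible_at(g, w0),
                      lo_feasible = TRUE)
  g_mid <- (g_lo + g_hi) / 2

  ## omega axis at gamma = g_mid
  w_lo <- bisect_edge(0, w0, function(w) feasible_at(g_mid, w),
                      lo_feasible = FALSE)
  w_hi_out <- expand_up(w0, function(w) feasible_at(g_mid, w))
  w_hi <- bisect_edge(w0, w_hi_out, function(w) feasible_at(g_mid, w),
                      lo_feasible = TRUE)

  ## pull in a safety margin, then repair failing corners by moving the
  ## offending box ends toward the reference point
  shrink <- function(r, f = 0.05) r + c(1, -1) * f * diff(r) / 2
  gr <- shrink(c(g_lo, g_hi))
  wr <- shrink(c(w_lo, w_hi))
  ref_g <- min(max(g0, gr[1L]), gr[2L])
  ref_w <- min(max(w0, wr[1L]), wr[2L])
  for (i in seq_len(max_shrink)) {
    corners <- expand.grid(g = gr, w = wr)
    ok <- mapply(feasible_at, corners$g, corners$w)
    if (all(ok)) break
    bad <- corners[!ok, , drop = FALSE]
    pull <- function(x, ref) x + 0.15 * (ref - x)
    if (any(bad$g == gr[1L])) gr[1L] <- pull(gr[1L], ref_g)
    if (any(bad$g == gr[2L])) gr[2L] <- pull(gr[2L], ref_g)
    if (any(bad$w == wr[1L])) wr[1L] <- pull(wr[1L], ref_w)
    if (any(bad$w == wr[2L])) wr[2L] <- pull(wr[2L], ref_w)
  }
  if (!all(ok))
    stop("could not certify a feasible {gamma, omega} box; corner stats: ",
         paste(sprintf("(%.3g, %.3g): %s", corners$g, corners$w, ok),
               collapse = "; "), call. = FALSE)
  structure(list(gamma_range = gr, omega_range = wr),
            class = "parameter_bounds")
}

#' @export
print.parameter_bounds <- function(x, ...) {
  cat(sprintf("<parameter_bounds> gamma [%.3g, %.3g], omega [%.3g, %.3g]\n",
              x$gamma_range[1L], x$gamma_range[2L], x$omega_range[1L],
              x$omega_range[2L]))
  invisible(x)
}

#' Rank-averaged flexibility over a parameter-space sample
#'
#' Samples `{gamma, omega}` pairs uniformly from the feasible box,
#' maximizes multilayer modularity at each, computes per-node flexibility,
#' ranks the nodes within each sample, and averages the ranks across
#' samples into a flexibility profile. Rank averaging makes the profile
#' robust to the overall flexibility scale varying across the box.
#'
#' @param ml a `multilayer_network`.
#' @param n_samples number of parameter samples (analysis default 10000;
#'   reduced sampling such as 200 is typical for testing).
#' @param bounds a `parameter_bounds`; estimated when `NULL`.
#' @param n_runs Louvain restarts per sample (default 1).
#' @return An object of class `flexibility_profile`: `profile` data.frame
#'   with `cell_id`, `mean_rank_flexibility`, `mean_flexibility`, plus
#'   `n_samples`, `bounds` and the per-sample parameter table.
#' @export
sample_flexibility <- function(ml, n_samples = 10000L, bounds = NULL,
                               n_runs = 1L) {
  n_samples <- check_count(n_samples, "n_samples")
  if (is.null(bounds)) bounds <- estimate_parameter_bounds(ml, n_runs)
  n <- length(ml$node_ids)
  gam <- runif(n_samples, bounds$gamma_range[1L], bounds$gamma_range[2L])
  ome <- runif(n_samples, bounds$omega_range[1L], bounds$omega_range[2L])
  rank_sum <- numeric(n)
  flex_sum <- numeric(n)
  for (s in seq_len(n_samples)) {
    part <- maximize_multilayer(ml, gam[s], ome[s], n_runs)
    f <- flexibility(part)
    rank_sum <- rank_sum + rank(f, ties.method = "average")
    flex_sum <- flex_sum + f
  }
  structure(list(
    profile = data.frame(cell_id = ml$node_ids,
                         mean_rank_flexibility = rank_sum / n_samples,
                         mean_flexibility = flex_sum / n_samples),
    n_samples = n_samples, bounds = bounds,
    samples = data.frame(gamma = gam, omega = ome)
  ), class = "flexibility_profile")
}

#' @export
print.flexibility_profile <- function(x, ...) {
  cat(sprintf(
    "<flexibility_profile> %d cells over %d {gamma, omega} samples\n",
    nrow(x$profile), x$n_samples))
  cat(sprintf("  mean flexibility %.3f (range %.3f-%.3f)\n",
              mean(x$profile$mean_flexibility),
              min(x$profile$mean_flexibility),
              max(x$profile$mean_flexibility)))
  invisible(x)
}
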