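## Degree-preserving rewiring null for the hierarchy significance test.
rewire_adjacency <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  m <- igraph::ecount(g)
  if (m < 2L) return(A)
  g <- igraph::rewire(g, igraph::keeping_degseq(niter = 10L * m))
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

## Test whether a (sub)graph splits significantly at resolution gamma:
## compare the maximized Q against the same statistic on degree-preserving
## rewired copies.  Returns NULL when the graph does not split.
test_split <- function(subA, gamma, n_runs, n_null, sig_alpha) {
  g <- maximize_modularity(subA, gamma, n_runs)
  if (length(unique(g)) < 2L) return(NULL)
  q_obs <- attr(g, "Q")
  q_null <- vapply(seq_len(n_null), function(b) {
    attr(maximize_modularity(rewire_adjacency(subA), gamma, n_runs), "Q")
  }, numeric(1L))
  p <- (1 + sum(q_null >= q_obs)) / (1 + n_null)
  list(labels = as.integer(g), p = p, q_obs = q_obs,
       significant = p < sig_alpha)
}

#' Multi-resolution hierarchical module detection with significance testing
#'
#' Recursive scheme: the whole network is scanned over increasing
#' resolutions until the coarsest `gamma` at which modularity maximization
#' splits it; the split is retained only if its modularity exceeds the same
#' statistic on degree-preserving rewired null graphs (`p < sig_alpha`).
#' Each retained module is then re-examined on its induced subgraph at equal
#' or finer resolutions, and recursion stops where no significant split
#' exists. Levels are reported coarse to fine and every retained level has
#' passed the null test, so hierarchies are never built from splits that a
#' random graph with the same degrees would also produce.
#'
#' @param A binary symmetric adjacency, zero diagonal.
#' @param gammas increasing grid of candidate resolutions.
#' @param n_runs Louvain restarts per maximization (observed and null alike,
#'   keeping the comparison calibrated).
#' @param n_null number of rewired null graphs per candidate split.
#' @param sig_alpha significance level for retaining a split.
#' @param min_size modules smaller than this are not examined further.
#' @return An object of class `hierarchical_partition`: `labels` (levels x
#'   nodes, level 1 coarsest), `gamma_per_level`, `p_per_level`, `n_levels`,
#'   and the individual `splits`.
#' @export
hierarchical_sweep <- function(A, gammas = seq(0.25, 4, by = 0.25),
                               n_runs = 100L, n_null = 100L,
                               sig_alpha = 0.05, min_size = 4L) {
  check_square(A)
  n <- nrow(A)
  splits <- list()
  queue <- list(list(nodes = seq_len(n), gi = 1L, depth = 1L))
  while (length(queue) > 0L) {
    task <- queue[[1L]]
    queue <- queue[-1L]
    subA <- A[task$nodes, task$nodes, drop = FALSE]
    if (sum(subA) < 2) next  # too few edges to define modularity
    for (gi in task$gi:length(gammas)) {
      res <- tryCatch(
        test_split(subA, gammas[gi], n_runs, n_null, sig_alpha),
        error = function(e) NULL)
      if (is.null(res)) next       # did not split; try a finer resolution
      if (!res$significant) break  # coarsest split fails the null test
      splits[[length(splits) + 1L]] <- list(
        nodes = task$nodes, labels = res$labels, depth = task$depth,
        gamma = gammas[gi], p = res$p)
      for (mod in unique(res$labels)) {
        child <- task$nodes[res$labels == mod]
        if (length(child) >= min_size)
          queue[[length(queue) + 1L]] <-
            list(nodes = child, gi = gi, depth = task$depth + 1L)
      }
      break
    }
  }

  n_levels <- if (length(splits)) max(vapply(splits, `[[`, integer(1L),
                                             "depth")) else 0L
  labels <- matrix(integer(0), 0L, n)
  colnames(labels) <- rownames(A)
  gamma_per_level <- p_per_level <- numeric(0)
  cur <- rep(1L, n)
  if (n_levels > 0L) {
    labels <- matrix(NA_integer_, n_levels, n,
                     dimnames = list(paste0("level_", seq_len(n_levels)),
                                     rownames(A)))
    for (d in seq_len(n_levels)) {
      depth_splits <- Filter(function(s) s$depth == d, splits)
      new <- cur
      offset <- max(cur)
      for (s in depth_splits) {
        new[s$nodes] <- offset + s$labels
        offset <- max(new)
      }
      cur <- match(new, unique(new))
      labels[d, ] <- cur
      gamma_per_level[d] <- mean(vapply(depth_splits, `[[`, numeric(1L),
                                        "gamma"))
      p_per_level[d] <- max(vapply(depth_splits, `[[`, numeric(1L), "p"))
    }
  }

  structure(list(labels = labels, gamma_per_level = gamma_per_level,
                 p_per_level = p_per_level, n_levels = n_levels,
                 splits = splits, sig_alpha = sig_alpha),
            class = "hierarchical_partition")
}

#' @export
print.hierarchical_partition <- function(x, ...) {
  cat(sprintf("<hierarchical_partition> %d significant level(s)\n",
              x$n_levels))
  if (x$n_levels > 0L) {
    for (d in seq_len(x$n_levels))
      cat(sprintf("  level %d: %d modules (gamma %.2f, p <= %.3f)\n", d,
                  length(unique(x$labels[d, ])), x$gamma_per_level[d],
                  x$p_per_level[d]))
  }
  invisible(x)
}

## Mean nearest same-module-neighbour distance for each module of one
## partition, given a full inter-cell distance matrix with Inf diagonal.
module_nn_stat <- function(Dmat, labels, mods) {
  vapply(mods, function(mod) {
    idx <- which(labels == mod)
    sub <- Dmat[idx, idx, drop = FALSE]
    mean(apply(sub, 1L, min))
  }, numeric(1L))
}

#' Spatial compactness of modules
#'
#' For each module, the mean Euclidean distance from each member cell to its
#' nearest same-module cell is compared with a null distribution obtained by
#' uniformly permuting all cell positions while preserving module
#' assignments, and expressed as a z-score. Negative z means the module is
#' more spatially compact than chance. When a hierarchy is supplied the
#' statistic is computed at every level and the Spearman correlation of z
#' with hierarchical level is reported.
#'
#' @param labels a label vector, or a `hierarchical_partition`.
#' @param positions cells x 2 coordinate matrix (micrometres).
#' @param n_perm number of position permutations (default 1000).
#' @return An object of class `spatial_stats`: per-module table with
#'   `observed`, `null_mean`, `null_sd`, `z`, and (for hierarchies)
#'   `rho_z_level`, the Spearman correlation of z with level.
#' @export
spatial_compactness <- function(labels, positions, n_perm = 1000L) {
  n_perm <- check_count(n_perm, "n_perm")
  if (inherits(labels, "hierarchical_partition")) {
    lab_mat <- labels$labels
  } else {
    lab_mat <- matrix(labels, 1L, length(labels))
    rownames(lab_mat) <- "level_1"
  }
  stopifnot(ncol(lab_mat) == nrow(positions))
  Dmat <- as.matrix(dist(positions))
  diag(Dmat) <- Inf
  n <- nrow(positions)

  rows <- list()
  for (lev in seq_len(nrow(lab_mat))) {
    lab <- lab_mat[lev, ]
    sizes <- table(lab)
    mods <- names(sizes)[sizes >= 2L]
    if (length(mods) < length(sizes))
      warning("skipping ", length(sizes) - length(mods),
              " singleton module(s) at level ", lev, call. = FALSE)
    if (length(mods) == 0L) next
    obs <- module_nn_stat(Dmat, lab, mods)
    null_stats <- matrix(NA_real_, n_perm, length(mods))
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      null_stats[b, ] <- module_nn_stat(Dmat[perm, perm], lab, mods)
    }
    null_mean <- colMeans(null_stats)
    null_sd <- apply(null_stats, 2L, sd)
    z <- ifelse(null_sd == 0, 0, (obs - null_mean) / null_sd)
    whole <- as.integer(sizes[mods]) == n
    if (any(whole)) {
      message("module spanning all cells: permutation-invariant, z = 0")
      z[whole] <- 0
    }
    rows[[length(rows) + 1L]] <- data.frame(
      level = lev, module = mods, size = as.integer(sizes[mods]),
      observed = obs, null_mean = null_mean, null_sd = null_sd, z = z,
      row.names = NULL)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(level = integer(0), module = character(0),
               size = integer(0), observed = numeric(0),
               null_mean = numeric(0), null_sd = numeric(0), z = numeric(0))
  rho <- if (length(unique(tab$level)) >= 2L)
    suppressWarnings(cor(tab$z, tab$level, method = "spearman")) else
      NA_real_
  structure(list(modules = tab, rho_z_level = rho, n_perm = n_perm),
            class = "spatial_stats")
}

#' @export
print.spatial_stats <- function(x, ...) {
  cat(sprintf("<spatial_stats> %d module(s), %d permutations\n",
              nrow(x$modules), x$n_perm))
  if (nrow(x$modules)) {
    cat(sprintf("  median z: %.2f\n", median(x$modules$z)))
    if (!is.na(x$rho_z_level))
      cat(sprintf("  Spearman rho(z, level): %.2f\n", x$rho_z_level))
  }
  invisible(x)
}
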