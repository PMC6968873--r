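#' Cross-session edge consistency matrix
#'
#' `G_ij` is the fraction of layers (recording sessions) in which the edge
#' `(i, j)` was present in the thresholded adjacency, so values are
#' multiples of `1/T` in `[0, 1]` with a zero diagonal. Persistent coupling
#' shows up as entries near 1.
#'
#' @param ml a `multilayer_network`.
#' @return An object of class `consistency_matrix` with `G`, `node_ids`,
#'   `T`.
#' @export
consistency_matrix <- function(ml) {
  stopifnot(inherits(ml, "multilayer_network"), ml$T >= 2L)
  G <- Reduce(`+`, ml$layers) / ml$T
  diag(G) <- 0
  structure(list(G = G, node_ids = ml$node_ids, T = ml$T),
            class = "consistency_matrix")
}

#' @export
print.consistency_matrix <- function(x, ...) {
  cat(sprintf(
    "<consistency_matrix> %d cells over %d layers; mean consistency %.3f\n",
    length(x$node_ids), x$T, mean(x$G[upper.tri(x$G)])))
  invisible(x)
}

as_G <- function(G) {
  if (inherits(G, "consistency_matrix")) G <- G$G
  check_square(G, "G")
  G
}

#' Sigmoidal coreness template
#'
#' `C*_m = 1 / (1 + exp(-(m - beta * N) * tan(pi * alpha / 2)))` for
#' `m = 1..N`. `alpha` sets the sharpness of the core-periphery transition
#' (0 = maximally fuzzy, every entry 0.5; 1 = binary step, handled as the
#' limit) and `beta` sets the core size (as `beta` goes from 0 to 1 the
#' core shrinks from `N` nodes to none). Entries are nondecreasing in `m`.
#'
#' @param N number of nodes.
#' @param alpha shape parameter in `[0, 1]`.
#' @param beta size parameter in `[0, 1]`.
#' @return numeric vector of length `N`.
#' @export
core_template <- function(N, alpha, beta) {
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, beta <= 1)
  m <- seq_len(N)
  if (alpha >= 1) {
    out <- ifelse(m < beta * N, 0, ifelse(m > beta * N, 1, 0.5))
  } else {
    out <- 1 / (1 + exp(-(m - beta * N) * tan(pi * alpha / 2)))
  }
  out
}

#' Core quality of a coreness assignment
#'
#' `R = sum_ij G_ij C_i C_j` over ordered pairs (the diagonal of `G` is
#' zero, so the pair convention is immaterial). Higher `R` means high-
#' coreness nodes concentrate on persistent edges.
#'
#' @param G consistency matrix (or `consistency_matrix` object).
#' @param coreness per-node coreness values.
#' @return numeric R.
#' @export
core_quality <- function(G, coreness) {
  G <- as_G(G)
  stopifnot(length(coreness) == nrow(G))
  as.numeric(t(coreness) %*% G %*% coreness)
}

#' Fit coreness by simulated annealing
#'
#' Assigns the [core_template()] values to nodes so as to maximize the core
#' quality `R`, by simulated annealing over template permutations
#' (pairwise swaps, geometric cooling, initial temperature calibrated to an
#' ~80% acceptance rate) followed by a greedy swap polish, best of
#' `n_restarts` restarts. The first restart starts from the strength
#' ranking of `G` (strong nodes get large template values); the rest start
#' from random assignments.
#'
#' @param G consistency matrix (or `consistency_matrix` object).
#' @param alpha,beta template parameters, see [core_template()].
#' @param n_restarts annealing restarts (default 10).
#' @param cooling geometric temperature decay per sweep.
#' @param stall_sweeps stop after this many sweeps without improvement.
#' @param max_sweeps hard cap on sweeps per restart.
#' @param normalize divide the fitted coreness by `sqrt(sum_ij C_i C_j)` so
#'   `R` is comparable across `(alpha, beta)`; the optimal assignment is
#'   unchanged.
#' @return An object of class `coreness_result`: named `coreness` vector (a
#'   permutation of the template), `alpha`, `beta`, `R`, and `core_mask`
#'   from thresholding the sigmoid at its midpoint (coreness > 0.5).
#' @export
anneal_coreness <- function(G, alpha, beta, n_restarts = 10L,
                            cooling = 0.95, stall_sweeps = 50L,
                            max_sweeps = 500L, normalize = FALSE) {
  ids <- if (inherits(G, "consistency_matrix")) G$node_ids else rownames(G)
  G <- as_G(G)
  n <- nrow(G)
  tmpl <- core_template(n, alpha, beta)
  strength_init <- rank(rowSums(G), ties.method = "first")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- if (r == 1L) strength_init else sample.int(n)
    res <- anneal_assignment(G, tmpl, init, cooling, stall_sweeps,
                             max_sweeps, 0.8)
    if (is.null(best) || res$R > best$R) best <- res
  }
  coreness <- best$coreness
  R <- best$R
  if (normalize) {
    denom <- sum(outer(coreness, coreness))
    if (denom > 0) {
      coreness <- coreness / sqrt(denom)  # makes sum_ij C_i C_j equal 1
      R <- core_quality(G, coreness)
    }
  }
  names(coreness) <- ids
  structure(list(coreness = coreness, alpha = alpha, beta = beta, R = R,
                 core_mask = coreness > 0.5, n_restarts = n_restarts),
            class = "coreness_result")
}

#' @export
print.coreness_result <- function(x, ...) {
  cat(sprintf(
    "<coreness_result> %d nodes, alpha %.3g beta %.3g, R = %.4f, %d core node(s) at midpoint\n",
    length(x$coreness), x$alpha, x$beta, x$R, sum(x$core_mask)))
  invisible(x)
}

## Weight-shuffling null: permute the off-diagonal entries of G uniformly,
## keeping the matrix symmetric with zero diagonal.  Destroys which node
## pairs carry persistent edges while preserving the weight distribution.
shuffle_weights <- function(G) {
  G <- as_G(G)
  v <- G[upper.tri(G)]
  out <- matrix(0, nrow(G), ncol(G))
  out[upper.tri(out)] <- sample(v)
  out + t(out)
}

## 31 x 31 default grid of template parameters on [0, 1]^2.
grid_points <- function(n_grid = 31L) {
  vals <- seq(0, 1, length.out = n_grid)
  expand.grid(alpha = vals, beta = vals)
}

#' Grid search of the core-periphery parameter space
#'
#' Evaluates the annealed core quality on a `n_grid` x `n_grid` grid of
#' linearly spaced `(alpha, beta)` values in `[0, 1]^2` (31 x 31 = 961
#' points by default). At each point the observed `R` is compared with the
#' mean over `n_null` weight-shuffled copies of `G` annealed with identical
#' settings, giving `delta_R`; the top 10% of grid points by `delta_R`
#' are flagged as the parameter regimes where the observed core most
#' exceeds chance.
#'
#' @param G consistency matrix (or `consistency_matrix` object).
#' @param n_grid grid points per axis (default 31).
#' @param n_null null matrices per grid point (default 100).
#' @param n_restarts annealing restarts per fit (default 10).
#' @param ... further arguments to [anneal_coreness()].
#' @return A data.frame of class `core_grid` with columns `alpha`, `beta`,
#'   `R_obs`, `R_null_mean`, `R_null_sd`, `delta_R`, `top10`.
#' @export
grid_search <- function(G, n_grid = 31L, n_null = 100L, n_restarts = 10L,
                        ...) {
  G <- as_G(G)
  pts <- grid_points(n_grid)
  res <- lapply(seq_len(nrow(pts)), function(i) {
    fit <- anneal_coreness(G, pts$alpha[i], pts$beta[i],
                           n_restarts = n_restarts, ...)
    null_R <- vapply(seq_len(n_null), function(b)
      anneal_coreness(shuffle_weights(G), pts$alpha[i], pts$beta[i],
                      n_restarts = n_restarts, ...)$R, numeric(1L))
    c(R_obs = fit$R, R_null_mean = mean(null_R), R_null_sd = sd(null_R))
  })
  res <- do.call(rbind, res)
  out <- cbind(pts, as.data.frame(res))
  out$delta_R <- out$R_obs - out$R_null_mean
  out$top10 <- out$delta_R >= quantile(out$delta_R, 0.9)
  class(out) <- c("core_grid", class(out))
  out
}

#' Top-coreness node ids
#'
#' The `top_frac` fraction of nodes ranked by coreness (the "top 10%" core
#' definition used for the core-versus-periphery stability comparison).
#' Warns when coreness is constant and the selection falls back to an
#' arbitrary tie-break.
#'
#' @param coreness named coreness vector or `coreness_result`.
#' @param top_frac fraction of nodes to select (default 0.1).
#' @return character vector of cell ids.
#' @export
top_core_ids <- function(coreness, top_frac = 0.1) {
  if (inherits(coreness, "coreness_result")) coreness <- coreness$coreness
  if (length(unique(coreness)) == 1L)
    warning("coreness is constant; top-fraction selection is an arbitrary ",
            "tie-break", call. = FALSE)
  n_core <- max(1L, round(top_frac * length(coreness)))
  names(sort(coreness, decreasing = TRUE))[seq_len(n_core)]
}

## Copy of a correlation network restricted to a cell subset.
restrict_network <- function(net, ids) {
  keep <- net$cell_ids %in% ids
  idx <- which(keep)
  out <- net
  out$cell_ids <- net$cell_ids[idx]
  for (fld in c("W", "R_raw", "P", "A"))
    if (!is.null(out[[fld]]))
      out[[fld]] <- out[[fld]][idx, idx, drop = FALSE]
  if (!is.null(out$positions))
    out$positions <- out$positions[idx, , drop = FALSE]
  out
}

#' Similarity decay within core versus non-core cells
#'
#' Runs the session-pair similarity decay analysis twice: once on the
#' correlation submatrices restricted to the top-coreness cells and once on
#' the remaining cells. A temporally stable core shows a weaker (less
#' negative) decay than the periphery.
#'
#' @param networks list of `correlation_network`s.
#' @param coreness named coreness vector or a `coreness_result`.
#' @param top_frac fraction of nodes forming the core (default 0.1).
#' @param n_perm Mantel permutations per pair.
#' @param min_shared minimum shared cells per pair within each group
#'   (default 4; a core smaller than 4 cells is flagged).
#' @return list of class `core_stability`: `core` and `noncore`
#'   `decay_result`s plus the core cell ids.
#' @export
core_noncore_stability <- function(networks, coreness, top_frac = 0.1,
                                   n_perm = 1000L, min_shared = 4L) {
  if (inherits(coreness, "coreness_result")) coreness <- coreness$coreness
  core_ids <- top_core_ids(coreness, top_frac)
  noncore_ids <- setdiff(names(coreness), core_ids)
  if (length(core_ids) < 4L)
    warning("core group has fewer than 4 cells; similarity estimates are ",
            "unstable", call. = FALSE)
  run_group <- function(ids) {
    nets <- lapply(networks, restrict_network, ids = ids)
    tab <- session_similarity(nets, kind = "correlation", n_perm = n_perm,
                              min_shared = min_shared)
    tryCatch(decay_analysis(tab), error = function(e) NULL)
  }
  structure(list(core = run_group(core_ids),
                 noncore = run_group(noncore_ids),
                 core_ids = core_ids, top_frac = top_frac),
            class = "core_stability")
}

#' @export
print.core_stability <- function(x, ...) {
  rc <- if (is.null(x$core)) NA_real_ else x$core$r
  rn <- if (is.null(x$noncore)) NA_real_ else x$noncore$r
  cat(sprintf(
    "<core_stability> top %.0f%% core (%d cells): decay r core %.3f vs non-core %.3f\n",
    100 * x$top_frac, length(x$core_ids), rc, rn))
  invisible(x)
}

#' Correlation of flexibility and coreness
#'
#' Spearman correlation of the rank-averaged flexibility profile against
#' the fitted coreness over the shared node set. Flexibility measures
#' variability and coreness stability, so the two are expected to be
#' inversely related.
#'
#' @param flex a `flexibility_profile`.
#' @param core a `coreness_result` or named coreness vector.
#' @return Spearman rho (`NA` with a warning if either input is constant).
#' @export
flexibility_vs_coreness <- function(flex, core) {
  stopifnot(inherits(flex, "flexibility_profile"))
  coreness <- if (inherits(core, "coreness_result")) core$coreness else core
  shared <- intersect(flex$profile$cell_id, names(coreness))
  stopifnot(length(shared) >= 3L)
  f <- flex$profile$mean_rank_flexibility[match(shared,
                                                flex$profile$cell_id)]
  c_vals <- coreness[shared]
  if (sd(f) == 0 || sd(c_vals) == 0) {
    warning("constant flexibility or coreness; correlation undefined",
            call. = FALSE)
    return(NA_real_)
  }
  cor(f, c_vals, method = "spearman")
}
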