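## Extract (matrix, cell ids, day offset) from the objects the similarity
## machinery accepts.
session_matrix <- function(x, what = c("W", "C")) {
  what <- match.arg(what)
  if (inherits(x, "correlation_network"))
    return(list(M = x$W, ids = x$cell_ids, day = x$day_offset))
  if (inherits(x, "coassignment_matrix"))
    return(list(M = x$C, ids = rownames(x$C), day = attr(x, "day_offset")))
  if (is.matrix(x)) {
    if (is.null(rownames(x)))
      stop("plain matrices need cell ids as dimnames", call. = FALSE)
    return(list(M = x, ids = rownames(x), day = attr(x, "day_offset")))
  }
  stop("unsupported session object", call. = FALSE)
}

#' Restrict two session matrices to their shared cells
#'
#' @param net_u,net_v `correlation_network` objects (their `W` is used) or
#'   matrices with cell ids as dimnames.
#' @param min_shared minimum number of shared cells (default 10); below it
#'   the pair is skipped with a warning and `NULL` is returned.
#' @return list with `M_u`, `M_v` (identical cell ordering) and
#'   `shared_ids`, or `NULL`.
#' @export
shared_submatrices <- function(net_u, net_v, min_shared = 10L) {
  su <- session_matrix(net_u)
  sv <- session_matrix(net_v)
  shared <- intersect(su$ids, sv$ids)
  if (length(shared) < min_shared) {
    warning(sprintf("only %d shared cells (< %d); pair skipped",
                    length(shared), min_shared), call. = FALSE)
    return(NULL)
  }
  iu <- match(shared, su$ids)
  iv <- match(shared, sv$ids)
  list(M_u = su$M[iu, iu, drop = FALSE],
       M_v = sv$M[iv, iv, drop = FALSE],
       shared_ids = shared)
}

#' Pearson similarity of two symmetric session matrices
#'
#' Vectorizes the strictly upper triangular elements of both matrices (the
#' diagonal is ignored) and returns their Pearson correlation.
#'
#' @param M_u,M_v symmetric matrices of identical shape, `n >= 3`.
#' @return numeric correlation in `[-1, 1]`, or `NA` with a warning when
#'   either upper-triangle vector is constant.
#' @export
matrix_similarity <- function(M_u, M_v) {
  check_square(M_u); check_square(M_v)
  stopifnot(identical(dim(M_u), dim(M_v)))
  if (nrow(M_u) < 3L)
    stop("need at least 3 cells (>= 3 off-diagonal pairs)", call. = FALSE)
  r <- safe_cor(upper_vec(M_u), upper_vec(M_v))
  if (is.na(r))
    warning("degenerate upper-triangle vector; similarity undefined",
            call. = FALSE)
  r
}

#' Mantel-style permutation z-score of matrix similarity
#'
#' The observed similarity [matrix_similarity()] is standardized against a
#' null in which the rows and columns of `M_u` are permuted by the same
#' random node permutation and the similarity with `M_v` recomputed. Note
#' the statistic is not symmetric in its arguments (only `M_u` is
#' permuted); [session_similarity()] reports both orderings.
#'
#' @param M_u,M_v symmetric matrices over the same cells.
#' @param n_perm number of permutations (>= 100, default 1000).
#' @return list with `z`, `r_obs`, `null_mean`, `null_sd`.
#' @export
mantel_z <- function(M_u, M_v, n_perm = 1000L) {
  n_perm <- check_count(n_perm, "n_perm", min = 100L)
  r_obs <- matrix_similarity(M_u, M_v)
  n <- nrow(M_u)
  v_v <- upper_vec(M_v)
  null_r <- vapply(seq_len(n_perm), function(b) {
    perm <- sample.int(n)
    safe_cor(upper_vec(M_u[perm, perm]), v_v)
  }, numeric(1L))
  null_sd <- sd(null_r, na.rm = TRUE)
  if (is.na(null_sd) || null_sd == 0) {
    warning("degenerate Mantel null (zero sd); z undefined", call. = FALSE)
    return(list(z = NA_real_, r_obs = r_obs,
                null_mean = mean(null_r, na.rm = TRUE), null_sd = null_sd))
  }
  list(z = (r_obs - mean(null_r, na.rm = TRUE)) / null_sd, r_obs = r_obs,
       null_mean = mean(null_r, na.rm = TRUE), null_sd = null_sd)
}

#' Pairwise session similarity table
#'
#' For every session pair, restricts the session matrices to shared cells,
#' computes the Pearson similarity of their upper triangles and the
#' Mantel-style permutation z-score in both orderings (permuting either
#' session's matrix), and records the day distance between the sessions.
#'
#' @param networks list of `correlation_network`s (supplies cell ids and day
#'   offsets; their `W` is used for `kind = "correlation"`).
#' @param kind `"correlation"` (jitter z-scored matrices `W`) or
#'   `"coassignment"` (module co-assignment matrices).
#' @param coassign for `kind = "coassignment"`: list of co-assignment
#'   matrices (or `coassignment_matrix` objects) parallel to `networks`;
#'   computed via [sample_partitions()] with `n_partitions` when `NULL`.
#' @param n_perm Mantel permutations per pair (default 1000).
#' @param min_shared minimum shared cells per pair (default 10).
#' @param n_partitions ensemble size when co-assignment matrices must be
#'   computed (analysis default 10000).
#' @param gamma_range resolution range for the ensemble.
#' @return A data.frame of class `session_pair_similarity` with columns
#'   `u`, `v`, `kind`, `n_shared`, `r`, `z_uv`, `z_vu`, `z` (mean of the
#'   two orderings) and `d` (day distance).
#' @export
session_similarity <- function(networks,
                               kind = c("correlation", "coassignment"),
                               coassign = NULL, n_perm = 1000L,
                               min_shared = 10L, n_partitions = 10000L,
                               gamma_range = c(0.5, 3)) {
  kind <- match.arg(kind)
  stopifnot(length(networks) >= 2L)
  days <- vapply(networks, `[[`, integer(1L), "day_offset")
  if (kind == "coassignment") {
    if (is.null(coassign)) {
      coassign <- lapply(networks, function(net) {
        C <- coassignment(sample_partitions(net$A, n_partitions,
                                            gamma_range))$C
        dimnames(C) <- list(net$cell_ids, net$cell_ids)
        C
      })
    }
    mats <- lapply(seq_along(networks), function(i) {
      M <- if (inherits(coassign[[i]], "coassignment_matrix"))
        coassign[[i]]$C else coassign[[i]]
      stopifnot(nrow(M) == length(networks[[i]]$cell_ids))
      dimnames(M) <- list(networks[[i]]$cell_ids, networks[[i]]$cell_ids)
      M
    })
  } else {
    mats <- lapply(networks, function(net) net$W)
    for (i in seq_along(mats))
      dimnames(mats[[i]]) <- list(networks[[i]]$cell_ids,
                                  networks[[i]]$cell_ids)
  }

  rows <- list()
  for (u in seq_len(length(networks) - 1L)) {
    for (v in (u + 1L):length(networks)) {
      sub <- shared_submatrices(mats[[u]], mats[[v]], min_shared)
      if (is.null(sub)) next
      r <- matrix_similarity(sub$M_u, sub$M_v)
      z_uv <- mantel_z(sub$M_u, sub$M_v, n_perm)$z
      z_vu <- mantel_z(sub$M_v, sub$M_u, n_perm)$z
      rows[[length(rows) + 1L]] <- data.frame(
        u = u, v = v, kind = kind, n_shared = length(sub$shared_ids),
        r = r, z_uv = z_uv, z_vu = z_vu, z = mean(c(z_uv, z_vu)),
        d = abs(days[u] - days[v]))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(u = integer(0), v = integer(0), kind = character(0),
               n_shared = integer(0), r = numeric(0), z_uv = numeric(0),
               z_vu = numeric(0), z = numeric(0), d = integer(0))
  class(out) <- c("session_pair_similarity", class(out))
  out
}

#' Decay of session similarity with day distance
#'
#' Pearson correlation of the per-pair Mantel z-scores against the day
#' distance separating the sessions; a negative value means sessions far
#' apart in time are less similar than sessions close in time.
#'
#' @param pairs a `session_pair_similarity` table (>= 3 usable pairs).
#' @return list of class `decay_result` with `r`, `n_pairs`, `pairs`.
#' @export
decay_analysis <- function(pairs) {
  ok <- is.finite(pairs$z) & is.finite(pairs$d)
  if (sum(ok) < 3L)
    stop("need at least 3 session pairs for the decay analysis",
         call. = FALSE)
  z <- pairs$z[ok]
  d <- pairs$d[ok]
  if (sd(z) == 0 || sd(d) == 0) {
    warning("constant z or d; decay correlation undefined", call. = FALSE)
    r <- NA_real_
  } else {
    r <- cor(z, d)
  }
  structure(list(r = r, n_pairs = sum(ok), pairs = pairs[ok, ]),
            class = "decay_result")
}

#' @export
print.decay_result <- function(x, ...) {
  cat(sprintf("<decay_result> r(z, day distance) = %.3f over %d pairs\n",
              x$r, x$n_pairs))
  invisible(x)
}

## Split hierarchy levels 1..L into three contiguous groups.
level_terciles <- function(L) {
  if (L < 3L) return(rep(1L, L))
  cut(seq_len(L), breaks = 3L, labels = FALSE)
}

#' Module-similarity decay by hierarchy tercile
#'
#' Splits each session's hierarchy levels into terciles (coarse, middle,
#' fine), recomputes co-assignment matrices from the levels within each
#' tercile, and runs the session-similarity decay analysis per tercile to
#' ask whether module stability depends on hierarchical depth.
#'
#' @param hierarchies list of `hierarchical_partition`s parallel to
#'   `networks`.
#' @param networks list of `correlation_network`s.
#' @param n_perm,min_shared passed to [session_similarity()].
#' @return list of class `tercile_similarity`: per-tercile `decay_result`s
#'   (`NULL` where no usable pairs exist).
#' @export
tercile_similarity <- function(hierarchies, networks, n_perm = 1000L,
                               min_shared = 10L) {
  stopifnot(length(hierarchies) == length(networks))
  depths <- vapply(hierarchies, `[[`, integer(1L), "n_levels")
  if (any(depths < 3L))
    warning("session(s) with fewer than 3 hierarchy levels: ",
            "terciles collapse", call. = FALSE)
  n_groups <- if (all(depths < 3L)) 1L else 3L
  out <- vector("list", n_groups)
  names(out) <- if (n_groups == 3L)
    c("coarse", "middle", "fine") else "all"
  for (t in seq_len(n_groups)) {
    coassign <- vector("list", length(networks))
    usable <- rep(FALSE, length(networks))
    for (i in seq_along(networks)) {
      L <- depths[i]
      if (L == 0L) next
      lev <- which(level_terciles(L) == t)
      if (length(lev) == 0L) next
      parts <- lapply(lev, function(l) hierarchies[[i]]$labels[l, ])
      coassign[[i]] <- coassignment(parts)$C
      usable[i] <- TRUE
    }
    if (sum(usable) < 2L) next
    tab <- session_similarity(networks[usable], kind = "coassignment",
                              coassign = coassign[usable], n_perm = n_perm,
                              min_shared = min_shared)
    out[[t]] <- tryCatch(decay_analysis(tab), error = function(e) NULL)
  }
  structure(out, class = "tercile_similarity")
}
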