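#' Configuration for a synthetic multi-session fluorescence study
#'
#' Describes the study design the generator emulates: several ~10-minute
#' spontaneous-activity recordings of the same field of view over days to
#' weeks, with cells tracked across sessions. Cells belong to hierarchically
#' nested activity modules that are spatially compact; module membership
#' drifts gradually from session to session for all cells except a small
#' stable core, and each cell can drop out of any session independently.
#'
#' @param n_cells number of tracked cells in the field of view.
#' @param n_sessions number of recording sessions.
#' @param day_offsets integer day of each session relative to the first
#'   (nondecreasing, length `n_sessions`).
#' @param n_frames frames per session (default 18000, ten minutes at 30 Hz).
#' @param sampling_rate_hz acquisition rate in frames per second.
#' @param hierarchy_branching module counts per hierarchy level, coarse to
#'   fine; `c(2, 2)` means two coarse modules each split into two.
#' @param signal_strength_per_level mixing weight in `[0, 1]` of each level's
#'   shared latent signal, coarse to fine (same length as
#'   `hierarchy_branching`).
#' @param noise_sd per-frame observation noise standard deviation, in the
#'   same arbitrary fluorescence units as the unit-variance latent signals.
#' @param core_fraction fraction of cells in the stable core that never
#'   changes module.
#' @param drift_prob_per_day probability per elapsed day that a non-core
#'   cell is reassigned to a random finest-level module.
#' @param dropout_prob probability that a cell is absent from a session.
#' @param spatial_module_sd within-module spatial scatter (micrometres).
#' @param fov_size_um field-of-view edge length (micrometres).
#' @param seed RNG seed used by [generate_study()].
#'
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_cells = 150L,
                         n_sessions = 5L,
                         day_offsets = c(0L, 3L, 7L, 10L, 14L),
                         n_frames = 18000L,
                         sampling_rate_hz = 30,
                         hierarchy_branching = c(2L, 2L),
                         signal_strength_per_level = c(0.55, 0.7),
                         noise_sd = 1,
                         core_fraction = 0.15,
                         drift_prob_per_day = 0.05,
                         dropout_prob = 0.1,
                         spatial_module_sd = 40,
                         fov_size_um = 500,
                         seed = 1L) {
  cfg <- list(
    n_cells = check_count(n_cells, "n_cells"),
    n_sessions = check_count(n_sessions, "n_sessions"),
    day_offsets = day_offsets,
    n_frames = check_count(n_frames, "n_frames", min = 3L),
    sampling_rate_hz = sampling_rate_hz,
    hierarchy_branching = hierarchy_branching,
    signal_strength_per_level = signal_strength_per_level,
    noise_sd = noise_sd,
    core_fraction = check_prob(core_fraction, "core_fraction"),
    drift_prob_per_day = check_prob(drift_prob_per_day, "drift_prob_per_day"),
    dropout_prob = check_prob(dropout_prob, "dropout_prob"),
    spatial_module_sd = spatial_module_sd,
    fov_size_um = fov_size_um,
    seed = check_count(seed, "seed", min = 0L)
  )
  if (length(cfg$day_offsets) != cfg$n_sessions)
    stop_field("day_offsets", "length must equal n_sessions")
  if (any(diff(cfg$day_offsets) < 0))
    stop_field("day_offsets", "must be nondecreasing")
  if (any(cfg$day_offsets != round(cfg$day_offsets)))
    stop_field("day_offsets", "must be integer days")
  cfg$day_offsets <- as.integer(cfg$day_offsets)
  if (!is.numeric(cfg$hierarchy_branching) ||
      length(cfg$hierarchy_branching) < 1L ||
      any(cfg$hierarchy_branching < 1) ||
      any(cfg$hierarchy_branching != round(cfg$hierarchy_branching)))
    stop_field("hierarchy_branching", "must be positive integers")
  cfg$hierarchy_branching <- as.integer(cfg$hierarchy_branching)
  if (prod(cfg$hierarchy_branching) > cfg$n_cells)
    stop_field("hierarchy_branching",
               "product of branching factors exceeds n_cells")
  if (length(cfg$signal_strength_per_level) !=
      length(cfg$hierarchy_branching))
    stop_field("signal_strength_per_level",
               "must have one weight per hierarchy level")
  if (any(cfg$signal_strength_per_level < 0) ||
      any(cfg$signal_strength_per_level > 1))
    stop_field("signal_strength_per_level", "weights must lie in [0, 1]")
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd < 0)
    stop_field("noise_sd", "must be a nonnegative number")
  if (!is.numeric(cfg$sampling_rate_hz) || cfg$sampling_rate_hz <= 0)
    stop_field("sampling_rate_hz", "must be positive")
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  %d cells, %d sessions on days [%s]\n", x$n_cells,
              x$n_sessions, paste(x$day_offsets, collapse = ", ")))
  cat(sprintf("  %d frames/session at %g Hz\n", x$n_frames,
              x$sampling_rate_hz))
  cat(sprintf("  hierarchy %s, signal weights %s, noise sd %g\n",
              paste(x$hierarchy_branching, collapse = "x"),
              paste(x$signal_strength_per_level, collapse = ", "),
              x$noise_sd))
  cat(sprintf("  core %g%%, drift %g/day, dropout %g\n",
              100 * x$core_fraction, x$drift_prob_per_day, x$dropout_prob))
  invisible(x)
}

## Ancestor label at level `level` of a finest-level module id, for a
## branching vector (coarse -> fine).
ancestor_label <- function(finest, level, branching) {
  below <- if (level < length(branching))
    prod(branching[(level + 1L):length(branching)]) else 1L
  as.integer((finest - 1L) %/% below + 1L)
}

## Low-pass latent signal: moving-average-smoothed Gaussian noise, scaled to
## unit sd.  White-noise latents would lose all cross-cell correlation under
## differencing of the observed traces; a ~0.5 s window keeps the differenced
## series correlated.
smooth_latent <- function(n_frames, window) {
  z <- rnorm(n_frames)
  if (window > 1L)
    z <- as.numeric(stats::filter(z, rep(1 / window, window),
                                  sides = 2L, circular = TRUE))
  z / sd(z)
}

#' Generate a synthetic multi-session fluorescence study
#'
#' Simulates tracked-cell fluorescence traces with planted hierarchical
#' module structure: each cell's trace is a weighted sum of its modules'
#' latent signals (one independent smooth signal per module per session,
#' at each hierarchy level) plus white observation noise. Non-core cells
#' drift to random finest-level modules between sessions at a rate set by
#' the elapsed days; core cells never move. Cell positions are drawn once
#' around module-specific spatial centers and are identical in every session
#' (cells are tracked). Dropout removes cells from individual sessions but
#' the generator guarantees every session pair shares at least 10 cells.
#'
#' @param config a [synth_config()] object.
#' @param seed RNG seed; defaults to `config$seed`. The output is
#'   bit-reproducible given `(config, seed)`.
#' @return A list of class `synthetic_study` with elements `sessions` (list
#'   of `fluorescence_session`), `ground_truth` (per-session label matrices,
#'   core mask, presence matrix, latent signals) and `config`.
#' @export
generate_study <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_cells
  S <- config$n_sessions
  L <- length(config$hierarchy_branching)
  M <- prod(config$hierarchy_branching)
  cell_ids <- sprintf("cell_%04d", seq_len(n))

  ## global structure: core, initial labels, positions, dropout
  set.seed(sub_seed(seed, 0L))
  finest <- sample(rep_len(seq_len(M), n))

  ## Core cells must have *stable coupling*: scattered singletons would have
  ## no persistent partners, so the core fills finest modules in order,
  ## forming one or more persistent ensembles.
  n_core <- round(config$core_fraction * n)
  core_mask <- rep(FALSE, n)
  core_mask[order(finest)[seq_len(n_core)]] <- TRUE
  names(core_mask) <- cell_ids
  centers <- matrix(runif(2L * M, 0, config$fov_size_um), ncol = 2L)
  positions <- centers[finest, , drop = FALSE] +
    matrix(rnorm(2L * n, sd = config$spatial_module_sd), ncol = 2L)
  dimnames(positions) <- list(cell_ids, c("x_um", "y_um"))

  presence <- draw_presence(n, S, config$dropout_prob)
  rownames(presence) <- cell_ids

  ## per-session label evolution (Markov over sessions, non-core only)
  labels_finest <- matrix(NA_integer_, n, S)
  labels_finest[, 1L] <- finest
  if (S > 1L) {
    parent_keep_prob <- 0.8
    sibs <- config$hierarchy_branching[L]
    for (s in 2L:S) {
      set.seed(sub_seed(seed, 1000L + s))
      gap <- config$day_offsets[s] - config$day_offsets[s - 1L]
      p_drift <- min(1, config$drift_prob_per_day * gap)
      cur <- labels_finest[, s - 1L]
      move <- !core_mask & runif(n) < p_drift
      if (any(move)) {
        keep_parent <- runif(sum(move)) < parent_keep_prob & L > 1L
        idx <- which(move)
        new <- integer(length(idx))
        for (k in seq_along(idx)) {
          if (keep_parent[k]) {
            parent <- ancestor_label(cur[idx[k]], L - 1L,
                                     config$hierarchy_branching)
            pool <- (parent - 1L) * sibs + seq_len(sibs)
          } else {
            pool <- seq_len(M)
          }
          new[k] <- pool[sample.int(length(pool), 1L)]
        }
        cur[idx] <- new
      }
      labels_finest[, s] <- cur
    }
  }

  ## ground-truth label matrices: level x cell, coarse -> fine
  labels <- lapply(seq_len(S), function(s) {
    out <- vapply(seq_len(L), function(l)
      ancestor_label(labels_finest[, s], l, config$hierarchy_branching),
      integer(n))
    t(matrix(out, nrow = n, dimnames = list(cell_ids, NULL)))
  })

  ## traces: sum of per-level latent module signals plus noise
  window <- max(1L, round(0.5 * config$sampling_rate_hz))
  sessions <- vector("list", S)
  latents <- vector("list", S)
  for (s in seq_len(S)) {
    set.seed(sub_seed(seed, 2000L + s))
    lat <- lapply(seq_len(L), function(l) {
      n_mod <- prod(config$hierarchy_branching[seq_len(l)])
      vapply(seq_len(n_mod), function(m)
        smooth_latent(config$n_frames, window), numeric(config$n_frames))
    })
    latents[[s]] <- lat
    traces <- matrix(0, n, config$n_frames)
    for (l in seq_len(L)) {
      w <- config$signal_strength_per_level[l]
      if (w > 0) traces <- traces + w * t(lat[[l]])[labels[[s]][l, ], ,
                                                   drop = FALSE]
    }
    traces <- traces +
      matrix(rnorm(n * config$n_frames, sd = config$noise_sd), n)
    rownames(traces) <- cell_ids
    keep <- presence[, s]
    sessions[[s]] <- new_fluorescence_session(
      session_id = sprintf("session_%02d", s),
      day_offset = config$day_offsets[s],
      cell_ids = cell_ids[keep],
      positions = positions[keep, , drop = FALSE],
      traces = traces[keep, , drop = FALSE]
    )
  }

  structure(list(
    sessions = sessions,
    ground_truth = list(labels = labels, core_mask = core_mask,
                        presence = presence, latents = latents,
                        positions = positions),
    config = config
  ), class = "synthetic_study")
}

## Dropout with the shared-cell guarantee: redraw whole presence patterns
## until every session pair shares >= 10 cells (up to 100 attempts).
draw_presence <- function(n, S, dropout_prob, min_shared = 10L,
                          max_attempts = 100L) {
  for (attempt in seq_len(max_attempts)) {
    presence <- matrix(runif(n * S) >= dropout_prob, n, S)
    if (S == 1L) {
      if (sum(presence) >= min_shared) return(presence)
      next
    }
    shared <- crossprod(presence)
    if (min(shared[upper.tri(shared)]) >= min_shared) return(presence)
  }
  stop("generation error: could not draw a dropout pattern with at least ",
       min_shared, " shared cells per session pair in ", max_attempts,
       " attempts", call. = FALSE)
}

new_fluorescence_session <- function(session_id, day_offset, cell_ids,
                                     positions, traces) {
  stopifnot(nrow(traces) == length(cell_ids),
            nrow(positions) == length(cell_ids),
            ncol(traces) >= 3L,
            !anyDuplicated(cell_ids))
  structure(list(session_id = session_id,
                 day_offset = as.integer(day_offset),
                 cell_ids = cell_ids,
                 positions = positions,
                 traces = traces),
            class = "fluorescence_session")
}

#' @export
print.fluorescence_session <- function(x, ...) {
  cat(sprintf("<fluorescence_session> %s (day %d): %d cells x %d frames\n",
              x$session_id, x$day_offset, length(x$cell_ids),
              ncol(x$traces)))
  invisible(x)
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d sessions, %d cells, hierarchy %s\n",
              length(x$sessions), x$config$n_cells,
              paste(x$config$hierarchy_branching, collapse = "x")))
  for (s in x$sessions) print(s)
  invisible(x)
}

#' Summarize a multi-session study
#'
#' @param sessions a `synthetic_study` or a list of `fluorescence_session`s.
#' @return A list of class `study_summary`: per-session cell counts, the
#'   session-pair shared-cell count matrix, and the day-gap matrix.
#' @export
summarize_study <- function(sessions) {
  if (inherits(sessions, "synthetic_study")) sessions <- sessions$sessions
  stopifnot(length(sessions) >= 1L)
  ids <- lapply(sessions, `[[`, "cell_ids")
  days <- vapply(sessions, `[[`, integer(1L), "day_offset")
  S <- length(sessions)
  shared <- matrix(NA_integer_, S, S)
  for (u in seq_len(S))
    for (v in seq_len(S))
      shared[u, v] <- length(intersect(ids[[u]], ids[[v]]))
  session_names <- vapply(sessions, `[[`, character(1L), "session_id")
  dimnames(shared) <- list(session_names, session_names)
  gaps <- abs(outer(days, days, "-"))
  dimnames(gaps) <- dimnames(shared)
  structure(list(
    cells = data.frame(session_id = session_names, day_offset = days,
                       n_cells = lengths(ids)),
    shared = shared,
    day_gap = gaps
  ), class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat("Study summary\n")
  print(x$cells, row.names = FALSE)
  cat("shared cells per session pair:\n")
  print(x$shared)
  invisible(x)
}
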