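## Shared scaled-down study designs.  The defaults of synth_config describe
## a full-scale study (18000 frames); tests use shorter recordings with a
## proportionally stronger signal contrast so the planted structure remains
## detectable at desk scale.

## Two-level hierarchy with strong fine modules and near-threshold coarse
## coupling (so the binary adjacency carries a two-level density contrast).
hier_config <- function(seed, n_cells = 60L, n_sessions = 1L,
                        day_offsets = 0L, drift = 0.05, dropout = 0) {
  synth_config(n_cells = n_cells, n_sessions = n_sessions,
               day_offsets = day_offsets, n_frames = 900L,
               noise_sd = 0.4, signal_strength_per_level = c(0.45, 0.8),
               core_fraction = 0.15, drift_prob_per_day = drift,
               dropout_prob = dropout, seed = seed)
}

## Five-session longitudinal design used for the similarity-decay analyses:
## moderate drift, realistic dropout.
drift_config <- function(seed, n_cells = 100L, drift = 0.05) {
  synth_config(n_cells = n_cells, n_sessions = 5L,
               day_offsets = c(0L, 3L, 7L, 10L, 14L), n_frames = 900L,
               noise_sd = 0.4, signal_strength_per_level = c(0.45, 0.8),
               core_fraction = 0.2, drift_prob_per_day = drift,
               dropout_prob = 0.1, seed = seed)
}

## Core-recovery design: a planted 20% core with persistent mutual coupling,
## weak coarse background (so periphery consistency stays low), strong
## periphery drift, and low dropout (so the core survives the all-session
## intersection).
core_config <- function(seed, n_cells = 100L, drift = 0.15) {
  synth_config(n_cells = n_cells, n_sessions = 5L,
               day_offsets = c(0L, 3L, 7L, 10L, 14L), n_frames = 900L,
               noise_sd = 0.4, signal_strength_per_level = c(0.3, 0.8),
               core_fraction = 0.2, drift_prob_per_day = drift,
               dropout_prob = 0.05, seed = seed)
}

## Overlap of the selected top-coreness set with the planted core, relative
## to what the all-session node set makes achievable.
core_overlap <- function(fit, truth_ids, ml, top_frac = 0.2) {
  top <- top_core_ids(fit, top_frac)
  avail <- sum(ml$node_ids %in% truth_ids)
  sum(top %in% truth_ids) / min(length(top), avail)
}

## Label-only studies (minimal frames) for tests that never touch traces.
label_config <- function(seed, ...) {
  args <- list(...)
  defaults <- list(n_cells = 80L, n_sessions = 5L,
                   day_offsets = c(0L, 3L, 7L, 10L, 14L), n_frames = 30L,
                   dropout_prob = 0, seed = seed)
  defaults[names(args)] <- args
  do.call(synth_config, defaults)
}

## Small toy multilayer object built directly from adjacency matrices.
toy_multilayer <- function(layers, days = seq_along(layers)) {
  n <- nrow(layers[[1L]])
  ids <- sprintf("cell_%04d", seq_len(n))
  nets <- lapply(seq_along(layers), function(u) {
    A <- layers[[u]]
    dimnames(A) <- list(ids, ids)
    structure(list(session_id = sprintf("session_%02d", u),
                   day_offset = as.integer(days[u]), cell_ids = ids,
                   A = A, W = A, alpha = 0.05, n_jitter = 100L),
              class = "correlation_network")
  })
  build_multilayer(nets, max_layers = length(layers))
}
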