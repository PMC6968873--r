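#' Write a study to delimited text files
#'
#' Writes one tab-separated trace matrix per session
#' (`traces_<session_id>.tsv`, cells x frames with cell ids as row names),
#' a cell-metadata table (`cell_metadata.tsv`: cell_id, session_id,
#' day_offset, x_um, y_um) and, for synthetic studies, the ground-truth
#' label table (`ground_truth_labels.tsv`: session_id, cell_id, level,
#' module_id) and core mask (`ground_truth_core.tsv`).
#'
#' @param study a `synthetic_study` or list of `fluorescence_session`s.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  truth <- NULL
  if (inherits(study, "synthetic_study")) {
    truth <- study$ground_truth
    sessions <- study$sessions
  } else {
    sessions <- study
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list()
  for (s in sessions) {
    write.table(s$traces,
                file.path(dir, paste0("traces_", s$session_id, ".tsv")),
                sep = "\t", quote = FALSE, col.names = FALSE)
    meta[[length(meta) + 1L]] <- data.frame(
      cell_id = s$cell_ids, session_id = s$session_id,
      day_offset = s$day_offset, x_um = s$positions[, 1L],
      y_um = s$positions[, 2L])
  }
  write.table(do.call(rbind, meta), file.path(dir, "cell_metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) {
    lab <- list()
    for (i in seq_along(truth$labels)) {
      m <- truth$labels[[i]]
      lab[[i]] <- data.frame(
        session_id = sessions[[i]]$session_id,
        cell_id = rep(colnames(m), each = nrow(m)),
        level = rep(seq_len(nrow(m)), times = ncol(m)),
        module_id = as.vector(m))
    }
    write.table(do.call(rbind, lab),
                file.path(dir, "ground_truth_labels.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(cell_id = names(truth$core_mask),
                           core = truth$core_mask),
                file.path(dir, "ground_truth_core.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a study written by [write_study()]
#'
#' @param dir directory containing the delimited files.
#' @return list of `fluorescence_session`s.
#' @export
read_study <- function(dir) {
  meta <- read.table(file.path(dir, "cell_metadata.tsv"), sep = "\t",
                     header = TRUE, stringsAsFactors = FALSE)
  sessions <- list()
  for (sid in unique(meta$session_id)) {
    m <- meta[meta$session_id == sid, ]
    traces <- as.matrix(read.table(
      file.path(dir, paste0("traces_", sid, ".tsv")), sep = "\t",
      row.names = 1L))
    colnames(traces) <- NULL
    traces <- traces[m$cell_id, , drop = FALSE]
    pos <- as.matrix(m[, c("x_um", "y_um")])
    rownames(pos) <- m$cell_id
    sessions[[length(sessions) + 1L]] <- new_fluorescence_session(
      session_id = sid, day_offset = m$day_offset[1L],
      cell_ids = m$cell_id, positions = pos, traces = traces)
  }
  sessions
}

#' Write a symmetric cell matrix as delimited text
#'
#' Square matrix with a cell-id header row and column, e.g. for the `W`,
#' `P` or `A` matrices of a network, or a co-assignment matrix.
#'
#' @param M matrix with cell ids as dimnames.
#' @param file output path.
#' @export
write_cell_matrix <- function(M, file) {
  write.table(M, file, sep = "\t", quote = FALSE, col.names = NA)
  invisible(file)
}

#' Read a matrix written by [write_cell_matrix()]
#'
#' @param file path.
#' @return matrix with cell-id dimnames.
#' @export
read_cell_matrix <- function(file) {
  as.matrix(read.table(file, sep = "\t", header = TRUE, row.names = 1L,
                       check.names = FALSE))
}
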