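#' Plain-text input and output
#'
#' All on-disk formats are delimited text: signal matrices are written
#' samples-by-channels with a header row of channel labels, events and
#' participant metadata as TSV, ground truth and epoch metadata as JSON.
#'
#' @name io
NULL

#' Write / read a continuous multichannel recording
#'
#' @param recording A [eeg_recording()].
#' @param path Path of the signal TSV (samples x channels, header = labels).
#' @param events_path Path of the events TSV (`sample_index`, `pulse_type`,
#'   `site`); defaults to `<path>` with an `_events.tsv` suffix.
#' @return `write_recording()` returns the paths invisibly; `read_recording()`
#'   returns a `tep_recording`.
#' @export
write_recording <- function(recording, path, events_path = NULL) {
  stopifnot(inherits(recording, "tep_recording"))
  if (is.null(events_path)) events_path <- sub("\\.tsv$", "_events.tsv", path)
  sig <- tibble::as_tibble(t(recording$data), .name_repair = "minimal")
  names(sig) <- recording$labels
  readr::write_tsv(sig, path)
  readr::write_tsv(recording$events, events_path)
  invisible(c(path, events_path))
}

#' @rdname write_recording
#' @param fs Sampling rate in Hz (not stored in the TSV).
#' @export
read_recording <- function(path, fs, events_path = NULL) {
  if (is.null(events_path)) events_path <- sub("\\.tsv$", "_events.tsv", path)
  sig <- readr::read_tsv(path, show_col_types = FALSE)
  events <- NULL
  if (file.exists(events_path)) {
    events <- readr::read_tsv(events_path, show_col_types = FALSE)
  }
  eeg_recording(t(as.matrix(sig)), fs = fs, events = events,
                labels = names(sig))
}

#' Write / read an epoch set as TSV plus JSON sidecar
#'
#' The data file holds one row per (epoch, sample) with channel columns; the
#' sidecar records sampling rate, window, condition and the kept mask.
#'
#' @param epochs A `tep_epochs`.
#' @param path_prefix Files are written as `<path_prefix>.tsv` and
#'   `<path_prefix>.json`.
#' @return `write_epochs()` returns the paths invisibly; `read_epochs()`
#'   returns the `tep_epochs`.
#' @export
write_epochs <- function(epochs, path_prefix) {
  stopifnot(inherits(epochs, "tep_epochs"))
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = d[1] * d[3], ncol = d[2])
  df <- tibble::as_tibble(flat, .name_repair = "minimal")
  names(df) <- epochs$labels
  df <- dplyr::bind_cols(
    tibble::tibble(epoch = rep(seq_len(d[1]), each = d[3]),
                   sample = rep(seq_len(d[3]), times = d[1])),
    df
  )
  data_path <- paste0(path_prefix, ".tsv")
  meta_path <- paste0(path_prefix, ".json")
  readr::write_tsv(df, data_path)
  jsonlite::write_json(
    list(fs = epochs$fs, window_ms = epochs$window_ms,
         site = epochs$condition$site, pulse = epochs$condition$pulse,
         labels = epochs$labels, kept_mask = epochs$kept_mask),
    meta_path, auto_unbox = TRUE, digits = NA
  )
  invisible(c(data_path, meta_path))
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path_prefix) {
  df <- readr::read_tsv(paste0(path_prefix, ".tsv"), show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(path_prefix, ".json"), simplifyVector = TRUE)
  labels <- meta$labels
  n_ep <- max(df$epoch)
  n_t <- max(df$sample)
  arr <- array(0, dim = c(n_ep, length(labels), n_t))
  m <- as.matrix(df[, labels])
  for (ep in seq_len(n_ep)) {
    arr[ep, , ] <- t(m[df$epoch == ep, , drop = FALSE])
  }
  epoch_set(arr, fs = meta$fs, window_ms = meta$window_ms, site = meta$site,
            pulse = meta$pulse, labels = labels,
            kept_mask = as.logical(meta$kept_mask))
}

#' Write a raw synthetic cohort to a directory
#'
#' Writes one epoch-set TSV/JSON pair per participant x condition
#' (`<id>_<side>_<pulse>`), a `participants.tsv` (id, group, SADQ, BDI,
#' OCDS) and a `ground_truth.json` with the planted coupling network and
#' group effect.
#'
#' @param cohort The list returned by [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(cohort$participants, file.path(dir, "participants.tsv"))
  for (i in seq_len(nrow(cohort$epochs))) {
    row <- cohort$epochs[i, ]
    prefix <- file.path(dir, paste(row$participant, row$side, row$pulse, sep = "_"))
    write_epochs(row$epochs[[1]], prefix)
  }
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(coupling = gt$coupling, true_group_effect = gt$true_group_effect,
         coherence = gt$coherence),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_participants <- function(dir) {
  readr::read_tsv(file.path(dir, "participants.tsv"), show_col_types = FALSE)
}

#' Write a connectivity result as two TSV matrices
#'
#' @param conn A `tep_connectivity`.
#' @param weights_path,lags_path Output paths for the weight and lag matrices.
#' @return The paths, invisibly.
#' @export
write_connectivity <- function(conn, weights_path, lags_path) {
  stopifnot(inherits(conn, "tep_connectivity"))
  wm <- conn$weights
  lm <- conn$lags_ms
  colnames(wm) <- colnames(lm) <- conn$labels
  w <- tibble::as_tibble(wm, .name_repair = "minimal")
  l <- tibble::as_tibble(lm, .name_repair = "minimal")
  readr::write_tsv(w, weights_path)
  readr::write_tsv(l, lags_path)
  invisible(c(weights_path, lags_path))
}

#' Export a thresholded graph
#'
#' `write_edge_list()` writes the weighted directed edge list (`src`, `dst`,
#' `weight`, `lag_ms`); `write_graphml()` exports GraphML via igraph with
#' `weight` and `lag_ms` edge attributes.
#'
#' @param graph A `tep_graph`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  readr::write_tsv(graph_edges(graph), path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(graph, path) {
  ig <- as_igraph(graph)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Convert a thresholded graph to an igraph object
#'
#' @param graph A `tep_graph`.
#' @return A directed `igraph` graph with `weight` and `lag_ms` edge
#'   attributes.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "tep_graph"))
  edges <- graph_edges(graph)
  igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = graph$labels)
  )
}
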