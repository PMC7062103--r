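# Tabular and graph I/O: landscape tables, equilibrium snapshots, run
# manifests and hypercube graph exports.

#' Write a landscape pair as a delimited text table
#'
#' Columns: `state_index`, `bitstring`, `F0`, `F1`, `incompatible` (0/1), with
#' a header line. Fitness values are the thresholded per-state values used by
#' the dynamics.
#'
#' @param pair A [landscape_pair()].
#' @param path Output file; a `.tsv` extension writes tab-separated values,
#'   anything else comma-separated.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(pair, path) {
  tab <- tidy(pair)
  if (grepl("\\.tsv$", path)) {
    readr::write_tsv(tab, path)
  } else {
    readr::write_csv(tab, path)
  }
  invisible(path)
}

#' Read a landscape pair from a delimited text table
#'
#' Expects the format written by [write_landscape()]. User-supplied fitness
#' tables are rescaled by their joint maximum (see
#' [landscape_pair_from_tables()]); the stored `incompatible` column defines
#' the frozen incompatible set, overriding any threshold rule.
#'
#' @param path Input file (CSV, or TSV with a `.tsv` extension).
#' @param rescale Rescale both fitness columns by their joint maximum.
#' @return A `landscape_pair`.
#' @export
read_landscape <- function(path, rescale = TRUE) {
  tab <- if (grepl("\\.tsv$", path)) {
    readr::read_tsv(path, show_col_types = FALSE)
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
  needed <- c("state_index", "bitstring", "F0", "F1", "incompatible")
  if (!all(needed %in% names(tab))) {
    stop("Landscape file must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  tab <- tab[order(tab$state_index), ]
  inc <- tab$incompatible > 0
  pair <- landscape_pair_from_tables(tab$F0, tab$F1, rescale = rescale)
  # the stored flags define the frozen incompatible set; endpoint fitness on
  # that set is irrelevant because interpolation pins it to zero
  pair$incompatible <- inc
  pair$viable <- which(!inc) - 1L
  pair
}

#' Write an equilibrium snapshot as CSV
#'
#' @param x Population fractions over all states.
#' @param fitness Per-state fitness at the current tau.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_equilibrium <- function(x, fitness, path) {
  n <- round(log2(length(x)))
  readr::write_csv(tibble::tibble(
    state_index = 0:(2^n - 1L),
    bitstring = state_bitstring(0:(2^n - 1L), n),
    fitness_at_tau = fitness,
    x = x
  ), path)
  invisible(path)
}

#' Write the similarity curves of a sweep as CSV
#'
#' @param sweep A `culture_sweep`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_similarity_curves <- function(sweep, path) {
  readr::write_csv(
    sweep$curves[, c("tau", "sim_to_initial", "sim_step",
                     "landscape_sim_step")],
    path
  )
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records the configuration, seeds and convergence diagnostics of a run so
#' results are reproducible from the manifest alone.
#'
#' @param sweep A `culture_sweep`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(sweep, path) {
  manifest <- list(
    n = sweep$n,
    direction = sweep$direction,
    eps = sweep$eps,
    pair_seed = sweep$pair_seed,
    f_th = sweep$f_th,
    params = unclass(sweep$params),
    settings = unclass(sweep$settings),
    jump_threshold = sweep$jump_threshold,
    n_jumps = nrow(sweep$jumps),
    max_residual = max(sweep$curves$residual),
    total_integration_time = sum(sweep$curves$time)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export the trait hypercube as a graph with node attributes
#'
#' Builds the Hamming graph of the state space (nodes are cultural states,
#' edges join states differing in one trait) with per-node fitness and,
#' optionally, population fraction, and writes it as GraphML or an edge list.
#'
#' @param fitness Per-state fitness vector (e.g. from
#'   [interpolate_fitness()]).
#' @param path Output path.
#' @param x Optional population fractions to attach as a node attribute.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
export_hypercube_graph <- function(fitness, path, x = NULL,
                                   format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  n <- round(log2(length(fitness)))
  edges <- hypercube_edges(n)
  g <- igraph::graph_from_data_frame(
    edges,
    directed = FALSE,
    vertices = data.frame(
      name = 0:(2^n - 1L),
      bitstring = state_bitstring(0:(2^n - 1L), n),
      fitness = fitness,
      x = if (is.null(x)) NA_real_ else x
    )
  )
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
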