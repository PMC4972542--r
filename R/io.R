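#' Serialize an odor panel to JSON
#'
#' Matrices are written row-wise (one array per odor); pixel order is
#' row-major over the grid. [read_odor_panel()] restores a bit-identical
#' panel object.
#'
#' @param panel An `odor_panel`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_odor_panel <- function(panel, path) {
  stopifnot(inherits(panel, "odor_panel"))
  obj <- list(
    grid = list(n_rows = panel$grid$n_rows, n_cols = panel$grid$n_cols),
    concentration = panel$concentration,
    n_odors = panel$n_odors,
    seed = panel$seed,
    pixel_state = panel$pixel_state,
    thresholds = panel$thresholds,
    base_intensity = panel$base_intensity,
    change_flags = panel$change_flags
  )
  # 17 significant digits: doubles survive the round trip bit-identically
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_odor_panel
#' @export
read_odor_panel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- grid_spec(obj$grid$n_rows, obj$grid$n_cols)
  as_num <- function(m) matrix(as.numeric(m), nrow(m), ncol(m))
  structure(list(
    grid = g,
    concentration = obj$concentration,
    n_odors = as.integer(obj$n_odors),
    pixel_state = matrix(as.character(obj$pixel_state),
                         nrow(obj$pixel_state), ncol(obj$pixel_state)),
    thresholds = as_num(obj$thresholds),
    base_intensity = as_num(obj$base_intensity),
    change_flags = matrix(as.logical(obj$change_flags),
                          nrow(obj$change_flags), ncol(obj$change_flags)),
    seed = as.integer(obj$seed)
  ), class = "odor_panel")
}

#' Write trial intensity (or rate) matrices as delimited tables
#'
#' One row per trial, one column per pixel/unit (row-major grid order),
#' preceded by the odor label column.
#'
#' @param x Pixels/units x trials matrix (as produced by [sample_trials()]
#'   or `simulate_trials()$rates`).
#' @param labels Odor label per trial.
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_trials <- function(x, labels, path) {
  stopifnot(is.matrix(x), ncol(x) == length(labels))
  d <- data.frame(odor = labels, t(x), check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  list(labels = d$odor,
       intensities = t(as.matrix(d[, -1, drop = FALSE])))
}

#' Write a sweep's accuracy table and resolved specification
#'
#' The accuracy table goes to `<prefix>_accuracy.csv`, the per-cell summary
#' to `<prefix>_summary.csv`, and the fully-resolved sweep specification to
#' `<prefix>_spec.json`.
#'
#' @param result A `sweep_result`.
#' @param prefix Output path prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_sweep_result <- function(result, prefix) {
  stopifnot(inherits(result, "sweep_result"))
  files <- paste0(prefix, c("_accuracy.csv", "_summary.csv", "_spec.json"))
  utils::write.csv(as.data.frame(result), files[1], row.names = FALSE)
  utils::write.csv(summary(result), files[2], row.names = FALSE)
  spec <- attr(result, "spec")
  jsonlite::write_json(unclass(spec), files[3], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(files)
}

#' Read and write voltage-clamp trace records as delimited tables
#'
#' CSV layout: a `#`-prefixed header line carrying `sample_rate`,
#' `stim_time` and `holding`, then one `time` column (s) and one column per
#' trial (pA).
#'
#' @param trace A [trace_record()].
#' @param path File path.
#' @return `path` (writer) or a [trace_record()] (reader).
#' @export
write_trace_record <- function(trace, path) {
  stopifnot(inherits(trace, "trace_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate=%.10g stim_time=%.10g holding=%.10g",
                     trace$sample_rate, trace$stim_time, trace$holding), con)
  d <- data.frame(time = (seq_len(nrow(trace$samples)) - 1L) /
                    trace$sample_rate,
                  trace$samples)
  names(d) <- c("time", sprintf("trial%d", seq_len(ncol(trace$samples))))
  utils::write.csv(d, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_record
#' @export
read_trace_record <- function(path) {
  hdr <- readLines(path, n = 1L)
  get_field <- function(name) {
    as.numeric(sub(sprintf(".*%s=([-0-9.eE+]+).*", name), "\\1", hdr))
  }
  d <- utils::read.csv(path, comment.char = "#")
  trace_record(as.matrix(d[, -1, drop = FALSE]),
               sample_rate = get_field("sample_rate"),
               stim_time = get_field("stim_time"),
               holding = get_field("holding"))
}

#' Read gemmule profiles from a delimited table
#'
#' Expects columns `cell_id` and `depth` (recording units along the
#' MCL-to-GL axis); all cells share one layer geometry.
#'
#' @param path CSV file.
#' @param layer_bounds Length-4 increasing numeric passed to
#'   [normalize_profile()].
#' @param n_bins Histogram bins.
#' @return List of `gemmule_profile` objects, one per cell, in order of
#'   first appearance.
#' @export
read_gemmule_profiles <- function(path, layer_bounds, n_bins = 20L) {
  d <- utils::read.csv(path)
  stopifnot(all(c("cell_id", "depth") %in% names(d)))
  ids <- unique(d$cell_id)
  lapply(ids, function(id) {
    normalize_profile(d$depth[d$cell_id == id], layer_bounds,
                      cell_id = id, n_bins = n_bins)
  })
}

#' Write clustering labels as a delimited table
#'
#' @param result A `cluster_result`.
#' @param path Output CSV.
#' @param cell_ids Optional identifiers (defaults to the tree's labels).
#' @return `path`, invisibly.
#' @export
write_cluster_labels <- function(result, path, cell_ids = NULL) {
  stopifnot(inherits(result, "cluster_result"))
  if (is.null(cell_ids)) cell_ids <- result$tree$labels
  if (is.null(cell_ids)) cell_ids <- seq_along(result$labels)
  utils::write.csv(data.frame(cell_id = cell_ids, cluster = result$labels),
                   path, row.names = FALSE)
  invisible(path)
}
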