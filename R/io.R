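#' Read and write centroid tables
#'
#' Centroid tables are tab-delimited text with a header row and
#' columns `sample_id`, `x_px`, `y_px` — one row per detected
#' ommatidium.
#'
#' @param path file path.
#' @return `read_centroids()` returns a data frame with those columns.
#' @export
read_centroids <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "x_px", "y_px")
  if (!all(need %in% names(d)))
    stop("centroid table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  d
}

#' @rdname read_centroids
#' @param centroids data frame with columns `sample_id`, `x_px`,
#'   `y_px` (a `make_hex_lattice()` result is converted, taking its
#'   `id` as a single sample).
#' @param sample_id sample label used when converting a bare lattice.
#' @export
write_centroids <- function(centroids, path, sample_id = "sample1") {
  if (!"sample_id" %in% names(centroids))
    centroids <- data.frame(sample_id = sample_id,
                            x_px = centroids$x, y_px = centroids$y)
  write.table(centroids[, c("sample_id", "x_px", "y_px")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write per-cell eye-disk tables
#'
#' Cell tables are tab-delimited text with a header row and columns
#' `disk_id`, `cell_type`, `x_px`, `y_px`, `reporter_mean`,
#' `reference_mean` (optionally `treatment`) — the contract of the
#' upstream segmentation export.
#'
#' @param path file path.
#' @return `read_cell_table()` returns the data frame.
#' @export
read_cell_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("disk_id", "cell_type", "x_px", "y_px", "reporter_mean",
            "reference_mean")
  if (!all(need %in% names(d)))
    stop("cell table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  d
}

#' @rdname read_cell_table
#' @param cells the per-cell data frame.
#' @export
write_cell_table <- function(cells, path) {
  write.table(cells, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a trajectory ensemble to delimited text
#'
#' One row per grid time per trajectory (`trajectory_id`, `t`, then
#' one column per retained species), plus a JSON metadata sidecar
#' (`<path>.json`) holding the parameters, seeds and variant.
#'
#' @param ensemble a `trajectory_ensemble`.
#' @param path output file path (tab-delimited).
#' @return The path, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  sp <- intersect(c("D", "R", "P"), names(ensemble))
  long <- data.frame(
    trajectory_id = rep(seq_len(ensemble$n), each = length(ensemble$grid)),
    t = rep(ensemble$grid, times = ensemble$n))
  for (s in sp) long[[s]] <- as.vector(t(ensemble[[s]]))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(variant = ensemble$variant,
               params = unclass(ensemble$params),
               input = unclass(ensemble$input),
               n = ensemble$n, seed = ensemble$seed,
               horizon = ensemble$horizon,
               grid_n = length(ensemble$grid),
               package_version =
                 as.character(utils::packageVersion("flypulse")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
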