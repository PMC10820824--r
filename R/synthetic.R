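#' Synthetic hexagonal ommatidium lattice
#'
#' Generates centroids of a triangular (hexagonally packed) lattice —
#' the idealized ommatidial array — then optionally degrades it with
#' isotropic Gaussian positional jitter, random point deletions and
#' near-duplicate insertions, emulating segmentation output from real
#' compound-eye images.  The ground truth of every modification is
#' recorded in attributes.
#'
#' @param rows,cols lattice extent.
#' @param spacing nearest-neighbor spacing in pixels.
#' @param jitter_sd standard deviation of the positional jitter, as a
#'   fraction of the spacing.
#' @param deletion_p per-point deletion probability.
#' @param duplication_p per-point probability of inserting a
#'   near-duplicate (offset by 10% of the spacing).
#' @param seed integer RNG seed.
#' @return Data frame with columns `id`, `x`, `y`; attributes
#'   `spec` (the generator settings) and `truth` (deleted ids,
#'   duplicated ids, jitter draws).  An empty result (everything
#'   deleted) carries attribute `empty = TRUE` and a warning.
#' @export
make_hex_lattice <- function(rows = 20L, cols = 20L, spacing = 20,
                             jitter_sd = 0, deletion_p = 0,
                             duplication_p = 0, seed = 1L) {
  stopifnot(spacing > 0, jitter_sd >= 0,
            deletion_p >= 0, deletion_p <= 1,
            duplication_p >= 0, duplication_p <= 1)
  set.seed(seed)
  base <- do.call(rbind, lapply(seq_len(rows), function(r)
    cbind(x = (seq_len(cols) - 1L) * spacing + (r %% 2L) * spacing / 2,
          y = (r - 1L) * spacing * sqrt(3) / 2)))
  n <- nrow(base)
  jit <- matrix(rnorm(2L * n, sd = jitter_sd * spacing), ncol = 2L)
  pts <- base + jit
  deleted <- which(runif(n) < deletion_p)
  duplicated_ids <- which(runif(n) < duplication_p)
  dup_pts <- NULL
  if (length(duplicated_ids) > 0L) {
    ang <- runif(length(duplicated_ids), 0, 2 * pi)
    dup_pts <- pts[duplicated_ids, , drop = FALSE] +
      0.1 * spacing * cbind(cos(ang), sin(ang))
  }
  keep <- setdiff(seq_len(n), deleted)
  out_pts <- rbind(pts[keep, , drop = FALSE], dup_pts)
  out <- data.frame(id = seq_len(nrow(out_pts)),
                    x = out_pts[, 1L], y = out_pts[, 2L])
  attr(out, "spec") <- list(rows = rows, cols = cols, spacing = spacing,
                            jitter_sd = jitter_sd,
                            deletion_p = deletion_p,
                            duplication_p = duplication_p, seed = seed)
  attr(out, "truth") <- list(deleted = deleted,
                             duplicated = duplicated_ids,
                             jitter = jit)
  if (nrow(out) == 0L) {
    warning("all lattice points deleted; empty centroid set",
            call. = FALSE)
    attr(out, "empty") <- TRUE
  }
  out
}

# single-peak pulse: smooth rise (timescale `rise`) followed by
# exponential decay (timescale `decay`), normalized to `peak`
pulse_shape <- function(t, onset, rise, decay, peak) {
  s <- t - onset
  f <- ifelse(s > 0, (1 - exp(-s / rise)) * exp(-s / decay), 0)
  s_star <- rise * log((rise + decay) / rise)
  fmax <- (1 - exp(-s_star / rise)) * exp(-s_star / decay)
  peak * f / fmax
}

#' Synthetic eye-disk cell table
#'
#' Emulates the per-cell measurement table exported by confocal-stack
#' segmentation: R8 neurons on regularly spaced anterior-posterior
#' columns, progenitor cells at random positions, a pulse-shaped true
#' expression trajectory (smooth rise to a single peak, then
#' exponential relaxation to baseline), multiplicative lognormal
#' measurement noise on the reporter channel, and a known
#' developmental time shift between replicates.  Both fluorescence
#' channels are emitted so that [normalize_expression()] recovers the
#' intended level, and the full ground truth travels in attributes.
#'
#' @param n_cells number of progenitor cells.
#' @param r8_spacing R8 column spacing in pixels.
#' @param n_columns number of R8 columns.
#' @param r8_per_column R8 cells per column.
#' @param onset,rise,decay,peak pulse parameters (hours, hours, hours,
#'   normalized fluorescence).
#' @param noise_sd standard deviation of the lognormal multiplicative
#'   measurement noise.
#' @param shift injected developmental-time shift of this replicate
#'   (hours).
#' @param disk_id identifier stored in the table.
#' @param hours_per_column furrow period used to translate x to time.
#' @param reference_level mean reference-channel fluorescence.
#' @param seed integer RNG seed.
#' @return Data frame with columns `disk_id`, `cell_type`, `x_px`,
#'   `y_px`, `reporter_mean`, `reference_mean`; attributes `spec` and
#'   `truth` (per-cell true time and level, and the shift).
#' @export
make_disk <- function(n_cells = 600L, r8_spacing = 40, n_columns = 12L,
                      r8_per_column = 8L, onset = 5, rise = 4,
                      decay = 12, peak = 2, noise_sd = 0.1, shift = 0,
                      disk_id = "disk1", hours_per_column = 2,
                      reference_level = 100, seed = 1L) {
  stopifnot(n_cells > 0, r8_spacing > 0, n_columns >= 2L,
            rise > 0, decay > 0, peak > 0, noise_sd >= 0)
  set.seed(seed)
  span <- n_columns * r8_spacing
  r8_x <- rep((seq_len(n_columns) - 0.5) * r8_spacing,
              each = r8_per_column)
  r8_y <- rep(seq(0, span, length.out = r8_per_column),
              times = n_columns)
  prog_x <- runif(n_cells, 0, span)
  prog_y <- runif(n_cells, 0, span)
  x <- c(r8_x, prog_x)
  y <- c(r8_y, prog_y)
  type <- c(rep("R8", length(r8_x)), rep("progenitor", n_cells))
  t_true <- x * hours_per_column / r8_spacing + shift
  level <- pulse_shape(t_true, onset, rise, decay, peak)
  obs <- level * exp(rnorm(length(level), 0, noise_sd))
  out <- data.frame(disk_id = disk_id, cell_type = type,
                    x_px = x, y_px = y,
                    reporter_mean = obs * reference_level,
                    reference_mean = reference_level)
  attr(out, "spec") <- list(n_cells = n_cells, r8_spacing = r8_spacing,
                            n_columns = n_columns,
                            r8_per_column = r8_per_column,
                            onset = onset, rise = rise, decay = decay,
                            peak = peak, noise_sd = noise_sd,
                            shift = shift,
                            hours_per_column = hours_per_column,
                            seed = seed)
  attr(out, "truth") <- data.frame(true_time = t_true,
                                   true_level = level)
  out
}
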