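#' Normalize reporter expression to the nuclear reference channel
#'
#' Per-cell expression is the ratio of the mean reporter (YFP)
#' fluorescence to the mean nuclear reference (DAPI) fluorescence,
#' which mitigates uneven illumination, segment-area and
#' expression-capacity differences.  Cells with a non-positive
#' reference signal cannot be normalized and are excluded with a
#' message.
#'
#' @param cells data frame with numeric columns `reporter_mean` and
#'   `reference_mean`.
#' @return The table with an added `expression` column, excluded cells
#'   dropped.
#' @export
normalize_expression <- function(cells) {
  bad <- !(cells$reference_mean > 0)
  if (any(bad))
    message(sum(bad), " cell(s) with non-positive reference channel ",
            "excluded")
  cells <- cells[!bad, , drop = FALSE]
  cells$expression <- cells$reporter_mean / cells$reference_mean
  cells
}

#' Map anterior-posterior position to developmental time
#'
#' The morphogenetic furrow moves at a constant rate of one column of
#' R8 neurons per `hours_per_column` (2 h), so the median spacing of
#' adjacent R8 columns provides a spatial ruler.  The spacing is
#' estimated from a Delaunay triangulation of the R8 positions: the
#' median of the between-column x-separations of triangulation edges
#' (the median, not the mean, to suppress occasional non-adjacent
#' links).  Each cell's developmental time is its x position times the
#' conversion factor `hours_per_column / spacing`; the time origin is
#' arbitrary at this stage and is fixed later by alignment.
#'
#' @param cells per-cell table for one disk, with columns `cell_type`
#'   (containing `"R8"` rows), `x_px` and `y_px`.
#' @param hours_per_column furrow period per R8 column (hours).
#' @return The table with an added `time` column (hours); attributes
#'   `conversion_factor` (h/px) and `column_spacing` (px).
#' @export
furrow_clock <- function(cells, hours_per_column = 2) {
  r8 <- cells[cells$cell_type == "R8", c("x_px", "y_px")]
  if (nrow(r8) < 3L)
    stop("disk rejected: fewer than 3 R8 neurons", call. = FALSE)
  lat <- tryCatch(
    triangulate(data.frame(x = r8$x_px, y = r8$y_px)),
    error = function(e)
      stop("disk rejected: R8 positions do not triangulate (",
           conditionMessage(e), ")", call. = FALSE))
  dx <- abs(lat$points[lat$edges$i, 1L] - lat$points[lat$edges$j, 1L])
  pos <- dx[dx > 1e-6 * max(dx)]
  if (length(pos) == 0L)
    stop("disk rejected: fewer than 2 R8 columns", call. = FALSE)
  spacing <- median(pos[pos > 0.5 * median(pos)])
  factor <- hours_per_column / spacing
  cells$time <- cells$x_px * factor
  attr(cells, "conversion_factor") <- factor
  attr(cells, "column_spacing") <- spacing
  cells
}

# symmetric truncated first-order (local linear) fit around each index
local_linear <- function(t, y, window) {
  n <- length(t)
  h <- floor(window / 2)
  ct <- cumsum(t); cy <- cumsum(y)
  ctt <- cumsum(t * t); cty <- cumsum(t * y)
  wsum <- function(cs, lo, up) cs[up] - ifelse(lo > 1L, cs[lo - 1L], 0)
  out <- numeric(n)
  for (i in seq_len(n)) {
    he <- min(h, i - 1L, n - i)
    lo <- i - he; up <- i + he
    m <- up - lo + 1L
    St <- wsum(ct, lo, up); Sy <- wsum(cy, lo, up)
    Stt <- wsum(ctt, lo, up); Sty <- wsum(cty, lo, up)
    den <- Stt - St * St / m
    if (m < 2L || den <= 1e-12 * max(Stt, 1e-300)) {
      out[i] <- Sy / m
    } else {
      slope <- (Sty - St * Sy / m) / den
      out[i] <- Sy / m + slope * (t[i] - St / m)
    }
  }
  out
}

#' Savitzky-Golay moving average for irregularly sampled series
#'
#' First-order Savitzky-Golay filtration generalized to irregular
#' sampling: within a window of `window` consecutive cells (ordered by
#' time) an ordinary least-squares line is fitted and evaluated at the
#' window center, which on a regular grid is exactly the first-order
#' Savitzky-Golay filter and preserves polynomials of degree <= 1
#' everywhere.  Windows shrink symmetrically at the series ends rather
#' than padding.  A secondary pass with one fifth of the window
#' smooths the displayed line.
#'
#' @param t sample times (hours), sorted non-decreasing.
#' @param y sample values.
#' @param window primary window size in cells (250 by default).
#' @param secondary apply the secondary one-fifth-window pass?
#' @return Data frame with columns `time` and `mean`; attribute
#'   `short_series` flags a series shorter than the window (a single
#'   global linear fit).
#' @export
moving_average <- function(t, y, window = 250L, secondary = TRUE) {
  if (is.unsorted(t)) stop("series must be sorted by time", call. = FALSE)
  n <- length(t)
  short <- n < window
  if (short)
    warning("series shorter than the window; single global linear fit",
            call. = FALSE)
  sm <- local_linear(t, y, min(window, 2L * n))
  if (short) {
    fit <- lm(y ~ t)
    sm <- as.numeric(coef(fit)[1L] + coef(fit)[2L] * t)
  } else if (secondary) {
    sm <- local_linear(t, sm, max(3L, floor(window / 5)))
  }
  out <- data.frame(time = t, mean = sm)
  attr(out, "short_series") <- short
  out
}

#' Bootstrap confidence band for the moving average
#'
#' Within each moving window, the expression levels are resampled with
#' replacement `n_boot` times (1000 by default); the 2.5th and 97.5th
#' percentiles of the resampled window means give the confidence
#' bounds at the window center.
#'
#' @inheritParams moving_average
#' @param n_boot bootstrap draws per window.
#' @param seed integer RNG seed.
#' @param probs lower/upper percentile probabilities.
#' @return Data frame with columns `time`, `lo`, `hi`.
#' @export
bootstrap_band <- function(t, y, window = 250L, n_boot = 1000L,
                           seed = 1L, probs = c(0.025, 0.975)) {
  if (is.unsorted(t)) stop("series must be sorted by time", call. = FALSE)
  n <- length(t)
  h <- floor(min(window, 2L * n) / 2)
  set.seed(seed)
  lo <- hi <- numeric(n)
  for (i in seq_len(n)) {
    he <- min(h, i - 1L, n - i)
    w <- y[(i - he):(i + he)]
    m <- length(w)
    bm <- colMeans(matrix(w[sample.int(m, m * n_boot, replace = TRUE)],
                          m))
    q <- quantile(bm, probs, names = FALSE, type = 1)
    lo[i] <- q[1L]; hi[i] <- q[2L]
  }
  data.frame(time = t, lo = lo, hi = hi)
}

#' Align one expression time series to a reference
#'
#' Determines the time shift `dt` maximizing the cross-correlation of
#' the progenitor expression series `Y(t)` with a reference series
#' `X(t)`.  Both series are smoothed with a ten-cell moving average
#' for robustness against noise, standardized by their mean and
#' standard deviation (so affine scaling of the levels does not move
#' the optimum), interpolated onto a shared uniform grid, and
#' correlated over a discrete lag grid.  `dt` is the delay of `Y`
#' relative to `X`: subtracting `dt` from the `Y` times aligns the two
#' populations.
#'
#' @param y_time,y_value the moving population's times and levels.
#' @param x_time,x_value the reference population's times and levels.
#' @param window smoothing window in cells.
#' @param lag_step lag-grid resolution (hours); defaults to the median
#'   inter-cell time spacing of the reference.
#' @param max_lag largest |lag| searched (hours); defaults to half the
#'   reference time span.
#' @param min_overlap smallest number of grid points that must overlap
#'   for a lag to be considered.
#' @return An object of class `alignment_result`: list with `dt`,
#'   `lags`, `profile` (correlation at each lag) and `lag_step`.
#' @export
align_pair <- function(y_time, y_value, x_time, x_value, window = 10L,
                       lag_step = NULL, max_lag = NULL,
                       min_overlap = 10L) {
  oy <- order(y_time); ox <- order(x_time)
  y_time <- y_time[oy]; y_value <- y_value[oy]
  x_time <- x_time[ox]; x_value <- x_value[ox]
  if (sd(y_value) == 0 || sd(x_value) == 0)
    stop("zero-variance series; alignment undefined", call. = FALSE)
  ys <- moving_average(y_time, y_value, window, secondary = FALSE)$mean
  xs <- moving_average(x_time, x_value, window, secondary = FALSE)$mean
  ys <- (ys - mean(ys)) / sd(ys)
  xs <- (xs - mean(xs)) / sd(xs)
  if (is.null(lag_step)) {
    lag_step <- median(diff(x_time))
    if (!is.finite(lag_step) || lag_step <= 0)
      lag_step <- diff(range(x_time)) / max(length(x_time) - 1L, 1L)
  }
  if (is.null(max_lag)) max_lag <- diff(range(x_time)) / 2
  grid <- seq(min(x_time, y_time), max(x_time, y_time), by = lag_step)
  xg <- approx(x_time, xs, grid, rule = 1)$y
  yg <- approx(y_time, ys, grid, rule = 1)$y
  kmax <- max(1L, floor(max_lag / lag_step))
  lags <- (-kmax:kmax) * lag_step
  profile <- vapply(-kmax:kmax, function(k) {
    # candidate: Y delayed by k*lag_step, i.e. compare X(t) to Y(t + k)
    if (k >= 0) {
      xa <- head(xg, length(xg) - k); ya <- tail(yg, length(yg) - k)
    } else {
      xa <- tail(xg, length(xg) + k); ya <- head(yg, length(yg) + k)
    }
    ok <- is.finite(xa) & is.finite(ya)
    if (sum(ok) < min_overlap) return(NA_real_)
    if (sd(xa[ok]) == 0 || sd(ya[ok]) == 0) return(NA_real_)
    stats::cor(xa[ok], ya[ok])
  }, numeric(1))
  if (all(is.na(profile)))
    stop("no candidate lag has sufficient overlap", call. = FALSE)
  dt <- lags[which.max(profile)]
  structure(list(dt = dt, lags = lags, profile = profile,
                 lag_step = lag_step),
            class = "alignment_result")
}

#' Align replicate disks and treatments in developmental time
#'
#' Within each treatment one disk is chosen at random and rebased so
#' that time zero is its first annotated R8 neuron; it then serves as
#' the reference for aligning every other replicate by
#' [align_pair()] on the progenitor expression series.  Treatments are
#' then aligned by aggregating all cells per treatment and repeating
#' the procedure with the first treatment as reference.  Finally the
#' display convention shifts time so that -10 h becomes the new 0 h
#' (reporter expression first becomes detectable around -10 h).
#'
#' @param cells per-cell table with columns `disk_id`, `cell_type`,
#'   `time`, `expression`, and optionally `treatment` (a single
#'   treatment is assumed when absent).
#' @param seed integer seed for the random reference-disk choice.
#' @param window smoothing window (cells) for the alignment.
#' @param rebase_offset display-rebase offset (hours) added at the end.
#' @return List with `cells` (the table with `time` replaced by
#'   aligned time, original kept as `time_raw`) and `shifts` (data
#'   frame: treatment, disk_id, dt, role).
#' @export
align_experiment <- function(cells, seed = 1L, window = 10L,
                             rebase_offset = 10) {
  if (is.null(cells$treatment)) cells$treatment <- "all"
  need <- c("disk_id", "cell_type", "time", "expression")
  if (!all(need %in% names(cells)))
    stop("cells must carry columns ", paste(need, collapse = ", "),
         call. = FALSE)
  cells$time_raw <- cells$time
  set.seed(seed)
  treatments <- unique(cells$treatment)
  shifts <- NULL
  for (tr in treatments) {
    sub <- cells$treatment == tr
    disks <- unique(cells$disk_id[sub])
    ref <- if (length(disks) == 1L) disks else sample(disks, 1L)
    ref_rows <- sub & cells$disk_id == ref
    r8_t <- cells$time[ref_rows & cells$cell_type == "R8"]
    if (length(r8_t) == 0L)
      stop("reference disk ", ref, " has no R8 cells", call. = FALSE)
    t0 <- min(r8_t)
    cells$time[ref_rows] <- cells$time[ref_rows] - t0
    shifts <- rbind(shifts, data.frame(treatment = tr, disk_id = ref,
                                       dt = t0, role = "reference"))
    ref_prog <- cells[ref_rows & cells$cell_type == "progenitor", ]
    if (nrow(ref_prog) == 0L)
      stop("treatment ", tr, " has no progenitor cells; cannot align",
           call. = FALSE)
    for (d in setdiff(disks, ref)) {
      rows <- sub & cells$disk_id == d
      prog <- cells[rows & cells$cell_type == "progenitor", ]
      if (nrow(prog) == 0L)
        stop("disk ", d, " has no progenitor cells; cannot align",
             call. = FALSE)
      al <- align_pair(prog$time, prog$expression,
                       ref_prog$time, ref_prog$expression,
                       window = window)
      cells$time[rows] <- cells$time[rows] - al$dt
      shifts <- rbind(shifts, data.frame(treatment = tr, disk_id = d,
                                         dt = al$dt, role = "replicate"))
    }
  }
  if (length(treatments) > 1L) {
    ref_tr <- treatments[1L]
    ref_prog <- cells[cells$treatment == ref_tr &
                      cells$cell_type == "progenitor", ]
    for (tr in treatments[-1L]) {
      rows <- cells$treatment == tr
      prog <- cells[rows & cells$cell_type == "progenitor", ]
      al <- align_pair(prog$time, prog$expression,
                       ref_prog$time, ref_prog$expression,
                       window = window)
      cells$time[rows] <- cells$time[rows] - al$dt
      shifts <- rbind(shifts, data.frame(treatment = tr, disk_id = NA,
                                         dt = al$dt, role = "treatment"))
    }
  }
  cells$time <- cells$time + rebase_offset
  list(cells = cells, shifts = shifts)
}
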