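#' Halton low-discrepancy sequence
#'
#' Quasi-random points in the unit hypercube by the radical-inverse
#' construction in the first `dim` prime bases, with a seeded random
#' Cranley--Patterson shift (mod 1) so that different seeds give
#' different, equally space-filling designs.
#'
#' @param n number of points.
#' @param dim dimension (up to 25).
#' @param seed integer seed for the random shift; `NULL` for the raw
#'   unshifted sequence.
#' @return An `n x dim` matrix with entries in `[0, 1)`.
#' @export
halton_sequence <- function(n, dim, seed = NULL) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47,
              53, 59, 61, 67, 71, 73, 79, 83, 89, 97)
  if (dim > length(primes)) stop("dim too large", call. = FALSE)
  radical_inverse <- function(i, base) {
    f <- 1 / base
    r <- 0
    while (i > 0) {
      r <- r + f * (i %% base)
      i <- i %/% base
      f <- f / base
    }
    r
  }
  u <- vapply(seq_len(dim), function(d)
    vapply(seq_len(n), radical_inverse, numeric(1), base = primes[d]),
    numeric(n))
  u <- matrix(u, nrow = n)
  if (!is.null(seed)) {
    set.seed(seed)
    shift <- runif(dim)
    u <- (u + matrix(shift, n, dim, byrow = TRUE)) %% 1
  }
  u
}

#' Quasi-random parameter sets over a tenfold range
#'
#' Draws `n` parameter sets with each of the seven model parameters
#' (the six rate constants and the severity) varied log-uniformly
#' across a `span`-fold range centered on its default value, i.e.
#' within `[default/sqrt(span), default*sqrt(span)]`, using a Halton
#' low-discrepancy design.  The auxiliary constants are tied to their
#' primary counterparts through the severity, which is how the
#' seven-parameter count arises.
#'
#' @param n number of parameter sets.
#' @param defaults a `rate_params` object supplying the center values.
#' @param span fold-range of variation (> = 1).
#' @param severity center value of the severity draw.
#' @param seed integer seed (drives the design shift).
#' @return A data frame (class `parameter_sets`) with columns `id`, the
#'   six rate constants and `severity`; attributes record the sampler,
#'   seed and bounds.
#' @export
sample_parameter_sets <- function(n = 1000L, defaults = default_rate_params(),
                                  span = 10, severity = NULL,
                                  seed = 1L) {
  if (span < 1) stop("span must be >= 1", call. = FALSE)
  if (is.null(severity)) severity <- default_severity("all")
  centers <- c(k_G = defaults$k_G, gamma_G = defaults$gamma_G,
               k_R = defaults$k_R, gamma_R = defaults$gamma_R,
               k_P = defaults$k_P, gamma_P = defaults$gamma_P,
               severity = severity)
  u <- halton_sequence(n, length(centers), seed = seed)
  vals <- sapply(seq_along(centers), function(j)
    centers[j] * span^(u[, j] - 0.5))
  vals <- matrix(vals, nrow = n,
                 dimnames = list(NULL, names(centers)))
  out <- data.frame(id = seq_len(n), vals)
  attr(out, "sampler") <- "halton-cranley-patterson"
  attr(out, "seed") <- seed
  attr(out, "span") <- span
  attr(out, "centers") <- centers
  class(out) <- c("parameter_sets", "data.frame")
  out
}

set_to_params <- function(row, defaults = default_rate_params()) {
  p <- unclass(defaults)
  for (nm in c("k_G", "gamma_G", "k_R", "gamma_R", "k_P", "gamma_P"))
    p[[nm]] <- row[[nm]]
  structure(p, class = "rate_params")
}

#' Run a full/partial x metabolic-condition simulation sweep
#'
#' For each parameter set and each metabolic condition, simulates a
#' full-activation and a partial-activation ensemble, derives the
#' threshold from the matching full-activation ensemble of the same
#' condition, and records the error statistics.  Full activation
#' assigns auxiliary activators at all three synthesis stages with the
#' set's severity; partial activation drops them all.
#'
#' Per-set outputs can be written incrementally to `out_dir` as JSON
#' records; a rerun with the same seed skips sets whose record already
#' exists, making a long sweep resumable without changing its result.
#'
#' @param sets a `parameter_sets` data frame.
#' @param variant `"linear"`, `"bounded"`, `"hill"`, or
#'   `"nonzero_basal"` (the linear model with a non-zero basal
#'   stimulus).
#' @param ensemble_n trajectories per ensemble.
#' @param conditions metabolic condition labels to simulate.
#' @param input an `input_signal`; for `"nonzero_basal"` its basal
#'   level is replaced by `basal`.
#' @param basal basal stimulus used by the `"nonzero_basal"` variant.
#' @param stages stages carrying auxiliary activators under full
#'   activation.
#' @param seed master seed; per-set, per-condition seeds are derived
#'   from it up front so the result is independent of resumption.
#' @param grid_n evaluation-grid size per ensemble.
#' @param out_dir optional directory for incremental per-set records.
#' @return An object of class `sweep_result`: list with `records` (one
#'   row per set x condition: id, condition, raw_failure,
#'   error_frequency, mean_underexpression, status) and the run
#'   settings.
#' @export
run_sweep <- function(sets, variant = "linear", ensemble_n = 5000L,
                      conditions = c("normal", "reduced"),
                      input = step_input(), basal = 0.1,
                      stages = c("gene", "transcript", "protein"),
                      seed = 1L, grid_n = 200L, out_dir = NULL) {
  stopifnot(nrow(sets) >= 1L)
  model <- variant
  if (variant == "nonzero_basal") {
    model <- "linear"
    input <- step_input(input$onset, input$duration, input$amplitude,
                        basal)
  }
  if (model == "hill") stages <- setdiff(stages, "gene")
  set.seed(seed)
  seed_tab <- matrix(sample.int(.Machine$integer.max - 1L,
                                2L * nrow(sets) * length(conditions)),
                     nrow = nrow(sets))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  records <- vector("list", nrow(sets))
  for (i in seq_len(nrow(sets))) {
    rec_file <- if (!is.null(out_dir))
      file.path(out_dir, sprintf("set_%05d.json", sets$id[i])) else NULL
    if (!is.null(rec_file) && file.exists(rec_file)) {
      records[[i]] <- as.data.frame(jsonlite::fromJSON(rec_file))
      next
    }
    base <- set_to_params(sets[i, ])
    rec <- tryCatch({
      rows <- lapply(seq_along(conditions), function(ci) {
        cond <- conditions[ci]
        s_full <- seed_tab[i, 2L * ci - 1L]
        s_part <- seed_tab[i, 2L * ci]
        p_full <- scale_for_metabolism(
          apply_activation(base,
            activation_scheme("full", stages, sets$severity[i])), cond)
        p_part <- scale_for_metabolism(
          apply_activation(base, activation_scheme("partial")), cond)
        horizon <- default_horizon(input, base)
        full <- simulate_ensemble(model, p_full, input, horizon,
                                  n = ensemble_n, seed = s_full,
                                  grid_n = grid_n)
        part <- simulate_ensemble(model, p_part, input, horizon,
                                  n = ensemble_n, seed = s_part,
                                  grid_n = grid_n)
        er <- error_report(part, full)
        data.frame(id = sets$id[i], condition = cond,
                   raw_failure = er$raw_failure,
                   error_frequency = er$error_frequency,
                   mean_underexpression = er$mean_underexpression,
                   status = "ok")
      })
      do.call(rbind, rows)
    }, error = function(e) {
      data.frame(id = sets$id[i], condition = conditions,
                 raw_failure = NA_real_, error_frequency = NA_real_,
                 mean_underexpression = NA_real_,
                 status = conditionMessage(e))
    })
    if (!is.null(rec_file))
      jsonlite::write_json(rec, rec_file, digits = NA, auto_unbox = FALSE)
    records[[i]] <- rec
  }
  structure(list(records = do.call(rbind, records), variant = variant,
                 conditions = conditions, ensemble_n = ensemble_n,
                 seed = seed, stages = stages, input = input),
            class = "sweep_result")
}

#' Condensed 1-D projection of a sweep
#'
#' Collapses a sweep onto one-dimensional summary distributions: the
#' per-set error frequency under each condition (the error-frequency
#' increase on auxiliary-activator loss) and the per-set differences
#' between metabolic conditions, computed strictly within parameter
#' sets.  Returns histograms and summary quantiles for each statistic.
#'
#' @param sweep a `sweep_result`.
#' @param probs quantiles to report.
#' @return List with `differences` (data frame: id, one column per
#'   condition's error frequency, plus `reduced_minus_normal` /
#'   `elevated_minus_normal` where available), `quantiles` and
#'   `histograms` (objects from [graphics::hist()] with `plot = FALSE`
#'   semantics).
#' @export
condense_projection <- function(sweep,
                                probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  rec <- sweep$records[sweep$records$status == "ok", ]
  wide <- NULL
  for (cond in sweep$conditions) {
    sub <- rec[rec$condition == cond, c("id", "error_frequency")]
    names(sub)[2] <- cond
    wide <- if (is.null(wide)) sub else merge(wide, sub, by = "id")
  }
  stats <- as.list(wide[-1])
  if (all(c("reduced", "normal") %in% names(wide)))
    wide$reduced_minus_normal <- wide$reduced - wide$normal
  if (all(c("elevated", "normal") %in% names(wide)))
    wide$elevated_minus_normal <- wide$elevated - wide$normal
  stat_cols <- setdiff(names(wide), c("id", sweep$conditions))
  stats <- c(stats, as.list(wide[stat_cols]))
  quantiles <- lapply(stats, quantile, probs = probs, na.rm = TRUE)
  histograms <- lapply(stats, function(x)
    graphics::hist(x, breaks = "FD", plot = FALSE))
  list(differences = wide, quantiles = quantiles,
       histograms = histograms)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("sweep_result:", length(unique(x$records$id)), "parameter sets x",
      length(x$conditions), "conditions (", x$variant, "variant,",
      x$ensemble_n, "trajectories per ensemble )\n")
  invisible(x)
}
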