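#' Simulate one exact stochastic trajectory
#'
#' Gillespie-type stochastic simulation of the chosen model variant.
#' States are discrete non-negative counts (the model is linearized
#' about a basal level of zero activity, so deviations are constrained
#' to non-negative integers).  The piecewise-constant stimulus is
#' handled exactly by restarting the exponential waiting-time clock at
#' the input discontinuities.
#'
#' Randomness comes from a counter-based per-trajectory generator
#' seeded by `(seed, stream)`, so identical arguments reproduce the
#' trajectory bit for bit and ensembles can hand out independent
#' streams; trajectory `i` of [simulate_ensemble()] with master seed
#' `s` and `method = "event"` equals
#' `simulate_ssa(..., seed = s, stream = i)` on the grid.
#'
#' @param variant `"linear"`, `"bounded"` or `"hill"`.
#' @param params a `rate_params` object.
#' @param input an `input_signal`.
#' @param horizon end time of the simulation (hours); must cover the
#'   input window.  Defaults to [default_horizon()].
#' @param seed integer RNG seed.
#' @param stream stream index within the seed (0 for standalone runs).
#' @param init initial state `c(D, R, P)`; the bounded variant starts
#'   as diploid with all copies off (`G_on = 0`).
#' @param max_events guard against runaway event counts.
#' @return An object of class `trajectory`: list with `time`, `D`, `R`,
#'   `P` (post-event states, piecewise constant between events), plus
#'   `seed`, `stream`, `variant` and a parameter snapshot.
#' @export
simulate_ssa <- function(variant, params, input,
                         horizon = default_horizon(input, params),
                         seed = 1L, stream = 0L, init = c(0L, 0L, 0L),
                         max_events = 5e6) {
  variant <- match.arg(variant, c("linear", "bounded", "hill"))
  if (horizon <= input$onset)
    stop("horizon must exceed the input onset", call. = FALSE)
  validate_rate_params(params)
  ev <- ssa_events_cpp(variant_code(variant), params_vector(params),
                       input$onset, input$duration, input$amplitude,
                       input$basal, 0, horizon, as.integer(init),
                       as.integer(max_events), seed, stream)
  structure(list(time = ev$time, D = ev$D, R = ev$R, P = ev$P,
                 seed = seed, stream = stream, variant = variant,
                 params = params, input = input, horizon = horizon),
            class = "trajectory")
}

#' Simulate an ensemble of trajectories on a shared grid
#'
#' Runs `n` independent stochastic trajectories (default 5000, the
#' ensemble size used for all reported statistics) and records each on
#' a shared uniform evaluation grid.  Trajectory `i` uses the
#' counter-based stream `(seed, i)`, so two calls with the same master
#' seed give identical ensembles.
#'
#' Two exact sampling methods are available.  `"conditional"` (the
#' default) simulates gene and mRNA dynamics event by event and
#' advances the protein count from grid point to grid point by its
#' exact conditional law given the mRNA path (binomial survival plus
#' Poisson influx; protein never feeds back into the other channels).
#' Its joint distribution at the grid times is identical to full SSA,
#' but it skips the individual protein events, which dominate the cost
#' at high protein counts.  `"event"` simulates every reaction event
#' and records the grid by last-value interpolation; with this method
#' trajectory `i` can be replayed in full with
#' `simulate_ssa(..., seed = seed, stream = i)`.
#'
#' @inheritParams simulate_ssa
#' @param n number of trajectories.
#' @param grid_n number of points of the uniform evaluation grid.
#' @param species which species to retain as `n x grid_n` matrices
#'   (protein `"P"` always; add `"D"`, `"R"` as needed).
#' @param method `"conditional"` or `"event"`; both are exact (see
#'   Details), differing only in which random numbers realize the same
#'   distribution.
#' @return An object of class `trajectory_ensemble`: list with `grid`
#'   (times), one matrix per retained species (rows = trajectories),
#'   `n`, `seed`, `variant`, `params`, `input`.
#' @export
simulate_ensemble <- function(variant, params, input,
                              horizon = default_horizon(input, params),
                              n = 5000L, seed = 1L, grid_n = 200L,
                              species = "P",
                              method = c("conditional", "event")) {
  variant <- match.arg(variant, c("linear", "bounded", "hill"))
  method <- match.arg(method)
  if (n < 1) stop("need n >= 1", call. = FALSE)
  if (horizon <= input$onset)
    stop("horizon must exceed the input onset", call. = FALSE)
  validate_rate_params(params)
  grid <- seq(0, horizon, length.out = grid_n)
  mats <- ssa_ensemble_cpp(variant_code(variant),
                           params_vector(params),
                           input$onset, input$duration,
                           input$amplitude, input$basal, grid,
                           c(0L, 0L, 0L), as.integer(n), seed,
                           "D" %in% species, "R" %in% species,
                           method == "conditional")
  structure(c(list(grid = grid, n = as.integer(n), seed = seed,
                   variant = variant, params = params, input = input,
                   horizon = horizon, method = method),
              mats[intersect(c("D", "R", "P"), c(names(mats)))]),
            class = "trajectory_ensemble")
}

#' Ensemble mean trajectory
#'
#' @param ensemble a `trajectory_ensemble`.
#' @param species species name present in the ensemble.
#' @return Numeric vector of per-grid-time means.
#' @export
ensemble_mean <- function(ensemble, species = "P") {
  colMeans(ensemble[[species]])
}

#' Per-trajectory peak protein levels
#'
#' @param ensemble a `trajectory_ensemble` carrying species `P`.
#' @return Numeric vector (length `n`) of each trajectory's maximum
#'   protein level on the evaluation grid.
#' @export
peak_levels <- function(ensemble) {
  apply(ensemble$P, 1L, max)
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat("trajectory_ensemble:", x$n, x$variant, "trajectories,",
      length(x$grid), "grid points on [0,", round(max(x$grid), 3), "]\n")
  invisible(x)
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory (", x$variant, "): ", length(x$time), " events on [0, ",
      round(x$horizon, 3), "], seed ", x$seed, ", stream ", x$stream,
      "\n", sep = "")
  invisible(x)
}

#' Convert a trajectory to a data frame
#'
#' @param x a `trajectory`.
#' @param ... unused.
#' @return A data frame with columns `time`, `D`, `R`, `P`.
#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time = x$time, D = x$D, R = x$R, P = x$P)
}
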