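#' Deterministic (continuum-limit) solution of the model
#'
#' Numerically integrates the ordinary-differential-equation
#' representation of the chosen variant on a dense time grid.  This is
#' the continuum limit of the stochastic model and serves as an oracle
#' for the ensemble mean of the stochastic simulation.
#'
#' Linear variant:
#' \deqn{dD/dt = (k_G+\eta_G) I(t) - \gamma_G D}
#' \deqn{dR/dt = (k_R+\eta_R) D - \gamma_R R}
#' \deqn{dP/dt = (k_P+\eta_P) R - \gamma_P P}
#' The bounded variant replaces the first equation with two-state gene
#' kinetics, \eqn{dG_{on}/dt = (k_G+\eta_G) I(t) G_{off} - \gamma_G
#' G_{on}} with \eqn{G_{off} = b - G_{on}}; the Hill variant drives
#' transcription directly by \eqn{I^H/(I^H + 0.5^H)}.
#'
#' @inheritParams simulate_ssa
#' @param grid_n number of output grid points.
#' @param init initial state `c(D, R, P)`.
#' @return A data frame with columns `time`, `D`, `R`, `P` (`D` is
#'   `G_on` in the bounded variant, identically 0 in the Hill variant).
#' @export
solve_deterministic <- function(variant, params, input,
                                horizon = default_horizon(input, params),
                                grid_n = 200L, init = c(0, 0, 0)) {
  variant <- match.arg(variant, c("linear", "bounded", "hill"))
  if (horizon <= input$onset)
    stop("horizon must exceed the input onset", call. = FALSE)
  validate_rate_params(params)
  p <- params
  deriv <- function(t, y, parms, stim) {
    D <- y[1]; R <- y[2]; P <- y[3]
    dD <- switch(variant,
      linear  = (p$k_G + p$eta_G) * stim - p$gamma_G * D,
      bounded = (p$k_G + p$eta_G) * stim * (p$allele_bound - D) -
                p$gamma_G * D,
      hill    = 0)
    drive <- switch(variant,
      linear  = D,
      bounded = D,
      hill    = hill_drive(stim, p$hill_H, p$hill_half_max))
    dR <- (p$k_R + p$eta_R) * drive - p$gamma_R * R
    dP <- (p$k_P + p$eta_P) * R - p$gamma_P * P
    list(c(dD, dR, dP))
  }
  grid <- seq(0, horizon, length.out = grid_n)
  breaks <- sort(unique(c(0, input$onset, input$onset + input$duration,
                          horizon)))
  breaks <- breaks[breaks >= 0 & breaks <= horizon]
  y <- init
  out <- NULL
  for (k in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[k]; t1 <- breaks[k + 1L]
    if (t1 <= t0) next
    stim <- stimulus_at(input, (t0 + t1) / 2)
    times <- sort(unique(c(t0, grid[grid > t0 & grid < t1], t1)))
    seg <- deSolve::ode(y = y, times = times, func = deriv, parms = NULL,
                        stim = stim, method = "lsoda",
                        rtol = 1e-9, atol = 1e-10)
    if (attr(seg, "istate")[1L] < 0)
      stop("ODE integration failed on [", t0, ", ", t1, "]",
           call. = FALSE)
    y <- as.numeric(seg[nrow(seg), -1L])
    out <- rbind(out, unclass(seg)[, , drop = FALSE])
  }
  out <- as.data.frame(out)
  names(out) <- c("time", "D", "R", "P")
  # keep exactly the requested grid (segment ends may duplicate points)
  out <- out[!duplicated(out$time), , drop = FALSE]
  res <- out[match_closest(grid, out$time), , drop = FALSE]
  res$time <- grid
  rownames(res) <- NULL
  res
}

match_closest <- function(x, table) {
  vapply(x, function(v) which.min(abs(table - v)), integer(1))
}

#' Closed-form steady state of the linear variant
#'
#' Under a sustained stimulus `I` the linear model's protein fixed
#' point is
#' \deqn{P^* = \frac{(k_P+\eta_P)(k_R+\eta_R)(k_G+\eta_G) I}
#'                  {\gamma_G \gamma_R \gamma_P}.}
#'
#' @param params a `rate_params` object.
#' @param stimulus sustained stimulus level.
#' @return Named vector with elements `D`, `R`, `P`.
#' @export
linear_steady_state <- function(params, stimulus = 1) {
  D <- (params$k_G + params$eta_G) * stimulus / params$gamma_G
  R <- (params$k_R + params$eta_R) * D / params$gamma_R
  P <- (params$k_P + params$eta_P) * R / params$gamma_P
  c(D = D, R = R, P = P)
}
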