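#' Transient step input signal
#'
#' The stimulus driving gene activation: a piecewise-constant step of
#' the given amplitude lasting `duration` hours (default 3 h), on top of
#' a basal stimulus level (default 0).  The amplitude is a dimensionless
#' multiplier of the gene-activation rate constant.
#'
#' @param onset start time of the step (hours).
#' @param duration length of the step (hours), must be positive.
#' @param amplitude stimulus level during the step.
#' @param basal stimulus level outside the step; `amplitude > basal >= 0`.
#' @return An object of class `input_signal`.
#' @export
step_input <- function(onset = 0, duration = 3, amplitude = 1, basal = 0) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (basal < 0 || amplitude < basal)
    stop("need amplitude >= basal >= 0", call. = FALSE)
  structure(list(onset = onset, duration = duration,
                 amplitude = amplitude, basal = basal),
            class = "input_signal")
}

#' Evaluate an input signal
#'
#' @param input an `input_signal`.
#' @param t vector of times (hours).
#' @return Stimulus level at each time (amplitude within
#'   `[onset, onset + duration)`, basal outside).
#' @export
stimulus_at <- function(input, t) {
  ifelse(t >= input$onset & t < input$onset + input$duration,
         input$amplitude, input$basal)
}

#' Default simulation horizon
#'
#' Long enough for the pulse to relax back towards baseline: the input
#' window plus five times the slowest of the mRNA and protein lifetimes.
#'
#' @param input an `input_signal`.
#' @param params a `rate_params` object.
#' @return Horizon time (hours).
#' @export
default_horizon <- function(input, params) {
  input$onset + input$duration + 5 / min(params$gamma_R, params$gamma_P)
}
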