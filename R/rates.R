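#' Kinetic rate parameters for one model instance
#'
#' Container for all rate constants of the pulsatile expression model.
#' Primary synthesis constants (`k_G`, `k_R`, `k_P`) and degradation
#' constants (`gamma_G`, `gamma_R`, `gamma_P`) describe gene activation,
#' transcription, translation and first-order turnover of each species.
#' Auxiliary activators act in parallel with the primary activators and
#' contribute additively to the synthesis rate constants through
#' `eta_G`, `eta_R`, `eta_P`.  The Hill variant additionally carries a
#' transcriptional Hill coefficient `hill_H` and the stimulus level of
#' half-maximal transcription `hill_half_max` (fixed at 0.5 for a binary
#' input signal); the gene-copy-bounded variant carries `allele_bound`,
#' the number of gene copies (2 for a diploid cell).
#'
#' All constants are in units of events per hour (per unit of the
#' upstream species where applicable) and must be non-negative.
#'
#' @param k_G,k_R,k_P primary activation, transcription and translation
#'   rate constants (per hour).
#' @param gamma_G,gamma_R,gamma_P first-order decay constants of
#'   activated gene state, mRNA and protein (per hour).
#' @param eta_G,eta_R,eta_P auxiliary activator rate constants at the
#'   gene, transcript and protein synthesis stages (per hour).
#' @param hill_H dimensionless Hill coefficient (Hill variant only).
#' @param hill_half_max stimulus at half-maximal transcription (Hill
#'   variant only).
#' @param allele_bound maximum number of simultaneously active gene
#'   copies (bounded variant only); positive integer.
#' @return An object of class `rate_params` (a named list).
#' @seealso [default_rate_params()], [scale_for_metabolism()],
#'   [apply_activation()]
#' @export
rate_params <- function(k_G, gamma_G, k_R, gamma_R, k_P, gamma_P,
                        eta_G = 0, eta_R = 0, eta_P = 0,
                        hill_H = 2, hill_half_max = 0.5,
                        allele_bound = 2L) {
  p <- list(k_G = k_G, gamma_G = gamma_G, k_R = k_R, gamma_R = gamma_R,
            k_P = k_P, gamma_P = gamma_P,
            eta_G = eta_G, eta_R = eta_R, eta_P = eta_P,
            hill_H = hill_H, hill_half_max = hill_half_max,
            allele_bound = as.integer(allele_bound))
  validate_rate_params(p)
  structure(p, class = "rate_params")
}

validate_rate_params <- function(p) {
  num <- c("k_G", "gamma_G", "k_R", "gamma_R", "k_P", "gamma_P",
           "eta_G", "eta_R", "eta_P", "hill_H", "hill_half_max")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("rate parameter '", f, "' must be a single non-negative number",
           call. = FALSE)
  }
  if (p$allele_bound < 1L)
    stop("allele_bound must be a positive integer", call. = FALSE)
  invisible(p)
}

#' Default rate parameters
#'
#' One documented default parameter set, used everywhere a caller does
#' not supply its own.  Transcript and protein synthesis and turnover
#' are on hour-scale kinetics typical of animal cells (mRNA half-life
#' about 40 min, protein half-life about 1.4 h), while gene activation
#' and decay are roughly tenfold faster so that promoter state tracks
#' the input closely.  Under a sustained unit stimulus the deterministic
#' fixed point is about 2 active gene units, 20 transcripts and 400
#' protein copies.
#'
#' @return A `rate_params` object with all auxiliary constants zero.
#' @export
default_rate_params <- function() {
  rate_params(k_G = 20, gamma_G = 10,
              k_R = 10, gamma_R = 1,
              k_P = 10, gamma_P = 0.5)
}

#' Metabolic condition
#'
#' Maps the three metabolic states to the multiplicative factor applied
#' to ATP-dependent rate constants: reduced metabolism halves them,
#' elevated metabolism increases them by 50%.
#'
#' @param label one of `"reduced"`, `"normal"`, `"elevated"`.
#' @return An object of class `metabolic_condition` with fields `label`
#'   and `factor`.
#' @export
metabolic_condition <- function(label = c("normal", "reduced", "elevated")) {
  label <- match.arg(label)
  factor <- c(reduced = 0.5, normal = 1.0, elevated = 1.5)[[label]]
  structure(list(label = label, factor = factor),
            class = "metabolic_condition")
}

#' Scale rate parameters for a metabolic condition
#'
#' Transcription, translation and protein degradation all require ATP
#' turnover, so their rate constants (`k_R`, `k_P`, `gamma_P`) are
#' multiplied by the condition's factor.  Auxiliary activator strengths
#' are scaled in an equivalent manner to their primary counterparts:
#' `eta_R` and `eta_P` are always scaled; `eta_G` is scaled only when
#' `scale_eta_G = TRUE`, because its primary counterpart `k_G` is not
#' ATP-dependent.  Optionally mRNA decay can be treated as
#' ATP-dependent as well (`scale_gamma_R = TRUE`).
#'
#' @param params a `rate_params` object.
#' @param condition a `metabolic_condition`, or a condition label.
#' @param scale_eta_G scale the auxiliary gene-activation constant too?
#' @param scale_gamma_R scale mRNA decay too?
#' @return A new `rate_params` object; the input is not modified.
#' @examples
#' p <- rate_params(k_G = 1, gamma_G = 1, k_R = 2, gamma_R = 1,
#'                  k_P = 4, gamma_P = 0.1)
#' scale_for_metabolism(p, "reduced")$k_R  # 1
#' @export
scale_for_metabolism <- function(params, condition,
                                 scale_eta_G = FALSE,
                                 scale_gamma_R = FALSE) {
  if (is.character(condition)) condition <- metabolic_condition(condition)
  if (!inherits(condition, "metabolic_condition"))
    stop("unknown metabolic condition", call. = FALSE)
  f <- condition$factor
  out <- unclass(params)
  scaled <- c("k_R", "k_P", "gamma_P", "eta_R", "eta_P")
  if (scale_eta_G) scaled <- c(scaled, "eta_G")
  if (scale_gamma_R) scaled <- c(scaled, "gamma_R")
  for (nm in scaled) out[[nm]] <- out[[nm]] * f
  structure(out, class = "rate_params")
}

#' Activation scheme: full vs. partial activation
#'
#' Full activation assigns auxiliary activators at the stated stages
#' with strength `severity` relative to the primary activator at the
#' same stage (`eta = severity * k`).  Partial activation models the
#' loss of the auxiliary activators: every `eta` is zero regardless of
#' severity.
#'
#' @param mode `"full"` or `"partial"`.
#' @param auxiliary_stage character subset of
#'   `c("gene", "transcript", "protein")` naming the stages that carry
#'   an auxiliary activator.
#' @param severity non-negative ratio of auxiliary to primary rate
#'   constant.
#' @return An object of class `activation_scheme`.
#' @export
activation_scheme <- function(mode = c("full", "partial"),
                              auxiliary_stage = "transcript",
                              severity = 1) {
  mode <- match.arg(mode)
  stages <- c("gene", "transcript", "protein")
  if (!all(auxiliary_stage %in% stages))
    stop("auxiliary_stage must be a subset of ",
         paste(stages, collapse = ", "), call. = FALSE)
  if (!is.numeric(severity) || length(severity) != 1L || severity < 0)
    stop("severity must be a single non-negative number", call. = FALSE)
  structure(list(mode = mode, auxiliary_stage = auxiliary_stage,
                 severity = severity),
            class = "activation_scheme")
}

#' Apply an activation scheme to rate parameters
#'
#' Sets the auxiliary constants `eta_G`, `eta_R`, `eta_P` from the
#' scheme: `severity * k` at each stage carrying an auxiliary activator
#' under full activation, zero everywhere under partial activation.
#'
#' @param params a `rate_params` object (its `eta` fields are replaced).
#' @param scheme an `activation_scheme`.
#' @return A new `rate_params` object.
#' @export
apply_activation <- function(params, scheme) {
  stopifnot(inherits(scheme, "activation_scheme"))
  out <- unclass(params)
  out$eta_G <- out$eta_R <- out$eta_P <- 0
  if (scheme$mode == "full") {
    if ("gene" %in% scheme$auxiliary_stage)
      out$eta_G <- scheme$severity * out$k_G
    if ("transcript" %in% scheme$auxiliary_stage)
      out$eta_R <- scheme$severity * out$k_R
    if ("protein" %in% scheme$auxiliary_stage)
      out$eta_P <- scheme$severity * out$k_P
  }
  structure(out, class = "rate_params")
}

#' Default calibrated severities
#'
#' Severity values produced by [calibrate_severity()] at the default
#' rate parameters under normal metabolism (raw failure target 60% at
#' 5000 trajectories): one value per single-stage auxiliary activator,
#' plus `"all"` for the configuration with auxiliary activators at all
#' three stages (used as the parameter-sweep default, where partial
#' activation loses the whole auxiliary set).  Stored for convenience;
#' [calibrate_severity()] recomputes them from scratch.
#'
#' @param stage `"gene"`, `"transcript"`, `"protein"`, or `"all"`.
#' @return The calibrated severity (numeric scalar).
#' @export
default_severity <- function(stage = c("transcript", "gene", "protein",
                                       "all")) {
  stage <- match.arg(stage)
  .default_severities[[stage]]
}

# calibrate_severity("linear", default_rate_params(), step_input(),
#                    stage, seed = 101) per stage; see vignette
.default_severities <- list(gene = 0.78125, transcript = 1.0,
                            protein = 1.22265625, all = 0.25)

# flat numeric vector in the layout the C++ kernel expects
params_vector <- function(p) {
  c(p$k_G, p$gamma_G, p$k_R, p$gamma_R, p$k_P, p$gamma_P,
    p$eta_G, p$eta_R, p$eta_P, p$hill_H, p$hill_half_max,
    as.numeric(p$allele_bound))
}

#' @export
print.rate_params <- function(x, ...) {
  cat("rate_params:\n")
  v <- unlist(unclass(x))
  print(v)
  invisible(x)
}
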