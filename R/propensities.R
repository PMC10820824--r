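#' Reaction propensities
#'
#' Evaluates the rate of each of the six reaction channels at a given
#' state, for any of the three model variants.  This is the reference
#' (pure R) implementation of the rate laws; the stochastic simulator
#' uses an identical compiled kernel.
#'
#' Channels, in order: gene activation, gene deactivation,
#' transcription, mRNA decay, translation, protein decay.
#'
#' * `linear`: gene activation at `(k_G + eta_G) * stimulus`,
#'   unbounded activated-DNA deviation `D`; transcription at
#'   `(k_R + eta_R) * D`.
#' * `bounded`: `D` is the number of active gene copies `G_on`;
#'   activation at `(k_G + eta_G) * stimulus * G_off` with
#'   `G_off = allele_bound - G_on`; transcription proportional to
#'   `G_on`.
#' * `hill`: no explicit gene species; transcription driven directly by
#'   the stimulus through
#'   `stimulus^H / (stimulus^H + hill_half_max^H)`.
#'
#' @param state named numeric vector or list with elements `D`, `R`,
#'   `P` (non-negative integer counts; `D` is `G_on` for the bounded
#'   variant).
#' @param params a `rate_params` object.
#' @param stimulus stimulus level (dimensionless, non-negative).
#' @param variant `"linear"`, `"bounded"` or `"hill"`.
#' @return Named numeric vector of six non-negative propensities.
#' @export
propensities <- function(state, params, stimulus,
                         variant = c("linear", "bounded", "hill")) {
  variant <- match.arg(variant)
  D <- state[["D"]]; R <- state[["R"]]; P <- state[["P"]]
  if (any(c(D, R, P) < 0))
    stop("state counts must be non-negative", call. = FALSE)
  if (variant == "bounded" && D > params$allele_bound)
    stop("G_on exceeds allele_bound", call. = FALSE)
  kG <- params$k_G + params$eta_G
  kR <- params$k_R + params$eta_R
  kP <- params$k_P + params$eta_P
  a <- switch(variant,
    linear = c(gene_act = kG * stimulus,
               gene_deact = params$gamma_G * D,
               transcribe = kR * D),
    bounded = c(gene_act = kG * stimulus * (params$allele_bound - D),
                gene_deact = params$gamma_G * D,
                transcribe = kR * D),
    hill = c(gene_act = 0,
             gene_deact = 0,
             transcribe = kR * hill_drive(stimulus, params$hill_H,
                                          params$hill_half_max)))
  c(a,
    rna_decay = params$gamma_R * R,
    translate = kP * R,
    prot_decay = params$gamma_P * P)
}

#' Hill transcription drive
#'
#' Fraction of the maximal transcription rate at a given stimulus, for
#' Hill coefficient `H` and half-maximal stimulus `half_max` (0.5 for a
#' binary input).
#'
#' @param stimulus stimulus level (non-negative).
#' @param H Hill coefficient.
#' @param half_max stimulus at half-maximal drive.
#' @return Drive in `[0, 1)`; 0 at zero stimulus, 1/2 at `half_max`.
#' @export
hill_drive <- function(stimulus, H, half_max = 0.5) {
  ifelse(stimulus > 0,
         stimulus^H / (stimulus^H + half_max^H),
         0)
}

variant_code <- function(variant) {
  match(match.arg(variant, c("linear", "bounded", "hill")),
        c("linear", "bounded", "hill")) - 1L
}
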