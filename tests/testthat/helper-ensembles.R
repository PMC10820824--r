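# Build a minimal trajectory_ensemble from a trajectory x grid matrix
# of protein levels, for metric tests with hand-constructed peaks.
fake_ensemble <- function(P, grid = seq_len(ncol(P)) - 1,
                          input = step_input()) {
  structure(list(grid = grid, n = nrow(P), P = P, variant = "linear",
                 input = input, seed = 0L, horizon = max(grid)),
            class = "trajectory_ensemble")
}

# Last-value (piecewise-constant) evaluation of an event trajectory on
# a grid, the reference for grid-resampling checks.
eval_on_grid <- function(times, values, grid) {
  stats::approx(times, values, grid, method = "constant",
                f = 0, rule = 2)$y
}

# chi-square goodness-of-fit p-value of integer draws against a pmf
chisq_gof_p <- function(x, pmf, hi) {
  obs <- tabulate(factor(pmin(x, hi) + 1, levels = 1:(hi + 1)))
  pr <- pmf(0:hi)
  pr[hi + 1] <- 1 - sum(pr[-(hi + 1)])
  keep <- pr * length(x) > 5
  suppressWarnings(
    stats::chisq.test(obs[keep], p = pr[keep] / sum(pr[keep]))$p.value)
}
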