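# Shared fixtures, built once per test run and cached across test files.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) assign(name, builder(), envir = .fx)
  .fx[[name]]
}

# default study conditions: 5000 sets, 30% absent, tongs opening 0.5
sim_default <- function() fixture("sim_default", function() {
  simulate_chip(simulate_controls(sim_config()), seed = 1103)
})

qc_default <- function() fixture("qc_default", function() {
  qc_chip(sim_default()$chip)
})

# flat undegraded chip with identical probes per set (no decay, no noise)
flat_chip <- function(n_sets = 30, n = 11, pm = 100, mm = 100) {
  chip_data(data.frame(
    probeset_id = rep(sprintf("s%03d", seq_len(n_sets)), each = n),
    k = rep(seq_len(n), n_sets),
    L = rep(50 * (seq_len(n) - 1), n_sets),
    pm = pm, mm = mm))
}

# deterministic chip whose PM intensities follow an exact exponential decay
# in k; constant affinities, MM at a fixed fraction of PM
decay_chip <- function(n_sets = 60, n = 11, lambda = 4, I0 = 5000) {
  k <- rep(seq_len(n), n_sets)
  pm <- I0 * exp(-(k - 1) / lambda)
  chip_data(data.frame(
    probeset_id = rep(sprintf("s%03d", seq_len(n_sets)), each = n),
    k = k, L = 50 * (k - 1), pm = pm, mm = pm / 8))
}

# hand-built decay_profile from an explicit d(x) law
make_profile <- function(x, d, scale = "k", subset = "S") {
  out <- data.frame(x = x, logI = log10(d) + 3, d = d,
                    n = rep(100L, length(x)))
  attr(out, "scale") <- scale
  attr(out, "subset") <- subset
  attr(out, "ref_logI") <- 3
  class(out) <- c("decay_profile", "data.frame")
  out
}

# reference hook parameters used by the self-consistency tests
ref_fit <- function(alpha = 0.85, beta = 2, sigma_start = 1.5,
                    delta_start = 0) {
  list(alpha = alpha, beta = beta, sigma_start = sigma_start,
       delta_start = delta_start,
       logM = sigma_start + beta - delta_start / 2)
}

# noiseless hook curve generated from the theoretical model
theory_curve <- function(fit, n = 400) {
  g <- theoretical_hook(10^seq(-3, 7, length.out = n), fit)
  out <- g[c("sigma", "delta")]
  class(out) <- c("hook_curve", "data.frame")
  out
}
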