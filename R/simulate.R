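#' Simulation configuration
#'
#' Parameters of the synthetic-chip generator. The generator draws probe sets
#' with a linear 3'-to-5' layout, assigns each set a specific transcript
#' concentration (zero for the absent fraction, log-uniform over
#' `expr_decades` decades starting at the detection boundary otherwise),
#' applies a positional degradation law to the specific binding strengths and
#' the chip-mean degradation factor to the non-specific ones, and evaluates
#' the two-species hyperbolic Langmuir isotherm per probe.
#'
#' The defaults emulate sequence-corrected GeneChip data, the input the hook
#' analysis expects: residual (post-correction) probe-affinity spreads
#' `sigma_affinity_s`/`sigma_affinity_n` in log10, and multiplicative
#' measurement noise of sd `noise_sd` in log10. The default decay is a single
#' exponential on the index scale with initial shift `x0 = 2` probes, with
#' `lambda` solved so that the tongs opening equals 0.5.
#'
#' @param n_psets number of regular probe sets.
#' @param n_pset_size probes per set.
#' @param delta_L mean probe spacing (nt per index increment).
#' @param L1_range range of the position of the first (most 3') probe.
#' @param L_jitter uniform jitter (nt) applied to each probe position.
#' @param fraction_absent share of sets with zero specific concentration.
#' @param expr_decades width of the log-uniform expression distribution.
#' @param r_min specific/non-specific binding ratio of the weakest expressed
#'   sets (the detection boundary).
#' @param x_n mean non-specific binding strength (dimensionless).
#' @param alpha_true log10 PM/MM gap of specific binding.
#' @param sigma_affinity_s,sigma_affinity_n sd (log10) of per-probe specific /
#'   non-specific affinity factors.
#' @param M saturation intensity; `O` optical background; `w` washing factor.
#' @param noise_sd sd (log10) of multiplicative intensity noise.
#' @param decay list with `scale` ("k" or "L"), `lambda`, `d_inf`, `x0`
#'   describing the positional degradation law, or `NULL` for no degradation.
#' @param controls `NULL`, or a list with `genes` (labels), `n_probes` per
#'   set, `L_centers` (3'/middle/5' region centers in nt), `spacing` (nt
#'   between probes) and `expr` (specific binding ratio of the control
#'   transcript).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_psets = 5000, n_pset_size = 11, delta_L = 50,
                       L1_range = c(20, 100), L_jitter = 10,
                       fraction_absent = 0.3, expr_decades = 4, r_min = 0.1,
                       x_n = 10^-2.5, alpha_true = 0.85,
                       sigma_affinity_s = 0.20, sigma_affinity_n = 0.05,
                       M = 1e4, O = 0, w = 1, noise_sd = 0.05,
                       decay = decay_for_opening(0.5),
                       controls = NULL) {
  cfg <- list(n_psets = n_psets, n_pset_size = n_pset_size, delta_L = delta_L,
              L1_range = L1_range, L_jitter = L_jitter,
              fraction_absent = fraction_absent, expr_decades = expr_decades,
              r_min = r_min, x_n = x_n, alpha_true = alpha_true,
              sigma_affinity_s = sigma_affinity_s,
              sigma_affinity_n = sigma_affinity_n,
              M = M, O = O, w = w, noise_sd = noise_sd,
              decay = decay, controls = controls)
  stopifnot(n_psets >= 1, n_pset_size >= 3, delta_L > 0,
            fraction_absent >= 0, fraction_absent <= 1,
            x_n > 0, M > O, O >= 0, noise_sd >= 0, r_min > 0)
  class(cfg) <- "sim_config"
  cfg
}

# evaluate the truth decay law at raw positions (k or L), clamped to (0, 1]
.decay_eval <- function(decay, k, L) {
  if (is.null(decay)) return(rep(1, length(k)))
  x <- if (decay$scale == "k") k else L
  d <- (1 - decay$d_inf) * exp(-(x - decay$x0) / decay$lambda) + decay$d_inf
  pmin(d, 1)
}

#' Decay law producing a given tongs opening
#'
#' Solves for the exponential decay length on the index scale such that the
#' logged ratio of mean transcript coverage between the 3' subset (probes
#' 1..3) and the 5' subset (probes N-2..N) equals `dgamma`.
#'
#' @param dgamma target tongs opening (log10).
#' @param x0 initial shift in probes (probes at `k <= x0` are fully covered).
#' @param d_inf asymptotic coverage level.
#' @param n_pset_size probes per set.
#' @return decay list suitable for [sim_config()].
#' @export
decay_for_opening <- function(dgamma, x0 = 2, d_inf = 0, n_pset_size = 11) {
  if (dgamma <= 0) return(NULL)
  k <- seq_len(n_pset_size)
  f <- function(lam) {
    d <- pmin((1 - d_inf) * exp(-(k - x0) / lam) + d_inf, 1)
    log10(mean(d[1:3]) / mean(d[(n_pset_size - 2):n_pset_size])) - dgamma
  }
  lam <- stats::uniroot(f, c(0.05, 500), tol = 1e-10)$root
  list(scale = "k", lambda = lam, d_inf = d_inf, x0 = x0)
}

#' Simulate a GeneChip hybridization
#'
#' Generates one synthetic array under the two-species Langmuir isotherm with
#' positional degradation: per probe, the intensity is
#' `I = M (X^S w + X^N w)/(1 + X^S + X^N) + O`, where the specific binding
#' strength of probe `p` is scaled by its positional coverage `d_p` and the
#' non-specific strength by the chip-mean degradation factor `d` (degradation
#' dilutes the total RNA). Multiplicative log-normal noise is applied in
#' log10. Deterministic for a given seed.
#'
#' @param config a `sim_config`.
#' @param seed integer seed.
#' @return list with `chip` (a `chip_data`) and `truth` (list: per-set table
#'   `sets` with `probeset_id`, `s_target`, `r_nominal`, `regime`; per-probe
#'   `d_p`; chip-mean `d`; `dgamma` (tongs opening of the coverage law);
#'   `log_dk` (two-point ratio of the coverage law); `config` echo).
#' @export
simulate_chip <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_psets
  ns <- config$n_pset_size

  k <- rep(seq_len(ns), n)
  set_id <- rep(sprintf("ps%05d", seq_len(n)), each = ns)
  L1 <- rep(round(stats::runif(n, config$L1_range[1], config$L1_range[2])), each = ns)
  L <- L1 + config$delta_L * (k - 1L) +
    round(stats::runif(n * ns, -config$L_jitter, config$L_jitter))
  L <- pmax(L, 0L)

  absent <- rep(stats::runif(n) < config$fraction_absent, each = ns)
  lg_s <- log10(config$x_n * config$r_min) +
    stats::runif(n, 0, config$expr_decades)
  s_target <- rep(10^lg_s, each = ns)
  s_target[absent] <- 0

  d_p <- .decay_eval(config$decay, k, L)
  d_mean <- mean(d_p)

  aff_s <- 10^stats::rnorm(n * ns, 0, config$sigma_affinity_s)
  aff_n <- 10^stats::rnorm(n * ns, 0, config$sigma_affinity_n)

  x_s_pm <- s_target * d_p * aff_s
  x_s_mm <- x_s_pm * 10^(-config$alpha_true)
  x_n_p <- config$x_n * d_mean * aff_n

  iso <- function(xs, xn)
    config$M * (xs * config$w + xn * config$w) / (1 + xs + xn) + config$O
  pm <- iso(x_s_pm, x_n_p)
  mm <- iso(x_s_mm, x_n_p)
  if (config$noise_sd > 0) {
    pm <- pm * 10^stats::rnorm(n * ns, 0, config$noise_sd)
    mm <- mm * 10^stats::rnorm(n * ns, 0, config$noise_sd)
  }

  probes <- data.frame(probeset_id = set_id, k = k, L = as.integer(L),
                       pm = pm, mm = mm, is_control = FALSE,
                       control_region = "none")
  if (!is.null(config$controls))
    probes <- rbind(probes, .control_probes(config, d_mean))
  chip <- chip_data(probes)

  per_set_d3 <- tapply(d_p[k <= 3], set_id[k <= 3], mean)
  per_set_d5 <- tapply(d_p[k >= ns - 2], set_id[k >= ns - 2], mean)
  dgamma <- log10(mean(per_set_d3) / mean(per_set_d5))
  lo <- k <= 2; hi <- k >= ns - 1
  log_dk <- mean(log10(d_p[hi])) - mean(log10(d_p[lo]))

  truth <- list(
    sets = data.frame(probeset_id = sprintf("ps%05d", seq_len(n)),
                      s_target = 10^lg_s * !(absent[seq(1, n * ns, ns)]),
                      r_nominal = ifelse(absent[seq(1, n * ns, ns)], 0,
                                         10^lg_s / (config$x_n * d_mean)),
                      regime = ifelse(absent[seq(1, n * ns, ns)], "N", "expressed")),
    d_p = d_p, d = d_mean, dgamma = dgamma, log_dk = log_dk,
    config = config, seed = seed)
  list(chip = chip, truth = truth)
}

# 3'/middle/5' control probe sets on one long transcript, sharing the chip's
# positional coverage law (evaluated on the L-scale via delta_L)
.control_probes <- function(config, d_mean) {
  ctl <- config$controls
  out <- lapply(seq_along(ctl$genes), function(g) {
    gene <- ctl$genes[g]
    do.call(rbind, lapply(seq_along(ctl$L_centers), function(i) {
      region <- c("3prime", "middle", "5prime")[i]
      np <- ctl$n_probes
      L <- round(ctl$L_centers[i] - (np - 1) / 2 * ctl$spacing +
                   (seq_len(np) - 1) * ctl$spacing)
      k_eq <- L / config$delta_L + 1   # position in index units of the layout
      dec <- config$decay
      d_p <- if (is.null(dec)) rep(1, np)
        else if (dec$scale == "k") .decay_eval(dec, k_eq, L)
        else .decay_eval(dec, NA, L)
      xs <- ctl$expr * config$x_n * d_p
      xn <- config$x_n * d_mean
      pm <- config$M * (xs + xn) / (1 + xs + xn) + config$O
      mm <- config$M * (xs * 10^(-config$alpha_true) + xn) /
        (1 + xs * 10^(-config$alpha_true) + xn) + config$O
      if (config$noise_sd > 0) {
        pm <- pm * 10^stats::rnorm(np, 0, config$noise_sd)
        mm <- mm * 10^stats::rnorm(np, 0, config$noise_sd)
      }
      data.frame(probeset_id = paste0(gene, "-", region), k = seq_len(np),
                 L = as.integer(L), pm = pm, mm = mm, is_control = TRUE,
                 control_region = region)
    }))
  })
  do.call(rbind, out)
}

#' Add simulated control probe sets to a configuration
#'
#' Convenience helper configuring three control probe sets (3', middle, 5')
#' of 20 probes each on one long transcript.
#'
#' @param config a `sim_config`.
#' @param genes control gene labels.
#' @param expr specific binding ratio of the control transcript (relative to
#'   the non-specific level).
#' @param n_probes probes per control set.
#' @param L_centers region centers (nt from the 3'-end).
#' @param spacing nt between consecutive control probes.
#' @return the updated `sim_config`.
#' @export
simulate_controls <- function(config, genes = c("ctrlA", "ctrlB"), expr = 30,
                              n_probes = 20, L_centers = c(300, 650, 1000),
                              spacing = 3) {
  config$controls <- list(genes = genes, expr = expr, n_probes = n_probes,
                          L_centers = L_centers, spacing = spacing)
  config
}

#' Apparent 5'/3' intensity ratios in the linear and saturation limits
#'
#' Closed-form limits of the apparent degradation index
#' `r_app = I_5'/I_3'` of a probe pairing under the isotherm: in the linear
#' range `r_lin = (d_5' x^S_5' + d x^N_5')/(d_3' x^S_3' + d x^N_3')`, which
#' reduces to the true ratio `d_5'/d_3'` only when specific binding dominates
#' and becomes independent of degradation when non-specific binding dominates;
#' in the saturation range `r_sat = w_5'/w_3'` (unity for equal washing),
#' independent of degradation.
#'
#' @param d3,d5 coverage factors at the 3' and 5' probes.
#' @param d chip-mean degradation factor.
#' @param xs3,xs5 specific binding strengths at ideal concentration.
#' @param xn3,xn5 non-specific binding strengths.
#' @param w3,w5 washing survival factors.
#' @return list with `r_lin` and `r_sat`.
#' @export
apparent_ratio_limits <- function(d3, d5, d, xs3, xs5, xn3, xn5 = xn3,
                                  w3 = 1, w5 = 1) {
  list(r_lin = (d5 * xs5 * w5 + d * xn5 * w5) / (d3 * xs3 * w3 + d * xn3 * w3),
       r_sat = w5 / w3)
}
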