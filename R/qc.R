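#' Full degradation analysis of one array
#'
#' Runs the complete pipeline: hook transformation and smoothing, hook fit,
#' regime classification, tongs plot and degradation hook, tongs-opening fit,
#' positional decay profiles and fits for the specific and non-specific
#' ensembles, the two-point degradation ratio and its decay-length
#' conversions, the all-probe degradation slope, and (when control sets are
#' present) the control metrics with the variable threshold hook.
#'
#' For PM-only chips the hook and regime machinery is unavailable; the tongs
#' curves, the two-point ratio (over all sets) and the all-probe slope are
#' still computed, with the tongs opening taken as the curve maximum.
#'
#' @param chip a `chip_data` object.
#' @param base_window smoothing window (probe sets).
#' @param scale decay/correction scale, `"k"` or `"L"`.
#' @param control_threshold constant control threshold (log10; default
#'   `log10(3)`).
#' @param include_mix_upper include upper-mix sets in the specific ensemble.
#' @return object of class `deg_summary`; see the individual component
#'   functions for the fields.
#' @export
qc_chip <- function(chip, base_window = 1000, scale = c("k", "L"),
                    control_threshold = log10(3), include_mix_upper = TRUE) {
  scale <- match.arg(scale)
  has_L <- !anyNA(chip$probes$L)
  out <- list(pm_only = chip$pm_only, base_window = base_window,
              scale = scale)

  tongs <- tongs_and_deghook(chip, base_window)
  out$tongs <- tongs$tongs
  out$deghook <- tongs$deghook

  if (!chip$pm_only) {
    pts <- probeset_hook_points(chip)
    out$hook_curve <- moving_average(pts[c("sigma", "delta")], base_window)
    fit <- fit_hook(out$hook_curve)
    regimes <- chip_regimes(chip, fit)
    fit$pct_absent <- pct_absent(regimes)
    ei <- expression_index(regimes, fit)
    fit$phi <- ei$phi
    out$hook_fit <- fit
    out$regimes <- regimes
    out$tongs_fit <- fit_tongs_opening(out$deghook, fit)
    dgamma <- out$tongs_fit$dgamma
  } else {
    regimes <- NULL
    out$hook_fit <- NULL
    dgamma <- max(out$deghook$dsig_35)
    out$tongs_fit <- list(dgamma = dgamma, dgamma_max = dgamma,
                          converged = FALSE, fallback = TRUE)
  }
  out$dgamma <- dgamma
  out$d_tongs <- d_from_tongs(dgamma)
  out$mean_log_d <- mean_log_d(dgamma)

  out$profile_s_k <- tryCatch(
    decay_profile(chip, regimes, "S", "k",
                  include_mix_upper = include_mix_upper),
    error = function(e) NULL)
  out$profile_n_k <- tryCatch(decay_profile(chip, regimes, "N", "k"),
                              error = function(e) NULL)
  out$decay_fit_k <- if (!is.null(out$profile_s_k))
    tryCatch(fit_decay(out$profile_s_k), error = function(e) NULL)
  if (has_L && !is.null(regimes)) {
    out$profile_s_L <- tryCatch(
      decay_profile(chip, regimes, "S", "L",
                    include_mix_upper = include_mix_upper),
      error = function(e) NULL)
    out$decay_fit_L <- if (!is.null(out$profile_s_L))
      tryCatch(fit_decay(out$profile_s_L), error = function(e) NULL)
  }

  dk <- tryCatch(degradation_ratio_dk(chip, regimes, include_mix_upper),
                 error = function(e) list(log_dk = NA_real_, n_sets = 0L,
                                          low_confidence = TRUE))
  out$log_dk <- dk$log_dk
  out$dk_n_sets <- dk$n_sets
  if (has_L) {
    out$spacing <- mean_probe_spacing(chip)
    if (is.finite(dk$log_dk) && dk$log_dk < 0) {
      lam <- suppressWarnings(lambda_from_dk(dk$log_dk, out$spacing$slope))
      out$lambda_k <- lam$lambda_k
      out$lambda_L <- lam$lambda_L
    }
  } else if (is.finite(dk$log_dk) && dk$log_dk < 0) {
    out$lambda_k <- lambda_from_dk(dk$log_dk, 1)$lambda_k
  }

  slp <- affyslope(chip)
  out$affyslope <- slp$slope
  out$affy_profile <- slp$profile

  if (any(chip$probes$is_control) && !is.null(out$hook_fit)) {
    out$controls <- control_metrics(chip)
    out$threshold_hook <- build_threshold_hook(out$hook_fit, control_threshold)
    out$control_verdict <- classify_controls(
      data.frame(sigma = out$controls$sigma_sum,
                 delta = out$controls$delta_35),
      out$threshold_hook)
  }
  if (!is.null(regimes) && has_L)
    out$sn_histograms <- sn_positional_histograms(chip, regimes,
                                                  include_mix_upper = include_mix_upper)
  class(out) <- "deg_summary"
  out
}

#' @export
print.deg_summary <- function(x, ...) {
  cat("Degradation summary\n")
  if (!is.null(x$hook_fit)) {
    cat(sprintf("  hook: alpha = %.3f, beta = %.3f, Sigma_start = %.3f, logM = %.3f\n",
                x$hook_fit$alpha, x$hook_fit$beta, x$hook_fit$sigma_start,
                x$hook_fit$logM))
    cat(sprintf("  %%N = %.1f%%, phi = %.3f\n",
                100 * x$hook_fit$pct_absent, x$hook_fit$phi))
  } else cat("  PM-only chip: hook fit unavailable\n")
  cat(sprintf("  tongs opening dgamma_3'/5' = %.3f (d_tongs = %.3f, mean log d = %.3f)\n",
              x$dgamma, x$d_tongs, x$mean_log_d))
  cat(sprintf("  two-point log d^k = %.3f over %d sets\n", x$log_dk, x$dk_n_sets))
  if (!is.null(x$lambda_k))
    cat(sprintf("  decay lengths: lambda_k = %.2f probes, lambda_L = %.0f nt\n",
                x$lambda_k, if (is.null(x$lambda_L)) NA else x$lambda_L))
  cat(sprintf("  all-probe slope (affyslope) = %.4f per index\n", x$affyslope))
  if (!is.null(x$control_verdict))
    cat(sprintf("  controls: TP %d / FP %d / TN %d (PPV %.2f, SP %.2f)\n",
                x$control_verdict$tp, x$control_verdict$fp,
                x$control_verdict$tn, x$control_verdict$ppv,
                x$control_verdict$sp))
  invisible(x)
}

#' Scalar summary record of a degradation analysis
#'
#' Flattens a `deg_summary` into a named list of scalar quality metrics with
#' deterministic field order, suitable for serialization.
#'
#' @param x a `deg_summary`.
#' @return named list of scalars.
#' @export
summary_record <- function(x) {
  stopifnot(inherits(x, "deg_summary"))
  rec <- list(
    dgamma_35 = x$dgamma,
    dgamma_35_curve_max = x$tongs_fit$dgamma_max,
    d_tongs = x$d_tongs,
    mean_log_d = x$mean_log_d,
    log_dk = x$log_dk,
    dk_n_sets = x$dk_n_sets,
    lambda_k = if (is.null(x$lambda_k)) NA_real_ else x$lambda_k,
    lambda_L = if (is.null(x$lambda_L)) NA_real_ else x$lambda_L,
    affyslope = x$affyslope,
    alpha = if (is.null(x$hook_fit)) NA_real_ else x$hook_fit$alpha,
    beta = if (is.null(x$hook_fit)) NA_real_ else x$hook_fit$beta,
    sigma_start = if (is.null(x$hook_fit)) NA_real_ else x$hook_fit$sigma_start,
    logM = if (is.null(x$hook_fit)) NA_real_ else x$hook_fit$logM,
    pct_absent = if (is.null(x$hook_fit)) NA_real_ else x$hook_fit$pct_absent,
    phi = if (is.null(x$hook_fit)) NA_real_ else x$hook_fit$phi,
    decay_lambda_k = if (is.null(x$decay_fit_k)) NA_real_ else x$decay_fit_k$lambda,
    decay_x0_k = if (is.null(x$decay_fit_k)) NA_real_ else x$decay_fit_k$x0,
    decay_lambda_L = if (is.null(x$decay_fit_L)) NA_real_ else x$decay_fit_L$lambda,
    decay_d_inf_L = if (is.null(x$decay_fit_L)) NA_real_ else x$decay_fit_L$d_inf,
    control_ppv = if (is.null(x$control_verdict)) NA_real_ else x$control_verdict$ppv,
    control_sp = if (is.null(x$control_verdict)) NA_real_ else x$control_verdict$sp)
  rec
}
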