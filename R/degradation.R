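#' Positional subset average of a probe set
#'
#' Averages `Sigma` over three consecutive probes of one probe set: the three
#' nearest the transcript 3'-end (`s = "3prime"`, indices 1..3), the three
#' most distant (`s = "5prime"`, indices N-2..N), or three centered about the
#' middle probe (`s = "middle"`, defined for sets of at least 5 probes).
#'
#' @param sigma per-probe `Sigma` values of one probe set, ordered by `k`.
#' @param s subset selector.
#' @return mean `Sigma` over the selected three probes.
#' @export
subset_sigma <- function(sigma, s = c("3prime", "middle", "5prime")) {
  s <- match.arg(s)
  n <- length(sigma)
  if (n < 3) stop("probe set too small for subset statistics (need >= 3)")
  switch(s,
         "3prime" = mean(sigma[1:3]),
         "5prime" = mean(sigma[(n - 2):n]),
         "middle" = {
           if (n < 5) stop("middle subset requires a set of >= 5 probes")
           im <- (n + 1L) %/% 2L
           mean(sigma[(im - 1L):(im + 1L)])
         })
}

#' Tongs plot and degradation hook
#'
#' Computes, per probe set, the differences between positional subset averages
#' and the set mean (`dsig_3`, `dsig_m`, `dsig_5`; the tongs branches) and the
#' 3'-5' difference `dsig_35` (the degradation hook ordinate), then smooths
#' them against the hook abscissa `Sigma` with a tail-shrinking moving window.
#' The branches coincide near the non-specific level and split with increasing
#' specific hybridization; the maximal split measures the 3' intensity bias.
#'
#' @param chip a `chip_data` object.
#' @param base_window,shrink_tail smoothing parameters, see [moving_average()].
#' @return list with `tongs` (smoothed `sigma`, `dsig_3`, `dsig_m`, `dsig_5`),
#'   `deghook` (smoothed `sigma`, `dsig_35`) and the per-set values in `sets`.
#' @export
tongs_and_deghook <- function(chip, base_window = 1000, shrink_tail = TRUE) {
  st <- pset_stats(chip)
  st <- st[order(st$sigma), , drop = FALSE]
  sets <- data.frame(probeset_id = st$probeset_id, sigma = st$sigma,
                     dsig_3 = st$sigma_3 - st$sigma,
                     dsig_m = st$sigma_m - st$sigma,
                     dsig_5 = st$sigma_5 - st$sigma,
                     dsig_35 = st$sigma_3 - st$sigma_5)
  deghook <- moving_average(sets[c("sigma", "dsig_35")], base_window, shrink_tail)
  has_m <- !is.na(sets$dsig_m)
  if (!all(has_m))
    message(sum(!has_m), " set(s) without middle subset excluded from tongs branches")
  tongs <- moving_average(sets[has_m, c("sigma", "dsig_3", "dsig_m", "dsig_5")],
                          base_window, shrink_tail)
  class(tongs) <- c("tongs_curve", class(tongs))
  class(deghook) <- c("deghook_curve", class(deghook))
  list(tongs = tongs, deghook = deghook, sets = sets)
}

#' Theoretical tongs / degradation-hook ordinate
#'
#' Evaluates the model difference between the hook `Sigma` coordinates of two
#' probe subsets whose specific transcript concentrations differ by the factors
#' `10^gamma_1` and `10^gamma_2`:
#' \deqn{\Delta\Sigma_{s1/s2}(R) =
#'   \tfrac12\log\frac{(R_1+1)(R_1 10^{-\alpha}+1)}{(R_2+1)(R_2 10^{-\alpha}+1)}
#'   - \tfrac12\log\frac{B^{PM}(R_1)B^{MM}(R_1)}{B^{PM}(R_2)B^{MM}(R_2)}}
#' with `R_i = R 10^{gamma_i}`. With `gamma_2 = 0` this is a single tongs
#' branch relative to the set average; the degradation-hook curve uses
#' `gamma_1 = gamma_3'`, `gamma_2 = gamma_5'`. The ordinate vanishes in both
#' the purely non-specific (`R -> 0`) and asymptotic saturation (`R -> Inf`)
#' limits and reaches its maximum (about `gamma_1 - gamma_2` when saturation
#' is negligible) in the specific range.
#'
#' @param R non-negative binding ratio(s) of the whole probe set.
#' @param fit a `hook_fit` (or list with `alpha`, `beta`, `sigma_start`,
#'   `delta_start`).
#' @param gamma_1,gamma_2 log10 concentration biases of the two subsets.
#' @return data.frame with columns `R`, `sigma` (whole-set hook abscissa) and
#'   `dsig` (the ordinate).
#' @export
theoretical_tongs <- function(R, fit, gamma_1, gamma_2 = 0) {
  stopifnot(all(R >= 0))
  a <- 10^(-fit$alpha)
  ds <- if (is.null(fit$delta_start)) 0 else fit$delta_start
  bfac <- 10^(-fit$beta + ds / 2)
  half_log <- function(r)
    (log1p(r) + log1p(r * a)) / (2 * LOG10) -
      (log1p(bfac * (r + 1)) + log1p(bfac * (r * a + 1))) / (2 * LOG10)
  data.frame(R = R,
             sigma = theoretical_hook(R, fit)$sigma,
             dsig = half_log(R * 10^gamma_1) - half_log(R * 10^gamma_2))
}

#' Tongs-opening estimate from the degradation hook
#'
#' Least-squares fit of the theoretical degradation-hook curve to the smoothed
#' experimental one, with the subset concentration biases `gamma_3'` and
#' `gamma_5'` free and the hook-shape parameters taken from the standard hook
#' fit. The observed abscissa is mapped onto the latent binding ratio by
#' monotone inversion of the fitted `Sigma(R)`. Returns the tongs opening
#' `dgamma = gamma_3' - gamma_5'`; the maximum of the smoothed curve is
#' reported separately as a model-free fallback (and returned as the primary
#' value, flagged, if the fit does not converge).
#'
#' @param deghook smoothed degradation hook (`sigma`, `dsig_35`), from
#'   [tongs_and_deghook()].
#' @param fit a `hook_fit`.
#' @return object of class `tongs_fit`: list with `dgamma`, `gamma_3`,
#'   `gamma_5`, `dgamma_max`, `converged`, `fallback`.
#' @export
fit_tongs_opening <- function(deghook, fit) {
  dmax <- max(deghook$dsig_35)
  R_obs <- invert_sigma(deghook$sigma, fit)
  resid_fun <- function(par)
    theoretical_tongs(R_obs, fit, par[1], par[2])$dsig - deghook$dsig_35
  init <- c(gamma_3 = max(dmax, 0.02) / 2, gamma_5 = -max(dmax, 0.02) / 2)
  ans <- try(minpack.lm::nls.lm(
    par = init, fn = resid_fun, lower = c(-2, -2), upper = c(2, 2),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12)),
    silent = TRUE)
  if (inherits(ans, "try-error") || ans$info == 0 || ans$info == 9) {
    warning("tongs fit did not converge; falling back to the curve maximum")
    out <- list(dgamma = dmax, gamma_3 = NA_real_, gamma_5 = NA_real_,
                dgamma_max = dmax, converged = FALSE, fallback = TRUE)
  } else {
    out <- list(dgamma = unname(ans$par[1] - ans$par[2]),
                gamma_3 = unname(ans$par[1]), gamma_5 = unname(ans$par[2]),
                dgamma_max = dmax, converged = TRUE, fallback = FALSE)
  }
  class(out) <- "tongs_fit"
  out
}

#' @export
print.tongs_fit <- function(x, ...) {
  cat(sprintf("tongs_fit: dgamma_3'/5' = %.3f (curve max %.3f%s)\n",
              x$dgamma, x$dgamma_max,
              if (x$fallback) ", fallback" else ""))
  invisible(x)
}

#' 5'/3' concentration ratio from the tongs opening
#' @param dgamma tongs opening (log10 scale).
#' @return `10^(-dgamma)`, the ratio of transcript concentration at the 5'
#'   probes relative to the 3' probes.
#' @export
d_from_tongs <- function(dgamma) 10^(-dgamma)

#' Mean logged degradation index from the tongs opening
#'
#' Under uniformly distributed probes the chip-mean transcript concentration is
#' approximately the geometric mean of the 3' and 5' subset concentrations, so
#' the mean logged degradation index is about half the (negated) tongs opening.
#'
#' @param dgamma tongs opening (log10 scale).
#' @return `-0.5 * dgamma`.
#' @export
mean_log_d <- function(dgamma) -0.5 * dgamma

#' Regime table for a chip
#'
#' Per-probe-set regime classification (see [classify_regimes()]) joined with
#' the probe-set identifiers and layout summaries.
#'
#' @param chip a `chip_data` object.
#' @param fit a `hook_fit`.
#' @return data.frame with `probeset_id`, `sigma`, `y_pm`, `L_first`, `L_max`,
#'   `R`, `label`.
#' @export
chip_regimes <- function(chip, fit) {
  st <- pset_stats(chip)
  cl <- classify_regimes(st$sigma, fit)
  data.frame(probeset_id = st$probeset_id, sigma = st$sigma, y_pm = st$y_pm,
             L_first = st$L_first, L_max = st$L_max,
             R = cl$R, label = cl$label)
}

# probe-set ids of the specific (or non-specific) ensemble
.subset_ids <- function(regimes, subset, include_mix_upper = TRUE) {
  switch(subset,
         S = {
           sel <- regimes$label == "S"
           if (include_mix_upper)
             sel <- sel | (regimes$label == "mix" & regimes$R >= 10^-0.5)
           regimes$probeset_id[sel]
         },
         N = regimes$probeset_id[regimes$label == "N"],
         all = regimes$probeset_id)
}

#' Positional intensity-decay profile
#'
#' Mean log10 PM intensity of the selected probe ensemble as a function of
#' probe position, on the index scale (`x = k`) or the nucleotide scale
#' (`x = L`, binned with width `bin_width`). The normalized profile
#' `d(x) = I(x)/I(3')` uses as 3'-reference the geometric mean intensity at
#' `k = 1, 2` (k-scale) or the first populated bin below 150 nt (L-scale).
#'
#' @param chip a `chip_data` object.
#' @param regimes regime table from [chip_regimes()], or `NULL` to use all
#'   probe sets.
#' @param subset `"S"`, `"N"` or `"all"`: ensemble selected by hybridization
#'   regime (the specific ensemble includes the upper mix range when
#'   `include_mix_upper`).
#' @param scale `"k"` (probe index) or `"L"` (nucleotides).
#' @param bin_width L-scale bin width in nucleotides.
#' @param min_count suppress L-bins with fewer probes than this.
#' @param include_mix_upper include mix-regime sets with `R >= 10^-0.5` in the
#'   specific ensemble.
#' @return object of class `decay_profile`: data.frame with columns `x`,
#'   `logI`, `d`, `n`; attributes `scale`, `subset`, `ref_logI`.
#' @export
decay_profile <- function(chip, regimes = NULL, subset = c("S", "N", "all"),
                          scale = c("k", "L"), bin_width = 25,
                          min_count = 20, include_mix_upper = TRUE) {
  subset <- match.arg(subset)
  scale <- match.arg(scale)
  p <- chip$probes[!chip$probes$is_control, , drop = FALSE]
  if (!is.null(regimes)) {
    ids <- .subset_ids(regimes, subset, include_mix_upper)
    p <- p[p$probeset_id %in% ids, , drop = FALSE]
  } else if (subset != "all") {
    stop("regime table required to select the ", subset, " ensemble")
  }
  if (!nrow(p)) stop("empty probe ensemble for subset '", subset, "'")
  logI <- log10(p$pm)
  if (scale == "k") {
    x <- sort(unique(p$k))
    m <- tapply(logI, factor(p$k, levels = x), mean)
    n <- as.integer(table(factor(p$k, levels = x)))
    ref <- mean(m[x %in% c(1, 2)])
  } else {
    if (anyNA(p$L)) stop("probe positions L missing; cannot bin on L-scale")
    bin <- floor(p$L / bin_width)
    m_all <- tapply(logI, bin, mean)
    n_all <- as.integer(table(bin))
    keep <- n_all >= min_count
    if (!any(keep)) stop("no L-bin reaches min_count = ", min_count)
    x <- (as.numeric(names(m_all)) + 0.5) * bin_width
    m <- m_all[keep]; n <- n_all[keep]; x <- x[keep]
    below <- which(x < 150)
    ref <- if (length(below)) m[below[1]] else m[1]
  }
  out <- data.frame(x = as.numeric(x), logI = as.numeric(m),
                    d = 10^(as.numeric(m) - ref), n = n)
  attr(out, "scale") <- scale
  attr(out, "subset") <- subset
  attr(out, "ref_logI") <- as.numeric(ref)
  class(out) <- c("decay_profile", "data.frame")
  out
}

#' Fit a shifted-exponential-plus-constant decay
#'
#' Nonlinear least squares of
#' `d(x) = (1 - d_inf) * exp(-(x - x0)/lambda) + d_inf`
#' to a normalized decay profile. On the index scale the fit argument is the
#' offset from the 3'-reference probe (`x = k - 1`) and `d_inf` is fixed to 0
#' by default (the index scale compresses the asymptotic range into the last
#' probes); on the nucleotide scale the default fit range is `100 < L < 600`
#' (the sparsely populated far range behaves differently and is excluded).
#'
#' @param profile a `decay_profile`.
#' @param fit_range numeric length-2 interval of raw `x` values used in the
#'   fit; `NULL` for the scale default.
#' @param fix_d_inf fix the asymptotic level (`0` on the k-scale by default;
#'   `NULL` to fit it).
#' @param clamp cap the model at 1 inside the fit (coverage cannot exceed the
#'   3' level); used for profiles with a flat 3' head.
#' @return object of class `decay_fit`: list with `lambda`, `d_inf`, `x0`
#'   (in fit coordinates: `k - 1` on the index scale, nucleotides on the
#'   L-scale), `scale`, `fit_range`, `residual_norm`, `at_bound`, `n_bins`.
#' @export
fit_decay <- function(profile, fit_range = NULL, fix_d_inf = NULL,
                      clamp = FALSE) {
  scale <- attr(profile, "scale")
  if (is.null(fit_range))
    fit_range <- if (scale == "L") c(100, 600) else range(profile$x)
  if (is.null(fix_d_inf) && scale == "k") fix_d_inf <- 0
  sel <- profile$x >= fit_range[1] & profile$x <= fit_range[2]
  d <- profile$d[sel]
  x <- profile$x[sel] - if (scale == "k") 1 else 0
  if (length(d) < 5)
    stop("need >= 5 populated bins in the fit range (have ", length(d), ")")

  dinf0 <- if (is.null(fix_d_inf)) max(0, 0.9 * min(d)) else fix_d_inf
  pos <- d - dinf0 > 0.02
  lam0 <- 1
  x00 <- max(0, x[1])
  if (sum(pos) >= 2) {
    lf <- stats::lm(log(d[pos] - dinf0) ~ x[pos])
    sl <- stats::coef(lf)[2]
    if (is.finite(sl) && sl < 0) {
      lam0 <- -1 / sl
      x00 <- max(0, stats::coef(lf)[1] * lam0)
    } else lam0 <- diff(range(x)) * 2
  }
  free_dinf <- is.null(fix_d_inf)
  par <- c(lambda = lam0, x0 = x00, if (free_dinf) c(d_inf = dinf0))
  lower <- c(1e-6, 0, if (free_dinf) 0)
  upper <- c(1e6, max(x) + 1, if (free_dinf) 1)
  model <- function(p, xx) {
    di <- if (free_dinf) p[3] else fix_d_inf
    m <- (1 - di) * exp(-(xx - p[2]) / p[1]) + di
    if (clamp) pmin(m, 1) else m
  }
  ans <- minpack.lm::nls.lm(
    par = par, fn = function(p) model(p, x) - d,
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-14, ptol = 1e-14))
  if (ans$info == 0 || ans$info == 9)
    stop("decay fit did not converge; residual norm ",
         signif(sqrt(ans$deviance), 4))
  p <- ans$par
  # x0 = 0 (no initial shift) and d_inf = 0 are natural boundaries; flag only
  # a decay length or asymptote pinned at its limit
  at_bound <- abs(p[1] - lower[1]) < 1e-9 || abs(p[1] - upper[1]) < 1e-9 ||
    (free_dinf && abs(p[3] - 1) < 1e-9)
  if (at_bound) warning("decay-fit parameter at bound")
  out <- list(lambda = unname(p[1]),
              d_inf = if (free_dinf) unname(p[3]) else fix_d_inf,
              x0 = unname(p[2]),
              scale = scale, fit_range = fit_range,
              residual_norm = sqrt(ans$deviance / length(d)),
              at_bound = at_bound, n_bins = length(d))
  class(out) <- "decay_fit"
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("decay_fit (%s-scale): lambda = %.4g, d_inf = %.3f, x0 = %.3g\n",
              x$scale, x$lambda, x$d_inf, x$x0))
  invisible(x)
}

#' Evaluate a fitted decay at probe positions
#' @param object a `decay_fit`.
#' @param x raw positions (probe index `k` or nucleotide distance `L`,
#'   matching the fitted scale).
#' @param ... unused.
#' @return predicted `d(x)` values.
#' @export
predict.decay_fit <- function(object, x, ...) {
  xx <- if (object$scale == "k") x - 1 else x
  (1 - object$d_inf) * exp(-(xx - object$x0) / object$lambda) + object$d_inf
}

#' Two-point degradation ratio
#'
#' Robust summary of the positional intensity decay of the specific ensemble:
#' the mean log10 PM intensity over the last two probe indices of each set
#' minus the mean over the first two (so `log_dk <= 0` for degraded RNA).
#'
#' @param chip a `chip_data` object.
#' @param regimes regime table from [chip_regimes()] (`NULL` uses all sets,
#'   the PM-only fallback).
#' @param include_mix_upper see [decay_profile()].
#' @return list with `log_dk`, `n_sets`, `low_confidence` (TRUE when fewer
#'   than 50 sets contribute).
#' @export
degradation_ratio_dk <- function(chip, regimes = NULL, include_mix_upper = TRUE) {
  p <- chip$probes[!chip$probes$is_control, , drop = FALSE]
  if (!is.null(regimes)) {
    ids <- .subset_ids(regimes, "S", include_mix_upper)
    p <- p[p$probeset_id %in% ids, , drop = FALSE]
  }
  if (!nrow(p)) stop("no specific probe sets for the degradation ratio")
  kmax <- stats::ave(p$k, p$probeset_id, FUN = max)
  hi <- p$k >= kmax - 1
  lo <- p$k <= 2
  log_dk <- mean(log10(p$pm[hi])) - mean(log10(p$pm[lo]))
  n_sets <- length(unique(p$probeset_id))
  low <- n_sets < 50
  if (low) warning("only ", n_sets,
                   " probe sets contribute to d^k; low confidence")
  if (log_dk > 0.05)
    warning("log d^k > 0.05: 5' probes brighter than 3' probes")
  list(log_dk = log_dk, n_sets = n_sets, low_confidence = low)
}

#' Decay lengths from the two-point degradation ratio
#'
#' Converts the two-point ratio into exponential decay lengths using the
#' printed index span of 8: `lambda_k = -8 / ln(10^log_dk)` (sign fixed so
#' that `lambda > 0`) and `lambda_L = lambda_k * <dL>`.
#'
#' @param log_dk two-point ratio (log10; must be negative).
#' @param delta_L mean probe spacing in nucleotides per index increment.
#' @return list with `lambda_k` (probes) and `lambda_L` (nucleotides); both
#'   `NA` with a warning when `log_dk >= 0`.
#' @export
lambda_from_dk <- function(log_dk, delta_L) {
  if (log_dk >= 0) {
    warning("log d^k >= 0: decay length undefined")
    return(list(lambda_k = NA_real_, lambda_L = NA_real_))
  }
  lambda_k <- -8 / (log_dk * LOG10)
  list(lambda_k = lambda_k, lambda_L = lambda_k * delta_L)
}

#' All-probe RNA degradation plot and slope
#'
#' Mean log10 PM intensity per probe index over all probes of the array,
#' together with the ordinary least-squares slope versus `k`. This is the
#' legacy QC measure; it dilutes the positional decay by the non-responsive
#' absent probes and therefore underestimates degradation when the absent
#' fraction is large. Provided for comparison with the specific-ensemble
#' profile.
#'
#' @param chip a `chip_data` object.
#' @return list with `profile` (data.frame `k`, `logI`, `n`) and `slope`.
#' @export
affyslope <- function(chip) {
  p <- chip$probes[!chip$probes$is_control, , drop = FALSE]
  ks <- sort(unique(p$k))
  m <- tapply(log10(p$pm), factor(p$k, levels = ks), mean)
  prof <- data.frame(k = ks, logI = as.numeric(m),
                     n = as.integer(table(factor(p$k, levels = ks))))
  list(profile = prof,
       slope = unname(stats::coef(stats::lm(logI ~ k, data = prof))[2]))
}

#' Positional histograms of specific and non-specific probe sets
#'
#' Fractions of probe sets in the specific (S) and non-specific (N) ensembles
#' as a function of the position of their first and last probe, each
#' normalized within its ensemble, together with the N - S difference and the
#' difference relative to the mean fraction. Probe sets covering only the
#' region near the 3'-end are typically enriched in the N ensemble.
#'
#' @param chip a `chip_data` object.
#' @param regimes regime table from [chip_regimes()].
#' @param breaks bin breaks for the positions (shared by both variables).
#' @param include_mix_upper see [decay_profile()].
#' @return list with data.frames `L_first` and `L_max`, each with columns
#'   `bin_lo`, `bin_hi`, `frac_S`, `frac_N`, `diff`, `rel_diff`.
#' @export
sn_positional_histograms <- function(chip, regimes,
                                     breaks = c(seq(0, 1000, 100), Inf),
                                     include_mix_upper = TRUE) {
  ids_S <- .subset_ids(regimes, "S", include_mix_upper)
  ids_N <- .subset_ids(regimes, "N")
  one <- function(values) {
    vs <- values[regimes$probeset_id %in% ids_S]
    vn <- values[regimes$probeset_id %in% ids_N]
    cs <- table(cut(vs, breaks, right = FALSE))
    cn <- table(cut(vn, breaks, right = FALSE))
    fs <- if (length(vs)) as.numeric(cs) / length(vs) else as.numeric(cs) * 0
    fn <- if (length(vn)) as.numeric(cn) / length(vn) else as.numeric(cn) * 0
    mid <- (fs + fn) / 2
    data.frame(bin_lo = utils::head(breaks, -1), bin_hi = breaks[-1],
               frac_S = fs, frac_N = fn, diff = fn - fs,
               rel_diff = ifelse(mid > 0, (fn - fs) / mid, 0))
  }
  list(L_first = one(regimes$L_first), L_max = one(regimes$L_max))
}
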