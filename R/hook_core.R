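LOG10 <- log(10)

#' Hook coordinates of a probe pair
#'
#' Transforms linear PM/MM intensities into the hook coordinates
#' `Sigma = (log10 pm + log10 mm)/2` (total signal) and
#' `Delta = log10 pm - log10 mm` (PM/MM contrast). All logarithms in this
#' package are decadic.
#'
#' @param pm,mm positive linear-scale intensities (vectorized).
#' @return list with numeric vectors `sigma` and `delta`.
#' @export
sigma_delta <- function(pm, mm) {
  bad <- which(pm <= 0 | mm <= 0)
  if (length(bad))
    stop("non-positive intensity at probe(s) ", paste(utils::head(bad, 5), collapse = ", "))
  lp <- log10(pm); lm_ <- log10(mm)
  list(sigma = (lp + lm_) / 2, delta = lp - lm_)
}

# Per-probe-set summary used by the hook, tongs and correction machinery.
# For PM-only chips Sigma_p falls back to log10(pm).
pset_stats <- function(chip, controls = FALSE) {
  p <- chip$probes
  if (!controls) p <- p[!p$is_control, , drop = FALSE]
  if (!nrow(p)) stop("no probe sets available")
  if (chip$pm_only) {
    sig_p <- log10(p$pm)
    del_p <- rep(NA_real_, nrow(p))
  } else {
    sd_ <- sigma_delta(p$pm, p$mm)
    sig_p <- sd_$sigma
    del_p <- sd_$delta
  }
  sp <- split(seq_len(nrow(p)), p$probeset_id)
  res <- lapply(sp, function(idx) {
    o <- idx[order(p$k[idx])]
    n <- length(o)
    s <- sig_p[o]
    im <- (n + 1L) %/% 2L
    data.frame(
      probeset_id = p$probeset_id[o[1]],
      n = n,
      sigma = mean(s),
      delta = if (chip$pm_only) NA_real_ else mean(del_p[o]),
      y_pm = mean(log10(p$pm[o])),
      y_mm = if (chip$pm_only) NA_real_ else mean(log10(p$mm[o])),
      sigma_3 = mean(s[1:3]),
      sigma_m = if (n >= 5) mean(s[(im - 1L):(im + 1L)]) else NA_real_,
      sigma_5 = mean(s[(n - 2L):n]),
      L_first = p$L[o[1]],
      L_max = p$L[o[n]],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-set hook points
#'
#' Averages the probe-level hook coordinates over each probe set:
#' `Delta` is the set mean of the per-probe PM/MM contrast and `Sigma` the set
#' mean of the per-probe total signal. Sets are returned sorted by `Sigma`,
#' the order in which the hook curve is smoothed.
#'
#' @param chip a `chip_data` object (PM/MM).
#' @return data.frame with one row per probe set, sorted by `sigma`.
#' @export
probeset_hook_points <- function(chip) {
  if (chip$pm_only) stop("hook points require MM intensities (PM-only chip)")
  st <- pset_stats(chip)
  st[order(st$sigma), , drop = FALSE]
}

#' Moving-average smoothing along the hook abscissa
#'
#' Centered moving average over points already sorted by the first column.
#' Only positions where the full window fits are emitted. With
#' `shrink_tail = TRUE` the window decays linearly from `base_window` to
#' `base_window/10` over the top 5% of ranks, compensating for the sparse
#' population of the saturation range.
#'
#' @param points data.frame sorted by its first column; all numeric columns
#'   are smoothed.
#' @param base_window window size in points (default 1000).
#' @param shrink_tail shrink the window towards the right end (default TRUE).
#' @return object of class `hook_curve`: the smoothed data.frame plus a
#'   `window` column of per-point window sizes.
#' @export
moving_average <- function(points, base_window = 1000, shrink_tail = TRUE) {
  if (!nrow(points)) stop("no points to smooth")
  n <- nrow(points)
  w <- min(base_window, n)
  if (w < base_window)
    message("window shrunk to ", w, " (only ", n, " points)")
  ranks <- seq_len(n) / n
  win <- rep(w, n)
  if (shrink_tail) {
    tail_idx <- ranks > 0.95
    frac <- (ranks[tail_idx] - 0.95) / 0.05
    win[tail_idx] <- pmax(3, round(w * (1 - 0.9 * frac)))
  }
  half <- win %/% 2L
  if (shrink_tail) {
    # let the shrunk window follow the right edge, but never below w/10
    half <- pmin(half, n - seq_len(n))
    half[half < max(1L, w %/% 20L)] <- 0L
  }
  centers <- which(half >= 1L & seq_len(n) - half >= 1L &
                     seq_len(n) + half <= n)
  num_cols <- names(points)[vapply(points, is.numeric, logical(1))]
  lo <- centers - half[centers]
  hi <- centers + half[centers]
  out <- as.data.frame(lapply(points[num_cols], function(col) {
    cs <- cumsum(c(0, col))
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }))
  out$window <- 2L * half[centers] + 1L
  class(out) <- c("hook_curve", "data.frame")
  out
}

#' Theoretical hook curve of the two-species Langmuir isotherm
#'
#' Evaluates the model hook coordinates as a function of the latent
#' specific-to-non-specific binding ratio `R`:
#' \deqn{\Delta(R) = \log\frac{R+1}{R\,10^{-\alpha}+1} -
#'       \log\frac{B^{PM}(R)}{B^{MM}(R)}}
#' \deqn{\Sigma(R) = \Sigma_{start} + \tfrac12\log[(R+1)(R\,10^{-\alpha}+1)] -
#'       \tfrac12\log[B^{PM}(R)B^{MM}(R)]}
#' with saturation terms `B^PM(R) = 1 + 10^(-beta + Delta_start/2) (R+1)` and
#' `B^MM(R) = 1 + 10^(-beta + Delta_start/2) (R 10^-alpha + 1)`. `alpha` is
#' the PM/MM log affinity gap of specific binding (hook height), `beta` the
#' hook width, `Sigma_start` the non-specific signal level, and the asymptotic
#' saturation level is `logM = Sigma_start + beta - Delta_start/2`.
#'
#' @param R non-negative binding ratio(s).
#' @param fit a `hook_fit` object or a named list with `alpha`, `beta`,
#'   `sigma_start` and optionally `delta_start` (default 0).
#' @return data.frame with columns `R`, `sigma`, `delta`.
#' @export
theoretical_hook <- function(R, fit) {
  stopifnot(all(R >= 0))
  a <- 10^(-fit$alpha)
  ds <- if (is.null(fit$delta_start)) 0 else fit$delta_start
  bfac <- 10^(-fit$beta + ds / 2)
  t_pm <- log1p(R) / LOG10
  t_mm <- log1p(R * a) / LOG10
  b_pm <- log1p(bfac * (R + 1)) / LOG10
  b_mm <- log1p(bfac * (R * a + 1)) / LOG10
  data.frame(R = R,
             sigma = fit$sigma_start + (t_pm + t_mm) / 2 - (b_pm + b_mm) / 2,
             delta = (t_pm - t_mm) - (b_pm - b_mm))
}

.hook_grid <- function(fit, n = 600, log_r_range = c(-4, 12)) {
  R <- c(0, 10^seq(log_r_range[1], log_r_range[2], length.out = n))
  theoretical_hook(R, fit)
}

#' Fit the theoretical hook curve to a smoothed hook
#'
#' Nonlinear least squares of the theoretical hook over the smoothed curve.
#' The latent per-point binding ratio is eliminated by evaluating the model on
#' a dense `R` grid and interpolating the model `Delta` at each observed
#' `Sigma`. Initialization: `Sigma_start` at the 2nd percentile of `Sigma`,
#' `logM` at the 98th percentile + 0.3, `alpha = max(Delta)`,
#' `beta = logM - Sigma_start`.
#'
#' @param curve a `hook_curve` from [moving_average()] with columns `sigma`,
#'   `delta`.
#' @return object of class `hook_fit`: list with `alpha`, `beta`,
#'   `sigma_start`, `delta_start`, `logM`, `converged`, `residual_norm`.
#' @export
fit_hook <- function(curve) {
  stopifnot(all(c("sigma", "delta") %in% names(curve)))
  sig <- curve$sigma; del <- curve$delta
  if (diff(range(sig)) < 0.5)
    stop("hook curve spans less than half a decade in Sigma")
  if (max(del) < 0.1)
    stop("no specific branch: hook curve is flat (max Delta < 0.1)")
  s0 <- stats::quantile(sig, 0.02, names = FALSE)
  lM0 <- stats::quantile(sig, 0.98, names = FALSE) + 0.3
  # Delta of the N-range: the saturation terms depend on beta and
  # delta_start only through beta - delta_start/2, so delta_start is pinned
  # to the left end of the curve instead of being fitted
  ds <- mean(del[sig <= s0 + 0.02])
  if (!is.finite(ds)) ds <- 0
  init <- c(alpha = max(del), beta = lM0 - s0, sigma_start = s0)
  resid_fun <- function(par) {
    f <- list(alpha = par[1], beta = par[2], sigma_start = par[3],
              delta_start = ds)
    g <- .hook_grid(f)
    pred <- stats::approx(g$sigma, g$delta,
                          xout = pmin(pmax(sig, min(g$sigma)), max(g$sigma)),
                          ties = "ordered")$y
    pred - del
  }
  ctl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12, ptol = 1e-12)
  fit <- minpack.lm::nls.lm(par = init, fn = resid_fun,
                            lower = c(0.01, 0.2, -Inf),
                            upper = c(3, 8, Inf), control = ctl)
  if (fit$info == 0 || fit$info == 9)
    stop("hook fit did not converge (info = ", fit$info,
         ", residual norm = ", signif(sqrt(fit$deviance), 4), ")")
  par <- fit$par
  out <- list(alpha = unname(par[1]), beta = unname(par[2]),
              sigma_start = unname(par[3]), delta_start = ds,
              logM = unname(par[3] + par[2] - ds / 2),
              converged = TRUE,
              residual_norm = sqrt(fit$deviance / length(del)))
  class(out) <- "hook_fit"
  out
}

#' @export
print.hook_fit <- function(x, ...) {
  cat(sprintf(paste0("hook_fit: alpha = %.3f, beta = %.3f, ",
                     "Sigma_start = %.3f, Delta_start = %.3f, logM = %.3f\n"),
              x$alpha, x$beta, x$sigma_start, x$delta_start, x$logM))
  if (!is.null(x$pct_absent))
    cat(sprintf("  %%N = %.1f%%, phi = %.3f\n", 100 * x$pct_absent, x$phi))
  invisible(x)
}

# Monotone inversion Sigma -> R on the fitted hook. Values outside
# [Sigma_start, logM] are clamped (with warning if warn = TRUE).
invert_sigma <- function(sigma, fit, warn = FALSE) {
  g <- .hook_grid(fit)
  rng <- range(g$sigma)
  outside <- sigma < rng[1] | sigma > rng[2]
  if (warn && any(outside))
    warning(sum(outside), " Sigma value(s) outside [Sigma_start, logM]; clamped")
  s <- pmin(pmax(sigma, rng[1]), rng[2])
  # interpolate in log10(R) using the positive-R part of the grid; rule = 2
  # clamps the sliver between Sigma(0) and the first positive grid point
  gi <- g[g$R > 0, ]
  lr <- stats::approx(gi$sigma, log10(gi$R), xout = s, ties = "ordered",
                      rule = 2)$y
  R <- 10^lr
  R[sigma <= rng[1]] <- 0
  R
}

#' Hybridization-regime classification
#'
#' Assigns each probe set to one of five regimes with increasing total signal:
#' `N` (non-specific only), `mix`, `S` (predominantly specific), `sat`
#' (saturation) and `as` (asymptotic). The per-set binding ratio `R` is
#' obtained by monotone inversion of the fitted `Sigma(R)`; boundaries are
#' `R < 0.1` (N), `R < 1` (mix), `R < R_sat` (S) where the PM saturation term
#' reaches 2, and `Sigma > logM - 0.05` (as).
#'
#' @param sigma per-set `Sigma` values (e.g. from [probeset_hook_points()]).
#' @param fit a `hook_fit`.
#' @return data.frame with columns `sigma`, `R`, `label` (factor with levels
#'   N, mix, S, sat, as).
#' @export
classify_regimes <- function(sigma, fit) {
  R <- invert_sigma(sigma, fit)
  r_sat <- max(1, 10^(fit$beta - fit$delta_start / 2) - 1)
  g <- .hook_grid(fit)
  s_as <- fit$logM - 0.05
  r_as <- if (max(g$sigma) > s_as) {
    gi <- g[g$R > 0, ]
    10^stats::approx(gi$sigma, log10(gi$R), xout = s_as, ties = "ordered")$y
  } else max(g$R)
  r_as <- max(r_as, r_sat)
  lab <- cut(R, breaks = c(-Inf, 0.1, 1, r_sat, r_as, Inf),
             labels = c("N", "mix", "S", "sat", "as"), right = FALSE)
  data.frame(sigma = sigma, R = R, label = lab)
}

#' Fraction of absent probe sets
#'
#' @param regimes output of [classify_regimes()].
#' @return fraction of probe sets in the `N` regime.
#' @export
pct_absent <- function(regimes) mean(regimes$label == "N")

#' Mean expression index of present probe sets
#'
#' Summarizes the mean specific expression of the chip as the average
#' `log10 R` over all present (non-N) probe sets, offset by
#' `Sigma_start - logM` so that the index is expressed relative to the
#' saturation intensity (the absolute offset is a convention).
#'
#' @param regimes output of [classify_regimes()].
#' @param fit a `hook_fit`.
#' @return list with `phi` and the number of contributing sets `n`; `phi` is
#'   `NA` (with a warning) when no present set exists.
#' @export
expression_index <- function(regimes, fit) {
  present <- regimes$label != "N" & regimes$R > 0
  if (!any(present)) {
    warning("no present (non-N) probe sets; expression index undefined")
    return(list(phi = NA_real_, n = 0L))
  }
  list(phi = mean(log10(regimes$R[present])) + fit$sigma_start - fit$logM,
       n = sum(present))
}
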