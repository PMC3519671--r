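#' 3'/5' control-probe metrics
#'
#' Summarizes the dedicated RNA-quality control probe sets (e.g. the GAPDH and
#' beta-actin 3'/middle/5' sets): per control gene, the PM-only set means of
#' the 3' and 5' sets give the apparent degradation ratio
#' `delta_35 = <log10 PM>_3' - <log10 PM>_5'` and the mean signal level
#' `sigma_sum = (<log10 PM>_3' + <log10 PM>_5')/2`.
#'
#' Control sets are grouped into genes by stripping the trailing region token
#' (`3prime`/`middle`/`5prime`) from the probe-set identifier.
#'
#' @param chip a `chip_data` object with control sets flagged.
#' @return data.frame with one row per control gene: `gene_label`,
#'   `sigma_sum`, `delta_35`, `sigma_3`, `sigma_5`, `sigma_m`.
#' @export
control_metrics <- function(chip) {
  p <- chip$probes[chip$probes$is_control, , drop = FALSE]
  if (!nrow(p)) stop("no control probe sets flagged on this chip")
  means <- tapply(log10(p$pm), p$probeset_id, mean)
  region <- tapply(p$control_region, p$probeset_id, function(x) x[1])
  gene <- sub("[._-]?(3prime|5prime|middle)$", "",
              names(means), ignore.case = TRUE)
  out <- lapply(split(seq_along(means), gene), function(idx) {
    r <- region[idx]
    s3 <- means[idx][r == "3prime"]
    s5 <- means[idx][r == "5prime"]
    sm <- means[idx][r == "middle"]
    if (!length(s3) || !length(s5)) {
      warning("control gene '", gene[idx[1]],
              "' lacks a 3' or 5' set; skipped")
      return(NULL)
    }
    data.frame(gene_label = gene[idx[1]],
               sigma_sum = (s3[1] + s5[1]) / 2,
               delta_35 = s3[1] - s5[1],
               sigma_3 = s3[1], sigma_5 = s5[1],
               sigma_m = if (length(sm)) sm[1] else NA_real_)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) stop("no control gene with both 3' and 5' sets")
  rownames(out) <- NULL
  out
}

# PM-only hook coordinates of a 3'/5' probe-set pairing as a function of the
# transcript binding ratio R, with the two ends biased by +/- dgamma/2 and
# both ends following the hyperbolic isotherm. b is the mean non-specific
# binding strength inferred from the hook anchors.
.threshold_curve <- function(R, dgamma, sigma_n, logM) {
  b <- 10^(sigma_n - logM)
  r3 <- R * 10^(dgamma / 2)
  r5 <- R * 10^(-dgamma / 2)
  l3 <- log1p(r3) / LOG10 - log1p(b * (r3 + 1)) / LOG10
  l5 <- log1p(r5) / LOG10 - log1p(b * (r5 + 1)) / LOG10
  data.frame(R = R,
             sigma = logM + log10(b) + (l3 + l5) / 2,
             delta = l3 - l5)
}

.threshold_max <- function(dgamma, sigma_n, logM) {
  obj <- function(lr) .threshold_curve(10^lr, dgamma, sigma_n, logM)$delta
  opt <- stats::optimize(obj, c(-6, (logM - sigma_n) + 6),
                         maximum = TRUE, tol = 1e-10)
  opt$objective
}

#' Variable RNA-quality threshold ("threshold hook")
#'
#' The constant 3'/5' intensity-ratio threshold for good RNA quality only
#' applies in the specific, unsaturated hybridization range: non-specific
#' binding and saturation both compress the apparent ratio towards zero. The
#' threshold hook converts the constant threshold into a signal-dependent one
#' by tracing the PM-only isotherm trajectory of a 3'/5' probe-set pairing
#' (the MM terms of the hook model are dropped analytically). Its start and
#' end anchors (`Sigma` of the non-specific level and of asymptotic
#' saturation) come from the standard hook fit; the underlying true bias
#' `dgamma` is calibrated by root finding so that the curve maximum equals
#' the constant threshold.
#'
#' @param fit a `hook_fit` supplying the anchors `sigma_start` and `logM`.
#' @param constant_threshold the constant log10 3'/5' ratio threshold
#'   (default `log10(3)`, about 0.48).
#' @return object of class `threshold_hook`: list with `curve` (data.frame
#'   `R`, `sigma`, `delta`), `dgamma`, `constant_threshold`, anchors
#'   `sigma_n`, `sigma_as`.
#' @export
build_threshold_hook <- function(fit, constant_threshold = log10(3)) {
  stopifnot(constant_threshold > 0)
  sigma_n <- fit$sigma_start
  logM <- fit$logM
  froot <- function(dg) .threshold_max(dg, sigma_n, logM) - constant_threshold
  upper <- 8
  if (froot(upper) < 0) stop("threshold-hook calibration failed: ",
                             "constant threshold unreachable")
  dg <- stats::uniroot(froot, c(1e-8, upper), tol = 1e-12)$root
  # include the argmax in the tabulated curve so its maximum attains the
  # calibrated threshold exactly
  r_star <- 10^stats::optimize(function(lr)
    .threshold_curve(10^lr, dg, sigma_n, logM)$delta,
    c(-6, (logM - sigma_n) + 6), maximum = TRUE, tol = 1e-10)$maximum
  R <- sort(c(0, r_star, 10^seq(-4, (logM - sigma_n) + 6, length.out = 800)))
  curve <- .threshold_curve(R, dg, sigma_n, logM)
  out <- list(curve = curve, dgamma = dg,
              constant_threshold = constant_threshold,
              sigma_n = sigma_n, sigma_as = logM)
  class(out) <- "threshold_hook"
  out
}

#' Threshold value at a given signal level
#' @param th a `threshold_hook`.
#' @param sigma signal level(s) (PM-only `Sigma` of the control pairing).
#' @return the variable threshold at `sigma`; 0 outside the anchor range.
#' @export
threshold_at <- function(th, sigma) {
  cv <- th$curve
  out <- stats::approx(cv$sigma, cv$delta, xout = sigma, ties = "ordered",
                       yleft = 0, yright = 0)$y
  pmin(out, th$constant_threshold)
}

#' Classify control measurements against both thresholds
#'
#' Compares control points (`sigma`, `delta`) against the variable threshold
#' hook and the constant threshold. Points below the hook threshold are true
#' positives (genuinely good RNA); points between the hook and the constant
#' threshold are false positives (called good by the constant rule although
#' their hybridization mode hides degradation); points at or above the
#' constant threshold are true negatives. False negatives are zero by
#' construction because the hook threshold never exceeds the constant one.
#' Boundary ties are assigned to the worse-quality side.
#'
#' @param points data.frame with columns `sigma` and `delta` (one row per
#'   control measurement, e.g. from [control_metrics()] via `sigma_sum` and
#'   `delta_35`).
#' @param th a `threshold_hook`.
#' @param constant_threshold the constant threshold (defaults to the one the
#'   hook was calibrated to).
#' @return list with counts `tp`, `fp`, `tn`, `fn`, and `ppv = TP/(TP+FP)`,
#'   `sp = TN/(FP+TN)`.
#' @export
classify_controls <- function(points, th,
                              constant_threshold = th$constant_threshold) {
  stopifnot(nrow(points) >= 1)
  hook_thr <- threshold_at(th, points$sigma)
  tp <- sum(points$delta < hook_thr)
  tn <- sum(points$delta >= constant_threshold)
  fp <- nrow(points) - tp - tn
  list(tp = tp, fp = fp, tn = tn, fn = 0L,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       sp = if (fp + tn > 0) tn / (fp + tn) else NA_real_)
}
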