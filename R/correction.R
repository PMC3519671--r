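#' Build the positional intensity-correction model
#'
#' The correction removes the 3'/5' degradation bias from raw probe
#' intensities using two ingredients estimated from the same array: the
#' fitted positional decay of the transcript coverage `d_S(x)` (index or
#' nucleotide scale) and the degree of specific, unsaturated hybridization of
#' each probe set, looked up via the set-mean logged PM intensity `y`.
#' Non-specific and strongly saturated sets receive no correction; the
#' correction is maximal for sets in the specific range.
#'
#' Two variants are provided. The default (`"isotherm"`) tabulates the
#' specific/non-specific binding ratio of each set (from the hook-curve
#' inversion) against `y` and evaluates the fitted two-species isotherm with
#' and without the positional coverage factor; the correction factor is the
#' ratio of the two model intensities. In the linear range this reduces to
#' the mixture `C(x, y) = d_S(x) f_s(y) + 1 - f_s(y)` with
#' `f_s = R/(R + 1)` (the specific signal fraction), and under saturation it
#' compresses the correction exactly as the isotherm compresses the bias.
#' The `"hook"` variant uses the mixture with `f_s(y)` taken as the smoothed
#' degradation hook normalized by its maximum (declining beyond the maximum,
#' so saturated sets are left alone); it needs no hook fit beyond the
#' degradation hook itself but under-weights sets of intermediate
#' specificity.
#'
#' When the degradation hook shows no detectable opening (maximum below
#' `min_opening`) or the chip has no specific ensemble, the model is the
#' identity.
#'
#' @param chip a `chip_data` object.
#' @param fit a `hook_fit` for the chip.
#' @param regimes regime table from [chip_regimes()] (computed if `NULL`).
#' @param scale `"k"` (one factor per probe index; robust, default) or `"L"`
#'   (per-probe positional factor in nucleotides).
#' @param base_window smoothing window for the lookup tables.
#' @param min_opening smallest degradation-hook maximum treated as a real
#'   3' bias (default 0.05).
#' @param f_method `"isotherm"` or `"hook"` (see Details).
#' @return object of class `correction_model`: list with `f_method`,
#'   `f_table` (data.frame `y`, `f`: specific fraction or hook weight),
#'   `b` (non-specific binding strength; isotherm variant), `decay` (a
#'   `decay_fit` or `NULL`), `g_mean` (chip-mean coverage factor), `scale`,
#'   `identity` flag.
#' @export
build_correction_model <- function(chip, fit = NULL, regimes = NULL,
                                   scale = c("k", "L"), base_window = 1000,
                                   min_opening = 0.05,
                                   f_method = c("isotherm", "hook")) {
  scale <- match.arg(scale)
  f_method <- match.arg(f_method)
  st <- pset_stats(chip)
  dsig_35 <- st$sigma_3 - st$sigma_5
  o <- order(st$y_pm)
  raw <- data.frame(y = st$y_pm[o], dsig = dsig_35[o])
  sm <- moving_average(raw, base_window, shrink_tail = TRUE)
  fmax <- max(sm$dsig)
  if (is.null(regimes) && !is.null(fit)) regimes <- chip_regimes(chip, fit)
  n_spec <- if (is.null(regimes)) 0L else length(.subset_ids(regimes, "S"))
  if (fmax < min_opening || n_spec == 0) {
    if (fmax >= min_opening)
      warning("degradation hook opens (", signif(fmax, 3),
              ") but no specific ensemble is available; identity correction")
    out <- list(f_method = f_method,
                f_table = data.frame(y = range(st$y_pm), f = c(0, 0)),
                b = NA_real_, decay = NULL, g_mean = 1, scale = scale,
                identity = TRUE, hook_max = fmax)
    class(out) <- "correction_model"
    return(out)
  }
  if (f_method == "isotherm") {
    if (is.null(fit)) stop("the isotherm variant requires a hook fit")
    b <- 10^(fit$sigma_start - fit$logM)
    # binding ratio vs y from the smoothed hook abscissa (per-set inversion
    # is too noisy near the non-specific level); the ramp keeps sets in the
    # N regime (R < 0.1) strictly uncorrected
    ss <- moving_average(data.frame(y = st$y_pm[o], sigma = st$sigma[o]),
                         base_window, shrink_tail = TRUE)
    R_tab <- invert_sigma(ss$sigma, fit)
    u <- pmax(0, (R_tab - 0.1) / (R_tab + 1))
    f_table <- data.frame(y = ss$y, f = pmin(u, 0.999))
  } else {
    b <- NA_real_
    f_table <- data.frame(y = sm$y, f = pmin(pmax(sm$dsig / fmax, 0), 1))
  }
  # reference decay of the full positional bias: raw intensity profiles are
  # compressed by the non-specific floor and by saturation, so the specific
  # binding strength of each probe is recovered through the fitted isotherm
  # before fitting the decay; without a hook fit the raw specific-ensemble
  # profile is used
  prof <- if (!is.null(fit))
    specific_decay_profile(chip, fit, regimes, scale = scale)
  else
    decay_profile(chip, regimes, subset = "S", scale = scale,
                  include_mix_upper = FALSE)
  dfit <- fit_decay(prof, clamp = TRUE)
  g_mean <- mean(pmin(predict(dfit, prof$x), 1))
  out <- list(f_method = f_method, f_table = f_table, b = b, decay = dfit,
              g_mean = g_mean, scale = scale, identity = FALSE,
              hook_max = fmax)
  class(out) <- "correction_model"
  out
}

#' @export
print.correction_model <- function(x, ...) {
  if (x$identity) {
    cat("correction_model: identity (no detectable 3' bias)\n")
  } else {
    cat(sprintf("correction_model (%s-scale, %s): hook max %.3f, lambda = %.4g\n",
                x$scale, x$f_method, x$hook_max, x$decay$lambda))
  }
  invisible(x)
}

# per-set weight at set-mean log intensity y (linear interpolation, nearest
# endpoint outside the tabulated range)
.f_s <- function(model, y) {
  tb <- model$f_table
  stats::approx(tb$y, tb$f, xout = y, ties = "ordered", rule = 2)$y
}

#' Correction factors for probe positions and set signal levels
#'
#' Evaluates the correction factor `C(x, y)` of a model: the isotherm
#' intensity ratio with and without the positional coverage factor
#' (`"isotherm"` variant) or the mixture `d_S(x) f_s(y) + 1 - f_s(y)`
#' (`"hook"` variant, also used for models without an `f_method` field).
#'
#' @param model a `correction_model`.
#' @param x probe positions (index `k` or nucleotides `L`, matching the model
#'   scale).
#' @param y set-mean logged PM (or MM) intensities.
#' @param g_mean set-mean coverage factor used to anchor the set's binding
#'   ratio at the 3'-reference level (defaults to the chip-mean factor).
#' @return correction factors `C(x, y)` in (0, 1].
#' @export
correction_factor <- function(model, x, y, g_mean = NULL) {
  if (model$identity) return(rep(1, length(x)))
  g <- pmin(pmax(predict(model$decay, x), 1e-6), 1)
  method <- if (is.null(model$f_method)) "hook" else model$f_method
  if (method == "isotherm") {
    if (is.null(g_mean)) g_mean <- model$g_mean
    u <- .f_s(model, y)
    R_set <- u / (1 - u)
    xs_ref <- model$b * R_set / g_mean    # specific strength at full coverage
    iso <- function(xs) (xs + model$b) / (1 + xs + model$b)
    cf <- iso(xs_ref * g) / iso(xs_ref)
  } else {
    fs <- .f_s(model, y)
    cf <- g * fs + (1 - fs)
  }
  if (any(cf <= 0)) stop("correction factor <= 0: model invariant breached")
  pmin(cf, 1)
}

#' Correct probe intensities for the 3'/5' degradation bias
#'
#' Divides each PM intensity by its correction factor `C(x_p, y_set)`, where
#' `x_p` is the probe position on the model scale and `y_set` the set-mean
#' log10 PM intensity; MM intensities are corrected with the set-mean log10
#' MM intensity as argument. Non-specific sets pass through unchanged;
#' specific probes distal from the 3'-end are scaled up.
#'
#' @param chip the `chip_data` the model was built from.
#' @param model a `correction_model`.
#' @return list with `chip` (corrected `chip_data`) and `factors` (data.frame
#'   `probeset_id`, `k`, `c_pm`, `c_mm` of applied factors, the audit
#'   sidecar).
#' @export
correct_intensities <- function(chip, model) {
  p <- chip$probes
  st <- pset_stats(chip, controls = TRUE)
  y_pm <- st$y_pm[match(p$probeset_id, st$probeset_id)]
  x <- if (model$scale == "k") p$k else p$L
  g_mean <- if (model$identity) NULL else {
    g_p <- pmin(pmax(predict(model$decay, x), 1e-6), 1)
    stats::ave(g_p, p$probeset_id)
  }
  c_pm <- correction_factor(model, x, y_pm, g_mean)
  new_p <- p
  new_p$pm <- p$pm / c_pm
  if (!chip$pm_only) {
    y_mm <- st$y_mm[match(p$probeset_id, st$probeset_id)]
    c_mm <- correction_factor(model, x, y_mm, g_mean)
    new_p$mm <- p$mm / c_mm
  } else c_mm <- rep(NA_real_, nrow(p))
  out_chip <- chip_data(new_p, metadata = c(chip$metadata,
                                            list(corrected = model$scale)))
  list(chip = out_chip,
       factors = data.frame(probeset_id = p$probeset_id, k = p$k,
                            c_pm = c_pm, c_mm = c_mm))
}

#' Positional decay of the specific binding strength
#'
#' Decomposes PM intensities of specific probe sets into specific binding
#' strengths using the fitted hyperbolic isotherm -- `X = I/(M - I)` minus
#' the mean non-specific level -- and averages their logs per position. This
#' removes the compression of raw intensity profiles by the non-specific
#' floor and by saturation, so the normalized profile tracks the transcript
#' coverage itself. Used as the reference decay of the correction model.
#'
#' @param chip a `chip_data` object.
#' @param fit a `hook_fit`.
#' @param regimes regime table from [chip_regimes()].
#' @param scale `"k"` or `"L"`.
#' @param bin_width,min_count L-scale binning, as in [decay_profile()].
#' @param r_min smallest binding ratio of the contributing sets (default 3).
#' @return a `decay_profile` (subset `"S"`).
#' @export
specific_decay_profile <- function(chip, fit, regimes, scale = c("k", "L"),
                                   bin_width = 25, min_count = 20,
                                   r_min = 3) {
  scale <- match.arg(scale)
  ids <- regimes$probeset_id[regimes$R >= r_min &
                               !regimes$label %in% c("N", "as")]
  if (length(ids) < 20)
    ids <- .subset_ids(regimes, "S")
  p <- chip$probes[chip$probes$probeset_id %in% ids &
                     !chip$probes$is_control, , drop = FALSE]
  if (!nrow(p)) stop("no specific probe sets for the reference decay")
  M <- 10^fit$logM
  b <- 10^(fit$sigma_start - fit$logM)   # mean non-specific binding strength
  I <- pmin(p$pm, 0.98 * M)
  xs <- I / (M - I) - b
  ok <- xs > b / 10
  p <- p[ok, , drop = FALSE]; xs <- xs[ok]
  lx <- log10(xs)
  if (scale == "k") {
    x <- sort(unique(p$k))
    m <- tapply(lx, factor(p$k, levels = x), mean)
    n <- as.integer(table(factor(p$k, levels = x)))
    ref <- mean(m[x %in% c(1, 2)])
  } else {
    if (anyNA(p$L)) stop("probe positions L missing")
    bin <- floor(p$L / bin_width)
    m_all <- tapply(lx, bin, mean)
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
  attr(out, "subset") <- "S"
  attr(out, "ref_logI") <- as.numeric(ref)
  class(out) <- c("decay_profile", "data.frame")
  out
}
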