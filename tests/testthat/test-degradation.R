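test_that("positional subset averages of a probe set", {
  sig <- rep(2.5, 11)
  expect_equal(subset_sigma(sig, "3prime"), 2.5)
  expect_equal(subset_sigma(sig, "middle"), 2.5)
  expect_equal(subset_sigma(sig, "5prime"), 2.5)

  # hand computation on Sigma_k = 3 - 0.05 (k - 1), k = 1..11:
  # 3' subset mean over k = 1..3 -> 3 - 0.05, 5' over k = 9..11 -> 3 - 0.45
  sig2 <- 3 - 0.05 * (0:10)
  expect_equal(subset_sigma(sig2, "3prime") - subset_sigma(sig2, "5prime"),
               0.05 * 8)
  expect_equal(subset_sigma(sig2, "middle"), 3 - 0.05 * 5)

  # a set of 3: the 3' and 5' subsets coincide
  sig3 <- c(1, 2, 3)
  expect_equal(subset_sigma(sig3, "3prime"), subset_sigma(sig3, "5prime"))
  expect_error(subset_sigma(sig3, "middle"), ">= 5")
  expect_error(subset_sigma(1:2, "3prime"), ">= 3")
})

test_that("tongs branches vanish on a purely non-specific chip", {
  sim <- simulate_chip(sim_config(n_psets = 800, fraction_absent = 1),
                       seed = 9)
  td <- tongs_and_deghook(sim$chip, base_window = 200)
  expect_lt(max(abs(td$deghook$dsig_35)), 0.02)
  expect_lt(max(abs(td$tongs$dsig_3)), 0.02)
  expect_lt(max(abs(td$tongs$dsig_5)), 0.02)
})

test_that("tongs branches are ordered 3' >= middle >= 5' on degraded chips", {
  # the branches coincide (all ~ 0) in the N range, so the ordering is
  # asserted up to the smoothing noise floor there
  qc <- qc_default()
  expect_true(all(qc$tongs$dsig_3 >= qc$tongs$dsig_m - 5e-3))
  expect_true(all(qc$tongs$dsig_m >= qc$tongs$dsig_5 - 5e-3))
  # where the tongs open, the ordering is strict
  open_ <- qc$tongs$dsig_3 - qc$tongs$dsig_5 > 0.1
  expect_true(any(open_))
  expect_true(all(qc$tongs$dsig_3[open_] > qc$tongs$dsig_m[open_]))
  expect_true(all(qc$tongs$dsig_m[open_] > qc$tongs$dsig_5[open_]))
})

test_that("theoretical tongs ordinate vanishes in both limits", {
  fit <- ref_fit(alpha = 0.85, beta = 2, sigma_start = 1.5)
  for (dg in c(0.2, 0.6, 1.0)) {
    lo <- theoretical_tongs(1e-9, fit, dg / 2, -dg / 2)$dsig
    hi <- theoretical_tongs(1e12, fit, dg / 2, -dg / 2)$dsig
    expect_lt(abs(lo), 1e-6)
    expect_lt(abs(hi), 1e-6)
    # the maximum approaches the split when saturation is negligible
    nosat <- ref_fit(alpha = 0.85, beta = 12, sigma_start = 1.5)
    mx <- max(theoretical_tongs(10^seq(-2, 8, 0.01), nosat,
                                dg / 2, -dg / 2)$dsig)
    expect_equal(mx, dg, tolerance = 0.01)
  }
})

test_that("tongs-opening fit recovers a self-generated curve", {
  fit <- ref_fit(alpha = 0.85, beta = 2, sigma_start = 1.5)
  g <- theoretical_tongs(10^seq(-2, 5, length.out = 300), fit, 0.3, -0.3)
  curve <- data.frame(sigma = g$sigma, dsig_35 = g$dsig)
  tf <- fit_tongs_opening(curve, fit)
  expect_true(tf$converged)
  expect_lt(abs(tf$dgamma - 0.6), 0.01)

  flat <- data.frame(sigma = seq(1.5, 3.5, length.out = 100),
                     dsig_35 = rep(0, 100))
  tf0 <- fit_tongs_opening(flat, fit)
  expect_lt(abs(tf0$dgamma), 0.01)
})

test_that("tongs opening to concentration-ratio conversions", {
  expect_equal(round(d_from_tongs(0.57), 2), 0.27)
  expect_equal(round(d_from_tongs(0.29), 2), 0.51)
  expect_equal(d_from_tongs(0), 1)
  expect_equal(mean_log_d(0.57), -0.285)
  expect_equal(mean_log_d(0.47), -0.235)
  expect_equal(mean_log_d(0), 0)
})

test_that("decay profile of flat and exponential chips", {
  prof <- decay_profile(flat_chip(), NULL, "all", "k")
  expect_true(all(abs(prof$d - 1) < 1e-12))

  chip <- decay_chip(lambda = 4)
  prof2 <- decay_profile(chip, NULL, "all", "k")
  # normalized to the k = 1,2 reference (geometric mean)
  expect_equal(prof2$d,
               exp(-(1:11 - 1) / 4) / exp(mean(-(0:1) / 4)),
               tolerance = 1e-12)
})

test_that("L-scale profile bins and reference", {
  chip <- decay_chip(n_sets = 60, lambda = 4)
  prof <- decay_profile(chip, NULL, "all", "L", bin_width = 25,
                        min_count = 20)
  expect_true(all(prof$n >= 20))
  ref_bin <- prof$x[prof$x < 150][1]
  expect_equal(prof$d[prof$x == ref_bin], 1)
})

test_that("non-specific profile is flat on degraded chips", {
  qc <- qc_default()
  expect_true(all(abs(qc$profile_n_k$d - 1) < 0.05))
})

test_that("decay fit recovers generating parameters exactly", {
  # single exponential on the index scale (fit coordinate x = k - 1)
  prof <- make_profile(1:11, exp(-(1:11 - 1) / 4), scale = "k")
  f <- fit_decay(prof)
  expect_equal(f$lambda, 4, tolerance = 1e-6)
  expect_equal(f$x0, 0, tolerance = 1e-6)
  expect_equal(f$d_inf, 0)
  expect_equal(predict(f, 1:11), prof$d, tolerance = 1e-8)

  # shifted exponential plus constant on the nucleotide scale
  L <- seq(112.5, 587.5, by = 25)
  dL <- (1 - 0.2) * exp(-(L - 150) / 150) + 0.2
  fL <- fit_decay(make_profile(L, dL, scale = "L"))
  expect_lt(abs(fL$lambda / 150 - 1), 0.01)
  expect_lt(abs(fL$d_inf / 0.2 - 1), 0.01)
  expect_lt(abs(fL$x0 / 150 - 1), 0.01)

  expect_error(fit_decay(make_profile(1:3, exp(-(0:2) / 4), scale = "k")),
               ">= 5")
})

test_that("two-point degradation ratio: exact oracle and flat chip", {
  # constant affinities, d(k) = exp(-(k-1)/4): independent arithmetic gives
  # log10 d^k = -((9 + 10)/2 - (0 + 1)/2) / (4 ln 10) = -9 / (4 ln 10)
  chip <- decay_chip(lambda = 4)
  dk <- degradation_ratio_dk(chip)
  expect_equal(dk$log_dk, -9 / (4 * log(10)), tolerance = 1e-12)

  flat <- flat_chip(n_sets = 60)
  expect_equal(degradation_ratio_dk(flat)$log_dk, 0)

  expect_warning(degradation_ratio_dk(decay_chip(n_sets = 10)),
                 "low confidence")
})

test_that("decay-length conversions from the two-point ratio", {
  # d^k = e^-2  <=>  log10 d^k = -2/ln 10 = -0.8686
  lam <- lambda_from_dk(-2 / log(10), delta_L = 50)
  expect_equal(lam$lambda_k, 4, tolerance = 1e-12)
  expect_equal(lam$lambda_L, 200, tolerance = 1e-12)
  expect_warning(out <- lambda_from_dk(0, 50), "undefined")
  expect_true(is.na(out$lambda_k))
})

test_that("all-probe degradation slope and its dilution by absent sets", {
  expect_equal(affyslope(flat_chip())$slope, 0, tolerance = 1e-12)

  # 100% specific exponential chip: slope equals the profile slope
  chip <- decay_chip(lambda = 4, n_sets = 50)
  s_all <- affyslope(chip)$slope
  expect_equal(s_all, -log10(exp(1)) / 4, tolerance = 1e-12)

  # diluting with 50% flat (non-responding) sets halves the slope
  flat <- flat_chip(n_sets = 50, pm = 50, mm = 50)
  flat$probes$probeset_id <- paste0("n_", flat$probes$probeset_id)
  mixed <- chip_data(rbind(chip$probes, flat$probes))
  s_mixed <- affyslope(mixed)$slope
  expect_lt(abs(s_mixed), abs(s_all))
  expect_equal(s_mixed, s_all / 2, tolerance = 1e-12)
})

test_that("positional S/N histograms", {
  reg <- data.frame(
    probeset_id = sprintf("s%03d", 1:40),
    sigma = 2, y_pm = 2,
    L_first = rep(c(50, 250), 20),
    L_max = rep(c(400, 800), 20),
    R = rep(c(0.01, 10), 20),
    label = factor(rep(c("N", "S"), 20), levels = c("N", "mix", "S", "sat", "as")))
  chip <- flat_chip(n_sets = 40)
  # N sets all at L_first = 50 / L_max = 400; S sets at 250 / 800
  h <- sn_positional_histograms(chip, reg)
  expect_equal(sum(h$L_first$frac_S), 1)
  expect_equal(sum(h$L_first$frac_N), 1)
  expect_equal(h$L_max$diff[h$L_max$bin_lo == 400], 1)   # N-enriched bin
  expect_equal(h$L_max$diff[h$L_max$bin_lo == 800], -1)

  # identical positional distributions: difference identically zero
  reg2 <- reg
  reg2$L_first <- 150; reg2$L_max <- 600
  h2 <- sn_positional_histograms(chip, reg2)
  expect_true(all(h2$L_first$diff == 0))
  expect_true(all(h2$L_max$diff == 0))
})

test_that("consistency chain: tongs opening, d^k and decay length agree", {
  # strong-expression, low-noise conditions so the specific ensemble is
  # dominated by its signal; the d^k -> lambda conversion uses the printed
  # constant 8 while the generating index span is 8.5 (shift k0 = 2), so the
  # chain comparison is made on the span-adjusted scale
  cfg <- sim_config(n_psets = 2500, fraction_absent = 0.1,
                    x_n = 10^-3.5, r_min = 30, expr_decades = 1.5,
                    noise_sd = 0.02)
  sim <- simulate_chip(cfg, seed = 23)
  qc <- qc_chip(sim$chip, base_window = 600)
  lambda_true <- cfg$decay$lambda
  # Eq-level closures against the generating truth
  expect_lt(abs(qc$dgamma - sim$truth$dgamma) / sim$truth$dgamma, 0.1)
  expect_lt(abs(qc$log_dk - sim$truth$log_dk) / abs(sim$truth$log_dk), 0.1)
  span <- 8.5  # mean index gap between k = {10,11} and {1,2} minus shift
  lambda_dk_adj <- -span / (qc$log_dk * log(10))
  expect_lt(abs(lambda_dk_adj / lambda_true - 1), 0.1)
  # the two-point and profile-fit decay lengths agree with each other
  pf <- fit_decay(decay_profile(sim$chip, qc$regimes, "S", "k"), clamp = TRUE)
  expect_lt(abs(lambda_dk_adj / pf$lambda - 1), 0.1)
})
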