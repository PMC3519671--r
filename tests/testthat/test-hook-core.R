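test_that("sigma/delta transform of PM/MM intensities", {
  expect_equal(sigma_delta(100, 100), list(sigma = 2, delta = 0))
  expect_equal(sigma_delta(1000, 100), list(sigma = 2.5, delta = 1))
  expect_equal(sigma_delta(100, 1000), list(sigma = 2.5, delta = -1))
  expect_error(sigma_delta(c(10, 0), c(10, 10)), "probe\\(s\\) 2")
})

test_that("per-set hook points equal a brute-force recomputation", {
  chip <- flat_chip(n_sets = 5)
  pts <- probeset_hook_points(chip)
  expect_equal(pts$sigma, rep(2, 5))
  expect_equal(pts$delta, rep(0, 5))

  sim <- simulate_chip(sim_config(n_psets = 40), seed = 3)
  pts2 <- probeset_hook_points(sim$chip)
  # oracle: recompute probe by probe with a plain loop
  p <- sim$chip$probes
  for (id in sample(unique(p$probeset_id), 5)) {
    rows <- p[p$probeset_id == id, ]
    sig <- mean((log10(rows$pm) + log10(rows$mm)) / 2)
    del <- mean(log10(rows$pm) - log10(rows$mm))
    expect_equal(pts2$sigma[pts2$probeset_id == id], sig)
    expect_equal(pts2$delta[pts2$probeset_id == id], del)
  }
  expect_false(is.unsorted(pts2$sigma))
})

test_that("moving average: exactness and noise reduction", {
  const <- data.frame(x = 1:50, y = rep(3, 50))
  sm <- moving_average(const, base_window = 11, shrink_tail = FALSE)
  expect_true(all(sm$y == 3))

  five <- data.frame(x = 1:5, delta = 1:5)
  sm3 <- moving_average(five, base_window = 3, shrink_tail = FALSE)
  expect_equal(sm3$delta, c(2, 3, 4))

  # white noise is damped about sqrt(window)-fold
  set.seed(11)
  n <- 6000; w <- 201
  noise <- data.frame(x = seq_len(n), y = rnorm(n))
  smn <- moving_average(noise, base_window = w, shrink_tail = FALSE)
  ratio <- sd(smn$y) / sd(noise$y)
  expect_lt(ratio, 1.6 / sqrt(w))
  expect_gt(ratio, 0.6 / sqrt(w))

  expect_error(moving_average(const[0, ]), "no points")
})

test_that("tail shrinking reduces the window over the top ranks", {
  pts <- data.frame(x = 1:2000, y = rnorm(2000))
  sm <- moving_average(pts, base_window = 400, shrink_tail = TRUE)
  expect_lt(utils::tail(sm$window, 1), 400)
  expect_equal(max(sm$window), 401)  # centered window is rounded to odd
})

test_that("theoretical hook limits", {
  fit <- ref_fit(alpha = 0.85, beta = 6, sigma_start = 1.5)
  at0 <- theoretical_hook(0, fit)
  expect_equal(at0$delta, 0, tolerance = 1e-12)
  expect_equal(at0$sigma, fit$sigma_start, tolerance = 1e-6)

  # R -> Inf: saturation terms cancel alpha, Delta -> 0, Sigma -> logM
  fit2 <- ref_fit(alpha = 0.85, beta = 2, sigma_start = 1.5)
  atInf <- theoretical_hook(1e12, fit2)
  expect_lt(abs(atInf$delta), 1e-6)
  expect_equal(atInf$sigma, fit2$logM, tolerance = 1e-6)

  # S-range with beta >> 1: Delta approaches alpha
  atS <- theoretical_hook(1e4, ref_fit(alpha = 0.85, beta = 12,
                                       sigma_start = 1.5))
  expect_equal(atS$delta, 0.85, tolerance = 1e-3)

  # Sigma is strictly increasing in R, Delta non-negative
  g <- theoretical_hook(10^seq(-4, 8, length.out = 300), fit2)
  expect_true(all(diff(g$sigma) > 0))
  expect_true(all(g$delta >= -1e-12))
})

test_that("hook fit recovers noiseless self-generated parameters", {
  fit_true <- ref_fit(alpha = 0.85, beta = 2, sigma_start = 1.5)
  fit <- fit_hook(theory_curve(fit_true))
  expect_lt(abs(fit$alpha - 0.85), 0.01)
  expect_lt(abs(fit$beta - 2), 0.01)
  expect_lt(abs(fit$sigma_start - 1.5), 0.01)
  expect_lt(abs(fit$logM - fit_true$logM), 0.01)
})

test_that("hook fit rejects degenerate curves", {
  flat <- data.frame(sigma = seq(1, 3, length.out = 100),
                     delta = rep(0.01, 100))
  expect_error(fit_hook(flat), "no specific branch")
  narrow <- data.frame(sigma = seq(1, 1.2, length.out = 100),
                       delta = seq(0, 0.5, length.out = 100))
  expect_error(fit_hook(narrow), "spans")
})

test_that("regime classification endpoints and expression index", {
  fit <- ref_fit(alpha = 0.85, beta = 2.5, sigma_start = 1.5)
  cl <- classify_regimes(c(fit$sigma_start, fit$logM), fit)
  expect_identical(as.character(cl$label), c("N", "as"))

  reg <- data.frame(sigma = rep(2, 10), R = rep(1, 10),
                    label = factor(rep("S", 10),
                                   levels = c("N", "mix", "S", "sat", "as")))
  ei <- expression_index(reg, fit)
  expect_equal(ei$phi, fit$sigma_start - fit$logM)

  regN <- transform(reg, label = factor("N", levels = levels(reg$label)))
  expect_warning(ei2 <- expression_index(regN, fit), "undefined")
  expect_true(is.na(ei2$phi))
})

test_that("doubling specific concentrations raises phi by log10(2)", {
  # expression kept clear of the detection boundary and of saturation so the
  # present ensemble is identical in both runs and the inversion is steep
  base <- sim_config(n_psets = 1200, fraction_absent = 0.2,
                     decay = NULL, expr_decades = 1.5, r_min = 3)
  sim1 <- simulate_chip(base, seed = 5)
  base2 <- base
  base2$r_min <- base$r_min * 2  # doubles every specific concentration
  sim2 <- simulate_chip(base2, seed = 5)
  phi_of <- function(sim) {
    pts <- probeset_hook_points(sim$chip)
    cv <- moving_average(pts[c("sigma", "delta")], 300)
    fit <- fit_hook(cv)
    reg <- chip_regimes(sim$chip, fit)
    expression_index(reg, fit)$phi
  }
  expect_lt(abs(phi_of(sim2) - phi_of(sim1) - log10(2)), 0.05)
})

test_that("percent absent is invariant under global intensity rescaling", {
  sim <- simulate_chip(sim_config(n_psets = 2000), seed = 17)
  run <- function(chip) {
    pts <- probeset_hook_points(chip)
    fit <- fit_hook(moving_average(pts[c("sigma", "delta")], 500))
    pct_absent(chip_regimes(chip, fit))
  }
  p0 <- run(sim$chip)
  scaled <- sim$chip
  scaled$probes$pm <- scaled$probes$pm * 10
  scaled$probes$mm <- scaled$probes$mm * 10
  p1 <- run(scaled)
  expect_lt(abs(p1 - p0), 0.02)
})
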