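test_that("probe position is the distance from the target 3' end", {
  set.seed(7)
  target <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                  collapse = "")
  # probe equal to the final 25 nt abuts the 3' terminus
  expect_identical(compute_probe_position(substr(target, 76, 100), target), 0L)
  # probe occupying positions 26..50 counted from the 3' end: 25 nt between
  # the terminus and its nearest base
  expect_identical(compute_probe_position(substr(target, 51, 75), target), 25L)
  expect_identical(compute_probe_position(substr(target, 1, 25), target), 75L)
  # U and T are equivalent
  probe_u <- chartr("T", "U", substr(target, 76, 100))
  expect_identical(compute_probe_position(probe_u, target), 0L)
})

test_that("probe position errors and multi-match handling", {
  target <- strrep("ACGT", 30)
  expect_error(compute_probe_position(strrep("A", 25), target), "not found")
  expect_error(compute_probe_position("ACGT", target), "25-mer")
  expect_error(compute_probe_position(strrep("N", 25), target), "outside")
  # repeated target: the most 3' (smallest L) match wins, with a warning
  expect_warning(L <- compute_probe_position(substr(target, 1, 25), target),
                 "most 3'")
  expect_identical(L, as.integer(nchar(target) - 25 -
                                   (max(gregexpr(substr(target, 1, 25),
                                                 target, fixed = TRUE)[[1]]) - 1)))
})

test_that("mean probe spacing estimators on exact and noisy layouts", {
  chip <- flat_chip(n_sets = 40)  # L = 50 * (k - 1)
  sp <- mean_probe_spacing(chip)
  expect_equal(sp$slope, 50, tolerance = 1e-12)
  expect_equal(sp$two_point, 50, tolerance = 1e-12)

  # noisy layout: slope stays within [45, 55]; oracle is the closed-form
  # least-squares slope on the same medians
  set.seed(42)
  n_sets <- 200; n <- 11
  k <- rep(seq_len(n), n_sets)
  L <- 50 * (k - 1) + round(runif(n_sets * n, -5, 5))
  chip2 <- chip_data(data.frame(
    probeset_id = rep(sprintf("s%03d", seq_len(n_sets)), each = n),
    k = k, L = pmax(L, 0), pm = 100, mm = 100))
  sp2 <- mean_probe_spacing(chip2)
  med <- tapply(chip2$probes$L, chip2$probes$k, median)
  ks <- as.numeric(names(med))
  slope_oracle <- sum((ks - mean(ks)) * (med - mean(med))) /
    sum((ks - mean(ks))^2)
  expect_equal(sp2$slope, slope_oracle, tolerance = 1e-10)
  expect_gt(sp2$slope, 45); expect_lt(sp2$slope, 55)
})

test_that("spacing degenerate cases", {
  chip <- flat_chip(n_sets = 5)
  chip$probes$L <- 100L
  expect_warning(sp <- mean_probe_spacing(chip), "degenerate")
  expect_equal(sp$slope, 0)
  expect_equal(sp$two_point, 0)

  one_k <- chip_data(data.frame(probeset_id = rep("a", 3), k = c(1, 1, 1) + 0:2,
                                L = 0:2, pm = 1, mm = 1))
  one_k$probes$k <- 1L   # force a single index
  expect_error(mean_probe_spacing(one_k), "distinct")
})

test_that("two-point spacing is translation invariant, the ratio is not", {
  chip <- flat_chip(n_sets = 20)
  sp0 <- mean_probe_spacing(chip)
  chip$probes$L <- chip$probes$L + 200L
  sp1 <- mean_probe_spacing(chip)
  expect_equal(sp1$two_point, sp0$two_point)
  expect_equal(sp1$slope, sp0$slope)
  expect_gt(sp1$ratio, sp0$ratio)  # vanishing-intercept estimator shifts
})

test_that("probe-set span classification", {
  expect_identical(classify_probeset_span(50, 300), "LL")
  expect_identical(classify_probeset_span(50, 700), "LH")
  expect_identical(classify_probeset_span(200, 700), "HH")
  expect_identical(classify_probeset_span(200, 400), "HL")
  expect_error(classify_probeset_span(-1, 300), "non-negative")
  expect_error(classify_probeset_span(500, 300), "exceed")
})

test_that("chip ingest validates and filters probe sets", {
  df <- data.frame(probeset_id = rep(c("a", "b"), c(11, 2)),
                   k = c(1:11, 1:2), L = 0, pm = 100, mm = 100)
  expect_message(chip <- chip_data(df), "fewer than 3")
  expect_identical(n_psets(chip), 1L)
  expect_identical(pset_size(chip), 11L)

  df2 <- df[df$probeset_id == "a", ]
  df2$pm[3] <- -5
  expect_error(chip_data(df2), "non-positive PM")

  df3 <- df[df$probeset_id == "a", ]
  df3$k[2] <- 1L
  expect_error(chip_data(df3), "duplicate")

  # missing MM pairs are dropped, set retained while >= 3 pairs remain
  df4 <- df[df$probeset_id == "a", ]
  df4$mm[1:2] <- NA
  expect_message(chip4 <- chip_data(df4), "dropped")
  expect_identical(nrow(chip4$probes), 9L)
})

test_that("vendor probe ordering can be reversed on ingest", {
  df <- data.frame(probeset_id = rep("a", 11), k = 1:11,
                   L = 50 * (10:0), pm = 100, mm = 100)
  chip <- chip_data(df, reverse_k = TRUE)
  expect_equal(chip$probes$L[chip$probes$k == 1], 0)
  expect_equal(chip$probes$L[chip$probes$k == 11], 500)
})
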