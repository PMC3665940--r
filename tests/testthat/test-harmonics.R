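test_that("cycle boundaries land on the gait period", {
  tr <- clean_trial(3.5, duration_s = 10)       # f1 = 0.8 Hz
  b <- detect_cycles(tr)
  expect_gte(length(b), 7L)
  expect_equal(unname(diff(b)), rep(1.25, length(b) - 1), tolerance = 0.02)
})

test_that("degenerate channels raise an insufficient-data error", {
  flat <- elevation_series(matrix(5, 200, 6), 100)
  expect_error(detect_cycles(flat), "insufficient data")
})

test_that("cycle spacing stays regular under period jitter", {
  tr <- generate_trial(gait_config(velocity_kmh = 3, duration_s = 20,
                                   noise_sd = 0, cycle_jitter = 0.05,
                                   seed = 3))
  b <- detect_cycles(tr)
  sp <- diff(b)
  expect_lte(sd(sp) / mean(sp), 0.1)
})

test_that("perfect periodicity selects the earliest cycle pair", {
  tr <- clean_trial(3.5, duration_s = 10)
  seg <- select_representative_cycles(tr)
  b <- detect_cycles(tr)
  expect_equal(seg$start, round(b[1] * tr$sample_rate) + 1L)
  expect_equal(seg$Tc, 1.25, tolerance = 0.01)
})

test_that("a corrupted cycle is excluded from the representative pair", {
  tr <- clean_trial(3.5, duration_s = 12, seed = 5)
  b <- detect_cycles(tr)
  idx <- round(b * tr$sample_rate) + 1L
  # inject a spike into the middle of the fourth cycle, all channels
  spike <- seq(idx[4] + 40L, idx[4] + 55L)
  tr$angles[spike, ] <- tr$angles[spike, ] + 40
  seg <- suppressWarnings(select_representative_cycles(tr))
  expect_true(seg$end <= min(spike) || seg$start >= max(spike))
  # oracle: the chosen pair is the global minimizer of the spectral distance
  expect_equal(min(seg$distance),
               seg$distance[which(seg$start == idx[seq_along(seg$distance)])])
})

test_that("representative pair preserves the full-record fundamental", {
  tr <- generate_trial(gait_config(velocity_kmh = 3, duration_s = 20,
                                   seed = 8))
  seg <- select_representative_cycles(tr)
  sp_seg <- extract_harmonics(seg)
  sp_all <- extract_harmonics(tr)
  expect_lt(abs(sp_seg$f1 - sp_all$f1), sp_seg$bin)
})

test_that("a pure tone reads back as its own fundamental", {
  tt <- seq(0, 10 - 0.01, by = 0.01)
  x <- sin(2 * pi * 0.8 * tt)
  sp <- suppressWarnings(extract_harmonics(matrix(x), sample_rate = 100))
  expect_equal(sp$f1, 0.8, tolerance = 1e-6)
  expect_equal(sp$a1, 1, tolerance = 1e-6)
  expect_lt(sp$a2, 0.01)
  expect_lt(sp$a3, 0.01)
})

test_that("no spectral peak in band raises an extraction error", {
  tt <- seq(0, 10 - 0.01, by = 0.01)
  x <- sin(2 * pi * 5 * tt)          # well above the physiologic band
  expect_error(extract_harmonics(matrix(x), sample_rate = 100),
               "no spectral peak")
})

test_that("oscillator inputs obey the closed forms of each variant", {
  spec <- list(f1 = 1, f2 = 2, f3 = 3, a1 = 2, a2 = 1, a3 = 0.5)
  tt <- seq(0, 2, by = 0.01)
  sea <- build_sine_inputs(spec, "SEA", tt)
  i25 <- which.min(abs(tt - 0.25))
  expect_equal(unname(sea$signals[i25, "y1_pos"]), sin(pi / 2),
               tolerance = 1e-12)
  expect_equal(unname(sea$signals[i25, "y1_neg"]), -1, tolerance = 1e-12)
  expect_equal(sea$freqs, c(1, 2, 3))

  seb <- build_sine_inputs(spec, "SEB", tt)
  expect_equal(seb$freqs, c(1.25, 2.50, 3.75))
  sec <- build_sine_inputs(spec, "SEC", tt)
  expect_equal(sec$freqs, c(0.75, 1.50, 2.25))
  expect_error(build_sine_inputs(list(f1 = 0.2), "SEC", tt), "not positive")

  am <- build_sine_inputs(spec, "AM", tt)
  expect_equal(unname(apply(abs(am$signals), 2, max)),
               c(2, 2, 1, 1, 0.5, 0.5), tolerance = 5e-3)
})

test_that("oscillator channel pairs are exactly anti-symmetric", {
  spec <- list(f1 = 0.73, f2 = 1.46, f3 = 2.19, a1 = 1.7, a2 = 0.6, a3 = 0.2)
  tt <- seq(0, 3, by = 0.01)
  for (v in c("SEA", "SEB", "SEC", "AM")) {
    s <- build_sine_inputs(spec, v, tt)$signals
    expect_identical(s[, c(2, 4, 6)], -s[, c(1, 3, 5)],
                     ignore_attr = TRUE)
  }
})

test_that("target normalization is an exact affine round trip", {
  x <- cbind(a = seq(-30, 50, length.out = 101),
             b = sin(seq(0, 7, length.out = 101)))
  nt <- normalize_targets(x)
  expect_equal(unname(nt$scale["a"]), 40)
  expect_equal(unname(nt$offset["a"]), 10)
  expect_equal(range(nt$signals[, 1]), c(-1, 1))
  expect_equal(denormalize_targets(nt$signals, nt), x, ignore_attr = TRUE,
               tolerance = 1e-12)
  # already-normalized input is a fixed point
  nt2 <- normalize_targets(nt$signals)
  expect_equal(nt2$signals, nt$signals, tolerance = 1e-12)
  expect_error(normalize_targets(cbind(rep(1, 10), 1:10)),
               "degenerate normalization")
})
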