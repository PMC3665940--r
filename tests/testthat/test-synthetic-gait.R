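test_that("trial shape and grid follow the configuration", {
  tr <- generate_trial(gait_config(velocity_kmh = 3, duration_s = 5,
                                   sample_rate_hz = 100, seed = 1))
  expect_s3_class(tr, "elevation_series")
  expect_equal(dim(tr$angles), c(500L, 6L))
  expect_equal(colnames(tr$angles),
               c("left_thigh", "left_shank", "left_foot",
                 "right_thigh", "right_shank", "right_foot"))
  expect_true(all(is.finite(tr$angles)))
  expect_equal(diff(tr$time)[1], 0.01, tolerance = 1e-12)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- gait_config(velocity_kmh = 2, duration_s = 6, seed = 42)
  expect_identical(generate_trial(cfg)$angles, generate_trial(cfg)$angles)
  cfg0 <- gait_config(velocity_kmh = 2, duration_s = 6,
                      noise_sd = 0, cycle_jitter = 0, seed = 7)
  cfg1 <- cfg0; cfg1$seed <- 99
  expect_identical(generate_trial(cfg0)$angles, generate_trial(cfg1)$angles)
})

test_that("invalid configurations are rejected", {
  expect_error(gait_config(duration_s = -1), "invalid config")
  expect_error(gait_config(sample_rate_hz = 0), "invalid config")
  expect_error(gait_config(left_right_shift = 1), "invalid config")
  bad_amp <- function(v) matrix(-1, 3, 3)
  expect_error(generate_trial(gait_config(amplitude_map = bad_amp)),
               "invalid config")
  expect_error(generate_trial(gait_config(duration_s = 1)), "2 gait cycles")
  expect_error(generate_dataset(numeric(0)), "non-empty")
})

test_that("right leg lags the left leg by half a cycle", {
  tr <- clean_trial(3.5, duration_s = 10)   # f1 = 0.8 -> 125-sample period
  half <- 125 / 2
  lt <- tr$angles[, "left_thigh"]; rt <- tr$angles[, "right_thigh"]
  # cross-correlation peaks at a half-period lag
  lags <- 50:75
  cc <- vapply(lags, function(L)
    cor(lt[1:(1000 - L)], rt[(1 + L):1000]), numeric(1))
  expect_equal(lags[which.max(cc)], round(half), tolerance = 1)
})

test_that("spectral peaks sit at f1, 2 f1 and 3 f1 within one bin", {
  tr <- clean_trial(3, duration_s = 20)
  sp <- extract_harmonics(tr)
  expect_true(sp$harmonic_ok)
  expect_lt(abs(sp$f2 - 2 * sp$f1), sp$bin)
  expect_lt(abs(sp$f3 - 3 * sp$f1), sp$bin)
  f1_true <- default_fundamental_map(3)
  expect_lt(abs(sp$f1 - f1_true), sp$bin)
})

test_that("harmonic closure: generator amplitudes are recovered within 5%", {
  amp <- function(v) matrix(rep(c(10, 4, 1), each = 3), 3, 3)
  tr <- generate_trial(gait_config(velocity_kmh = 3, duration_s = 20,
                                   amplitude_map = amp, noise_sd = 0,
                                   cycle_jitter = 0, seed = 2))
  sp <- extract_harmonics(tr)
  expect_equal(sp$a1, 10, tolerance = 0.05)
  expect_equal(sp$a2 / sp$a1, 0.4, tolerance = 0.05)
  expect_equal(sp$a3 / sp$a1, 0.1, tolerance = 0.05)
})

test_that("velocity trends: f1 strictly increasing, a1 non-decreasing", {
  ds <- generate_dataset(c(1.5, 2.5, 3.5, 4.5, 5.5),
                         gait_config(duration_s = 20, seed = 7))
  sps <- lapply(ds, extract_harmonics)
  f1 <- vapply(sps, `[[`, numeric(1), "f1")
  a1 <- vapply(sps, `[[`, numeric(1), "a1")
  expect_true(all(diff(f1) > 0))
  expect_true(all(diff(a1) >= 0))
})

test_that("first two harmonics dominate the waveform variance", {
  ds <- generate_dataset(c(1.5, 3.5, 5.5),
                         gait_config(duration_s = 20, noise_sd = 0,
                                     cycle_jitter = 0, seed = 11))
  for (tr in ds)
    expect_true(all(harmonic_variance_fraction(tr) >= 0.98))
  # with measurement noise and stride jitter the lines broaden but the
  # first two harmonics still carry almost all the variance
  noisy <- generate_trial(gait_config(duration_s = 20, seed = 11))
  expect_true(all(harmonic_variance_fraction(noisy) >= 0.95))
})

test_that("default segment phasing yields a planar covariation loop", {
  for (seed in 1:3) {
    tr <- clean_trial(3, duration_s = 10, seed = seed)
    seg <- select_representative_cycles(tr)
    nt <- normalize_targets(seg)
    for (side in c("left", "right")) {
      cols <- paste(side, c("thigh", "shank", "foot"), sep = "_")
      pl <- fit_covariation_plane(nt$signals[, cols])
      expect_gte(pl$planarity, 0.98)
    }
  }
})

test_that("singleton dataset equals a single trial", {
  cfg <- gait_config(duration_s = 8, noise_sd = 0, cycle_jitter = 0)
  ds <- generate_dataset(3, cfg)
  expect_length(ds, 1L)
  cfg$velocity_kmh <- 3
  expect_identical(ds[[1]]$angles, generate_trial(cfg)$angles)
})
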