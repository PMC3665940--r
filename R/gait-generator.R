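#' Configuration for the synthetic gait generator
#'
#' The generator replaces treadmill motion-capture recordings with
#' three-harmonic elevation-angle waveforms that carry the spectral and
#' inter-segmental structure the downstream analysis assumes: a gait
#' fundamental `f1` increasing with walking speed, harmonics locked at
#' `2*f1` and `3*f1`, first-two-harmonic dominance (>= 98% of waveform
#' variance), a half-cycle left-right shift, and segment phase lags that
#' produce the elliptic, nearly planar covariation loop of thigh-shank-foot
#' elevation angles.
#'
#' Defaults are frozen package-level choices for plausible adult treadmill
#' walking (see the methods vignette): fundamental 0.6 Hz at 1 km/h rising
#' linearly to 1.0 Hz at 6 km/h; first-harmonic amplitudes of 20, 35 and
#' 45 degrees (thigh, shank, foot) at 3 km/h, growing 6% per km/h; harmonic
#' amplitude ratios and segment phase offsets tuned once so the default loop
#' is planar (>= 98% of variance in the first two principal components).
#'
#' @param velocity_kmh walking speed in km/h.
#' @param duration_s trial duration in seconds.
#' @param sample_rate_hz sampling rate in Hz.
#' @param fundamental_map function velocity -> fundamental frequency f1 (Hz);
#'   must be strictly increasing on the velocity range used.
#' @param amplitude_map function velocity -> 3 x 3 non-negative matrix of
#'   harmonic amplitudes in degrees, rows = segments (thigh, shank, foot),
#'   columns = harmonics 1..3.
#' @param segment_phases 3 x 3 matrix of phase offsets (radians), same layout.
#' @param left_right_shift right-leg delay as a fraction of the gait cycle,
#'   in `[0, 1)`.
#' @param noise_sd additive i.i.d. Gaussian noise per sample (degrees).
#' @param cycle_jitter fractional standard deviation of per-cycle period
#'   perturbations.
#' @param seed integer seed for noise and jitter; `NULL` leaves the RNG alone.
#' @return A list of class `gait_config`.
#' @export
gait_config <- function(velocity_kmh = 3,
                        duration_s = 40,
                        sample_rate_hz = 100,
                        fundamental_map = default_fundamental_map,
                        amplitude_map = default_amplitude_map,
                        segment_phases = default_segment_phases(),
                        left_right_shift = 0.5,
                        noise_sd = 0.3,
                        cycle_jitter = 0.02,
                        seed = NULL) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("invalid config: duration_s must be positive")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    stop("invalid config: sample_rate_hz must be positive")
  if (!is.function(fundamental_map) || !is.function(amplitude_map))
    stop("invalid config: fundamental_map and amplitude_map must be functions")
  if (left_right_shift < 0 || left_right_shift >= 1)
    stop("invalid config: left_right_shift must lie in [0, 1)")
  if (noise_sd < 0 || cycle_jitter < 0)
    stop("invalid config: noise_sd and cycle_jitter must be non-negative")
  segment_phases <- as.matrix(segment_phases)
  if (!all(dim(segment_phases) == c(3L, 3L)))
    stop("invalid config: segment_phases must be a 3 x 3 matrix")
  structure(
    list(velocity_kmh = velocity_kmh, duration_s = duration_s,
         sample_rate_hz = sample_rate_hz, fundamental_map = fundamental_map,
         amplitude_map = amplitude_map, segment_phases = segment_phases,
         left_right_shift = left_right_shift, noise_sd = noise_sd,
         cycle_jitter = cycle_jitter, seed = seed),
    class = "gait_config")
}

#' @rdname gait_config
#' @export
default_fundamental_map <- function(velocity_kmh) {
  # 0.6 Hz at 1 km/h to 1.0 Hz at 6 km/h, linear: plausible stride rates.
  0.52 + 0.08 * velocity_kmh
}

#' @rdname gait_config
#' @export
default_amplitude_map <- function(velocity_kmh) {
  base <- c(thigh = 20, shank = 35, foot = 45)        # degrees at 3 km/h
  ratios <- rbind(thigh = c(1, 0.15, 0.05),
                  shank = c(1, 0.22, 0.08),
                  foot  = c(1, 0.28, 0.10))
  scale <- 1 + 0.06 * (velocity_kmh - 3)
  out <- ratios * base * scale
  colnames(out) <- paste0("h", 1:3)
  out
}

#' @rdname gait_config
#' @export
default_segment_phases <- function() {
  # First-harmonic lags thigh -> shank -> foot shape the elliptic loop;
  # shared higher-harmonic phases keep the loop planar (tuned once against
  # the planarity target, see vignette).
  rbind(thigh = c(0.0, 1.1, 0.8),
        shank = c(-1.1, 1.1, 0.8),
        foot  = c(-1.45, 1.1, 0.8))
}

# Piecewise-linear gait phase (radians) on grid `tt`, with per-cycle period
# jitter. Without jitter this is exactly 2*pi*f1*t.
gait_phase <- function(tt, f1, cycle_jitter) {
  if (cycle_jitter <= 0) return(2 * pi * f1 * tt)
  period <- 1 / f1
  n_cycles <- ceiling(max(tt) / period) + 2L
  periods <- period * (1 + rnorm(n_cycles, 0, cycle_jitter))
  periods <- pmax(periods, 0.2 * period)
  bounds <- c(0, cumsum(periods))
  k <- findInterval(tt, bounds, rightmost.closed = FALSE)
  2 * pi * ((k - 1) + (tt - bounds[k]) / periods[k])
}

#' Generate one synthetic gait trial
#'
#' Each channel is `theta(t) = sum_{k=1..3} A_k sin(k * phi(t) + phase_k)`
#' plus optional Gaussian noise, where `phi` is the (possibly jittered) gait
#' phase at fundamental `f1 = fundamental_map(velocity)`. Right-side channels
#' are the left-side channels delayed by `left_right_shift` of a cycle.
#'
#' @param config a [gait_config()].
#' @return An [elevation_series()].
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "gait_config"))
  f1 <- config$fundamental_map(config$velocity_kmh)
  if (!is.finite(f1) || f1 <= 0)
    stop("invalid config: fundamental_map returned a non-positive frequency")
  if (config$duration_s * f1 < 2)
    stop("invalid config: trial must span at least 2 gait cycles")
  if (config$sample_rate_hz < 20 * 3 * f1)
    stop("invalid config: sample rate must be at least 20 x the third harmonic")
  A <- config$amplitude_map(config$velocity_kmh)
  if (any(A < 0) || !all(dim(as.matrix(A)) == c(3L, 3L)))
    stop("invalid config: amplitude_map must return a non-negative 3 x 3 matrix")
  A <- as.matrix(A)

  n <- round(config$duration_s * config$sample_rate_hz)
  tt <- (seq_len(n) - 1L) / config$sample_rate_hz

  angles <- with_seed(config$seed, {
    phi_left <- gait_phase(tt, f1, config$cycle_jitter)
    phi <- list(left = phi_left,
                right = phi_left - 2 * pi * config$left_right_shift)
    out <- matrix(0, n, 6L, dimnames = list(NULL, elevation_channels()))
    for (side in c("left", "right")) {
      for (s in seq_along(gait_segments())) {
        ch <- paste(side, gait_segments()[s], sep = "_")
        th <- rep(0, n)
        for (k in 1:3)
          th <- th + A[s, k] * sin(k * phi[[side]] + config$segment_phases[s, k])
        out[, ch] <- th
      }
    }
    if (config$noise_sd > 0)
      out <- out + matrix(rnorm(n * 6L, 0, config$noise_sd), n, 6L)
    out
  })

  elevation_series(angles, config$sample_rate_hz,
                   velocity_kmh = config$velocity_kmh,
                   meta = list(seed = config$seed, f1 = f1,
                               noise_sd = config$noise_sd,
                               cycle_jitter = config$cycle_jitter))
}

#' Generate one trial per walking velocity
#'
#' @param velocities vector of walking speeds in km/h (non-empty).
#' @param base_config a [gait_config()] supplying everything but the velocity;
#'   per-trial seeds are derived from `base_config$seed`.
#' @return A named list of [elevation_series()], one per velocity.
#' @export
generate_dataset <- function(velocities, base_config = gait_config()) {
  if (length(velocities) == 0)
    stop("invalid config: velocities must be non-empty")
  stopifnot(inherits(base_config, "gait_config"))
  f1s <- vapply(velocities, base_config$fundamental_map, numeric(1))
  if (is.unsorted(f1s[order(velocities)], strictly = TRUE))
    stop("invalid config: fundamental_map must be strictly increasing in velocity")
  seeds <- derive_seeds(base_config$seed, length(velocities))
  out <- lapply(seq_along(velocities), function(i) {
    cfg <- base_config
    cfg$velocity_kmh <- velocities[i]
    cfg$seed <- seeds[[i]]
    generate_trial(cfg)
  })
  names(out) <- paste0("v", velocities)
  out
}
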