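#' Detect gait-cycle boundaries
#'
#' Cycle boundaries are placed at successive maxima of the (lightly smoothed)
#' right-thigh elevation angle, the least noisy and most sinusoidal of the
#' six channels. Maxima closer than half the median spacing are merged
#' (keeping the higher peak).
#'
#' @param series an [elevation_series()].
#' @param channel channel used for peak picking.
#' @param smooth_s moving-average window in seconds applied before peak
#'   detection.
#' @return Numeric vector of boundary times (seconds), length >= 3.
#' @export
detect_cycles <- function(series, channel = "right_thigh", smooth_s = 0.15) {
  stopifnot(inherits(series, "elevation_series"))
  x <- series$angles[, channel]
  rate <- series$sample_rate
  w <- max(1L, round(smooth_s * rate))
  if (w > 1L) {
    kern <- rep(1 / w, w)
    xs <- stats::filter(x, kern, sides = 2)
    xs[is.na(xs)] <- x[is.na(xs)]
    x <- as.numeric(xs)
  }
  if (diff(range(x)) < 1e-8)
    stop("insufficient data: channel is constant, no cycles to detect")
  # expected period from the channel's own spectral fundamental; noisy
  # flat-topped maxima are then merged within 60% of a period
  f1 <- tryCatch(channel_harmonics(x, rate)$f1_ref,
                 error = function(e) NA_real_)
  min_gap <- if (is.finite(f1) && f1 > 0) round(0.6 / f1 * rate) else
    round(0.3 * length(x) / 3)
  d <- diff(x)
  peaks <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  # drop low-amplitude ripples: keep peaks above the channel midline
  peaks <- peaks[x[peaks] > mean(range(x))]
  if (length(peaks) >= 2L) {
    keep <- rep(TRUE, length(peaks))
    for (i in seq_along(peaks)[-1]) {
      prev <- max(which(keep[seq_len(i - 1L)]))
      if (peaks[i] - peaks[prev] < min_gap) {
        if (x[peaks[i]] > x[peaks[prev]]) keep[prev] <- FALSE else keep[i] <- FALSE
      }
    }
    peaks <- peaks[keep]
  }
  if (length(peaks) < 3L)
    stop("insufficient data: fewer than 3 cycle maxima found")
  spacing <- diff(peaks)
  if (any(abs(spacing - median(spacing)) > 0.3 * median(spacing)))
    warning("cycle spacing deviates more than 30% from the median period")
  (peaks - 1L) / rate
}

#' Select the two consecutive gait cycles most representative of a trial
#'
#' Among all pairs of consecutive detected cycles, picks the pair whose FFT
#' peak (frequency, amplitude) triplets are closest to those of the full
#' recording: distance is the sum over the three harmonics of relative
#' frequency error plus relative amplitude error, equally weighted. Ties go
#' to the earliest pair.
#'
#' @param series an [elevation_series()].
#' @return An object of class `cycle_segment`: list with `start`/`end`
#'   (sample indices), `angles` (the excised waveforms), `time` (seconds,
#'   from 0), `Tc` (mean cycle period, s), `sample_rate`, `velocity_kmh`,
#'   `distance` (per-pair spectral distances).
#' @export
select_representative_cycles <- function(series) {
  stopifnot(inherits(series, "elevation_series"))
  bounds <- detect_cycles(series)
  rate <- series$sample_rate
  idx <- round(bounds * rate) + 1L
  ref <- extract_harmonics(series)
  n_pairs <- length(idx) - 2L
  dist <- numeric(n_pairs)
  for (p in seq_len(n_pairs)) {
    seg <- series$angles[idx[p]:idx[p + 2L], , drop = FALSE]
    sp <- extract_harmonics(seg, sample_rate = rate)
    fr <- c(sp$f1, sp$f2, sp$f3); fr0 <- c(ref$f1, ref$f2, ref$f3)
    am <- c(sp$a1, sp$a2, sp$a3); am0 <- c(ref$a1, ref$a2, ref$a3)
    dist[p] <- sum(abs(fr - fr0) / fr0) + sum(abs(am - am0) / pmax(am0, 1e-12))
  }
  best <- which(dist <= min(dist) + 1e-9)[1]    # earliest on (near-)ties
  i0 <- idx[best]; i1 <- idx[best + 2L]
  structure(
    list(start = i0, end = i1,
         angles = series$angles[i0:i1, , drop = FALSE],
         time = (seq_len(i1 - i0 + 1L) - 1L) / rate,
         Tc = (i1 - i0) / (2 * rate),
         sample_rate = rate,
         velocity_kmh = series$velocity_kmh,
         distance = dist),
    class = "cycle_segment")
}

# Single-channel FFT harmonic read-out. Rectangular window, zero-padding
# x `pad` for peak localization; amplitudes are linear single-sided
# magnitudes (a pure A*sin tone of integer period count reads back as A).
channel_harmonics <- function(x, rate, band = c(0.3, 2), pad = 4L) {
  x <- x - mean(x)
  n <- length(x)
  nfft <- pad * n
  sp <- abs(fft(c(x, rep(0, nfft - n)))) * 2 / n
  freqs <- (seq_len(nfft) - 1L) * rate / nfft
  half <- seq_len(floor(nfft / 2))
  sp <- sp[half]; freqs <- freqs[half]
  bin <- rate / n                                # pre-padding resolution
  in_band <- which(freqs >= band[1] & freqs <= band[2])
  if (length(in_band) == 0 || max(sp) <= 0 ||
      max(sp[in_band]) < 0.05 * max(sp))
    stop("harmonic extraction failed: no spectral peak in band [",
         band[1], ", ", band[2], "] Hz")
  i1 <- in_band[which.max(sp[in_band])]
  f1 <- freqs[i1]
  # sub-bin fundamental by maximizing the variance explained by a
  # quadrature (sin, cos) pair at frequency f; unlike a plain DTFT peak
  # this is unbiased by the negative-frequency mirror of a real tone
  tt <- (seq_len(n) - 1L) / rate
  expl_ss <- function(f) {
    A <- cbind(sin(2 * pi * f * tt), cos(2 * pi * f * tt))
    cf <- solve(crossprod(A), crossprod(A, x))
    sum((A %*% cf)^2)
  }
  f1_ref <- stats::optimize(expl_ss, c(f1 - bin / 2, f1 + bin / 2),
                            maximum = TRUE, tol = 1e-7)$maximum
  out <- list(f = numeric(3), a = numeric(3), f1_ref = f1_ref)
  out$f[1] <- f1; out$a[1] <- sp[i1]
  # +/- 2 bins around k*f1, capped so the window can never reach the
  # neighbouring harmonic (short two-cycle segments have coarse bins);
  # candidates restricted to pre-padding bins — between-bin points of a
  # zero-padded spectrum carry kernel skirts, not harmonic energy
  half_width <- min(2 * bin, 0.45 * f1)
  on_grid <- (seq_along(freqs) - 1L) %% pad == 0L
  for (k in 2:3) {
    win <- which(abs(freqs - k * f1) <= half_width & on_grid)
    if (length(win) == 0) win <- which(abs(freqs - k * f1) <= half_width)
    ik <- win[which.max(sp[win])]
    out$f[k] <- freqs[ik]; out$a[k] <- sp[ik]
  }
  out$bin <- bin
  out
}

#' Extract first-three-harmonic characteristics
#'
#' Reads the frequencies `f1, f2, f3` and linear peak amplitudes
#' `a1, a2, a3` of the first three gait harmonics from the FFT of each
#' channel, then aggregates across channels (median `f1..f3`, mean
#' amplitudes) for robustness to a noisy channel. The fundamental is the
#' largest peak in the physiologic band; higher harmonics are read at the
#' maximal bins within two (pre-padding) frequency bins of `k * f1`. For
#' inputs longer than four cycles the series is first truncated to an
#' integer number of estimated periods so the rectangular window is
#' leakage-free.
#'
#' @param x an [elevation_series()], a `cycle_segment`, a numeric matrix
#'   (samples x channels) or a numeric vector.
#' @param sample_rate required when `x` is a bare matrix/vector.
#' @param band frequency band (Hz) searched for the fundamental.
#' @return An object of class `harmonic_spec`: list with `f1,f2,f3` (Hz),
#'   `a1,a2,a3` (linear magnitudes), `bin` (Hz), `per_channel` (matrix),
#'   `velocity_kmh`, `harmonic_ok` (logical: `|f_k - k f1| <= 1` bin).
#' @export
extract_harmonics <- function(x, sample_rate = NULL, band = c(0.3, 2)) {
  velocity <- NA_real_
  if (inherits(x, "elevation_series")) {
    sample_rate <- x$sample_rate; velocity <- x$velocity_kmh; x <- x$angles
  } else if (inherits(x, "cycle_segment")) {
    sample_rate <- x$sample_rate; velocity <- x$velocity_kmh; x <- x$angles
  }
  if (is.null(sample_rate))
    stop("sample_rate is required for matrix or vector input")
  x <- as.matrix(x)

  extract_one <- function(col) {
    h <- channel_harmonics(col, sample_rate, band)
    # long records: truncate to integer periods and re-read, killing leakage
    n_per <- h$f1_ref * length(col) / sample_rate
    if (n_per > 4) {
      n_keep <- floor(floor(n_per) / h$f1_ref * sample_rate)
      if (n_keep >= 2 / h$f1_ref * sample_rate)
        h <- channel_harmonics(col[seq_len(n_keep)], sample_rate, band)
    }
    h
  }
  hs <- lapply(seq_len(ncol(x)), function(j) extract_one(x[, j]))
  per_channel <- t(vapply(hs, function(h) c(h$f, h$a), numeric(6)))
  colnames(per_channel) <- c("f1", "f2", "f3", "a1", "a2", "a3")
  if (!is.null(colnames(x))) rownames(per_channel) <- colnames(x)

  f <- apply(per_channel[, 1:3, drop = FALSE], 2, median)
  a <- colMeans(per_channel[, 4:6, drop = FALSE])
  bin <- hs[[1]]$bin
  ok <- abs(f[2] - 2 * f[1]) <= bin && abs(f[3] - 3 * f[1]) <= bin
  if (!ok)
    warning("harmonic relation f2 = 2 f1, f3 = 3 f1 violated beyond one FFT bin")
  structure(
    list(f1 = unname(f[1]), f2 = unname(f[2]), f3 = unname(f[3]),
         a1 = unname(a[1]), a2 = unname(a[2]), a3 = unname(a[3]),
         bin = bin, per_channel = per_channel, velocity_kmh = velocity,
         harmonic_ok = ok),
    class = "harmonic_spec")
}

#' @export
print.harmonic_spec <- function(x, ...) {
  cat(sprintf("<harmonic_spec> f = (%.4g, %.4g, %.4g) Hz, a = (%.4g, %.4g, %.4g)\n",
              x$f1, x$f2, x$f3, x$a1, x$a2, x$a3))
  invisible(x)
}

#' Save / load a harmonic spec as JSON
#'
#' Frequencies in Hz, amplitudes as unitless linear magnitudes. A
#' [build_sine_inputs()] set is reconstructed from a spec plus variant and
#' time grid, so the spec file is the unit of exchange.
#'
#' @param spec a [extract_harmonics()] result.
#' @param path file path.
#' @return `write_harmonic_spec` returns `path` invisibly;
#'   `read_harmonic_spec` returns a `harmonic_spec`.
#' @export
write_harmonic_spec <- function(spec, path) {
  stopifnot(inherits(spec, "harmonic_spec"))
  payload <- unclass(spec)
  payload$per_channel <- as.data.frame(payload$per_channel)
  payload$channel <- rownames(spec$per_channel)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_harmonic_spec
#' @export
read_harmonic_spec <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  pc <- as.matrix(p$per_channel)
  rownames(pc) <- p$channel
  structure(
    list(f1 = p$f1, f2 = p$f2, f3 = p$f3, a1 = p$a1, a2 = p$a2, a3 = p$a3,
         bin = p$bin, per_channel = pc,
         velocity_kmh = p$velocity_kmh %||% NA_real_,
         harmonic_ok = isTRUE(p$harmonic_ok)),
    class = "harmonic_spec")
}

#' Fraction of waveform variance carried by the first two harmonics
#'
#' For each channel: truncate to an integer number of fundamental periods
#' (leakage-free rectangular window), read the first three harmonic
#' amplitudes and return `(a1^2 + a2^2) / 2` divided by the truncated
#' waveform's variance. This is the quantity behind the "first two Fourier
#' harmonics carry ~98% of the variance" property of gait elevation angles.
#'
#' @param series an [elevation_series()] (or matrix with `sample_rate`).
#' @inheritParams extract_harmonics
#' @return Named numeric vector, one fraction in `[0, 1]` per channel.
#' @export
harmonic_variance_fraction <- function(series, sample_rate = NULL,
                                       band = c(0.3, 2)) {
  if (inherits(series, "elevation_series")) {
    sample_rate <- series$sample_rate
    x <- series$angles
  } else {
    x <- as.matrix(series)
    if (is.null(sample_rate)) stop("sample_rate is required for matrix input")
  }
  out <- vapply(seq_len(ncol(x)), function(j) {
    col <- x[, j]
    h <- channel_harmonics(col, sample_rate, band)
    n_per <- floor(h$f1_ref * length(col) / sample_rate)
    n_keep <- floor(n_per / h$f1_ref * sample_rate)
    col <- col[seq_len(n_keep)]
    h <- channel_harmonics(col, sample_rate, band)
    v <- mean((col - mean(col))^2)
    (h$a[1]^2 + h$a[2]^2) / 2 / v
  }, numeric(1))
  names(out) <- colnames(x)
  out
}

#' Build the six sinusoidal oscillator inputs for the network
#'
#' For each harmonic `i`, two anti-phase channels are produced:
#' `y_{fi,1}(t) = a_i sin(2 pi f_i t)` and `y_{fi,2}(t) = -y_{fi,1}(t)`.
#' Variants: `"SEA"` uses the extracted fundamental with unit amplitudes and
#' frequencies `(f1, 2 f1, 3 f1)`; `"SEB"`/`"SEC"` shift the fundamental by
#' +0.25 / -0.25 Hz before tripling (so `(f1 +/- 0.25, 2 f1 +/- 0.50,
#' 3 f1 +/- 0.75)` Hz); `"AM"` keeps the extracted frequencies and scales
#' each channel pair by its extracted amplitude `a_i` (times
#' `amplitude_scale`).
#'
#' @param spec a [harmonic_spec()] (or any list with `f1..f3`, `a1..a3`).
#' @param variant one of `"SEA"`, `"SEB"`, `"SEC"`, `"AM"`.
#' @param time numeric time grid in seconds (typically the target segment's).
#' @param amplitude_scale common multiplier applied to the `AM` amplitudes.
#' @return An object of class `sine_input_set`: list with `signals`
#'   (length(time) x 6 matrix, columns `y1_pos, y1_neg, ..., y3_neg`),
#'   `time`, `freqs`, `amps`, `variant`, `frequency_shift` (Hz on `f1`).
#' @export
build_sine_inputs <- function(spec, variant = c("SEA", "SEB", "SEC", "AM"),
                              time, amplitude_scale = 1) {
  variant <- match.arg(variant)
  shift <- switch(variant, SEA = 0, AM = 0, SEB = 0.25, SEC = -0.25)
  f1 <- spec$f1 + shift
  if (f1 <= 0)
    stop("invalid config: shifted fundamental f1 = ", f1, " Hz is not positive")
  if (variant == "AM") {
    freqs <- c(spec$f1, spec$f2, spec$f3)
    amps <- c(spec$a1, spec$a2, spec$a3) * amplitude_scale
  } else {
    freqs <- f1 * (1:3)
    amps <- c(1, 1, 1)
  }
  sig <- matrix(0, length(time), 6L)
  for (i in 1:3) {
    yi <- amps[i] * sin(2 * pi * freqs[i] * time)
    sig[, 2L * i - 1L] <- yi
    sig[, 2L * i] <- -yi                        # exact anti-symmetry
  }
  colnames(sig) <- c("y1_pos", "y1_neg", "y2_pos", "y2_neg", "y3_pos", "y3_neg")
  structure(
    list(signals = sig, time = time, freqs = freqs, amps = amps,
         variant = variant, frequency_shift = shift),
    class = "sine_input_set")
}

#' Normalize target waveforms to [-1, 1] per channel
#'
#' Each channel is mapped affinely so its minimum becomes -1 and its maximum
#' +1; the per-channel offset and scale are retained so predictions can be
#' mapped back to degrees with [denormalize_targets()].
#'
#' @param x a `cycle_segment`, [elevation_series()] or numeric matrix
#'   (samples x channels).
#' @return List of class `normalized_targets`: `signals` (matrix in
#'   `[-1, 1]`), `offset`, `scale` (per channel; `x = signals * scale +
#'   offset`), plus `time`/`Tc`/`sample_rate` when available.
#' @export
normalize_targets <- function(x) {
  extra <- list()
  if (inherits(x, c("cycle_segment", "elevation_series"))) {
    extra <- list(time = x$time, Tc = x$Tc, sample_rate = x$sample_rate)
    x <- x$angles
  }
  x <- as.matrix(x)
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  if (any(hi - lo < 1e-12))
    stop("degenerate normalization: constant channel cannot be scaled to [-1, 1]")
  scale <- (hi - lo) / 2
  offset <- (hi + lo) / 2
  signals <- sweep(sweep(x, 2, offset, "-"), 2, scale, "/")
  structure(c(list(signals = signals, offset = offset, scale = scale), extra),
            class = "normalized_targets")
}

#' @rdname normalize_targets
#' @param normalized matrix in normalized units (samples x channels).
#' @param record a `normalized_targets` object carrying `offset` and `scale`.
#' @export
denormalize_targets <- function(normalized, record) {
  sweep(sweep(as.matrix(normalized), 2, record$scale, "*"), 2,
        record$offset, "+")
}
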