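#' Similarity index between two periodic waveforms
#'
#' `SI = integral(p1 p2) / sqrt(integral(p1^2) integral(p2^2))` over exactly
#' one cycle period `Tc`, after synchronizing the two patterns on their
#' maxima: `p2` is circularly shifted (at sample resolution) so its maximum
#' coincides with `p1`'s; ties go to the earliest maximum. The period
#' analyzed is the last full cycle of the waveforms, where an integrated
#' trajectory has settled onto its limit cycle. `SI = 1` for identical (or
#' positively proportional) aligned patterns, and the normalized inner
#' product is bounded by `|SI| <= 1`.
#'
#' @param p1,p2 numeric waveforms on a common uniform grid covering at least
#'   one period.
#' @param Tc cycle period in seconds.
#' @param dt grid spacing in seconds.
#' @return Scalar SI in `[-1, 1]`, with attributes `shift` (samples applied
#'   to `p2`) and `n` (samples per period).
#' @export
similarity_index <- function(p1, p2, Tc, dt) {
  stopifnot(Tc > 0, dt > 0)
  n_per <- round(Tc / dt)
  if (n_per < 2)
    stop("period Tc must span at least two samples")
  if (length(p1) < n_per || length(p2) < n_per)
    stop("patterns must cover at least one period Tc")
  idx_last <- seq(length(p1) - n_per + 1L, length(p1))
  w1 <- p1[idx_last]
  w2 <- p2[idx_last]
  if (sum(w1^2) == 0 || sum(w2^2) == 0)
    stop("undefined SI: zero-energy pattern")
  # locate the synchronization maxima on quarter-period-smoothed copies so
  # that sample noise on a flat peak cannot slip the alignment; the inner
  # product itself uses the raw waveforms
  argmax_smooth <- function(w) {
    k <- max(1L, round(n_per / 4))
    if (k > 1L) {
      ws <- stats::filter(w, rep(1 / k, k), method = "convolution",
                          sides = 2, circular = TRUE)
      which.max(as.numeric(ws))
    } else which.max(w)
  }
  shift <- argmax_smooth(w1) - argmax_smooth(w2)  # earliest max on ties
  idx <- ((seq_len(n_per) - 1L - shift) %% n_per) + 1L
  w2 <- w2[idx]
  si <- sum(w1 * w2) / sqrt(sum(w1^2) * sum(w2^2))
  structure(si, shift = shift, n = n_per)
}

#' Per-channel similarity of a predicted trial against a reference
#'
#' Computes the similarity index channel by channel, with the cycle period
#' `Tc` taken from the reference pattern (detected cycle maxima when a full
#' series is given). The mean over the six channels is the headline score.
#'
#' @param predicted matrix (samples x 6) or [elevation_series()].
#' @param reference matrix of the same shape, [elevation_series()] or
#'   `cycle_segment`; defines `Tc`.
#' @param Tc cycle period override (s).
#' @param dt grid spacing (s); required for bare matrices.
#' @return Object of class `si_result`: `si` (named per-channel vector),
#'   `mean_si`, `Tc`, `shift` (per-channel alignment, samples).
#' @export
evaluate_fit <- function(predicted, reference, Tc = NULL, dt = NULL) {
  if (inherits(reference, "elevation_series")) {
    if (is.null(Tc)) {
      bounds <- detect_cycles(reference)
      Tc <- median(diff(bounds))
    }
    dt <- dt %||% (1 / reference$sample_rate)
    ref <- reference$angles
  } else if (inherits(reference, "cycle_segment")) {
    Tc <- Tc %||% reference$Tc
    dt <- dt %||% (1 / reference$sample_rate)
    ref <- reference$angles
  } else {
    ref <- as.matrix(reference)
  }
  if (inherits(predicted, "elevation_series")) {
    dt <- dt %||% (1 / predicted$sample_rate)
    predicted <- predicted$angles
  }
  predicted <- as.matrix(predicted)
  if (is.null(dt) || is.null(Tc))
    stop("dt and Tc are required when both arguments are bare matrices")
  if (!all(dim(predicted) == dim(ref)))
    stop("shape error: predicted and reference must match")
  si <- numeric(ncol(ref)); shift <- integer(ncol(ref))
  for (j in seq_len(ncol(ref))) {
    s <- similarity_index(ref[, j], predicted[, j], Tc, dt)
    si[j] <- as.numeric(s); shift[j] <- attr(s, "shift")
  }
  names(si) <- colnames(ref) %||% paste0("ch", seq_along(si))
  structure(list(si = si, mean_si = mean(si), Tc = Tc, shift = shift),
            class = "si_result")
}

#' @export
print.si_result <- function(x, ...) {
  cat(sprintf("<si_result> mean SI = %.4f (Tc = %.3f s)\n", x$mean_si, x$Tc))
  print(round(x$si, 4))
  invisible(x)
}

#' Planar covariation of thigh, shank and foot elevation angles
#'
#' Principal component analysis of the mean-centered three-angle trajectory.
#' The planarity index is the variance fraction captured by the first two
#' principal components; values near 1 mean the gait loop lies on a plane.
#'
#' @param thigh,shank,foot equal-length numeric waveforms (typically
#'   normalized elevation angles over >= one cycle); alternatively `thigh`
#'   may be a samples x 3 matrix.
#' @return Object of class `covariation_plane`: `axes` (3 orthonormal
#'   principal directions, columns), `var_fraction` (length 3, sums to 1),
#'   `planarity`, `loop` (scores for plotting).
#' @export
fit_covariation_plane <- function(thigh, shank = NULL, foot = NULL) {
  M <- if (is.null(shank)) as.matrix(thigh) else cbind(thigh, shank, foot)
  if (ncol(M) != 3L)
    stop("expected three angle waveforms")
  if (nrow(M) < 3L || all(apply(M, 2, sd) < 1e-12))
    stop("degenerate input: trajectory has no variance")
  pc <- prcomp(M, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  frac <- v / sum(v)
  structure(
    list(axes = pc$rotation, var_fraction = frac,
         planarity = frac[1] + frac[2], loop = pc$x),
    class = "covariation_plane")
}

#' @export
print.covariation_plane <- function(x, ...) {
  cat(sprintf("<covariation_plane> planarity = %.4f (PC variance fractions: %s)\n",
              x$planarity, paste(sprintf("%.3f", x$var_fraction), collapse = ", ")))
  invisible(x)
}

#' Sign distribution of the synaptic weights
#'
#' Counts positive and negative entries of the full weight matrix (all
#' directed connections among units, self-connections included). Exact
#' zeros are counted separately and excluded from the sign percentages
#' (they have measure zero after training).
#'
#' @param params a `drnn_params` or `drnn_model`.
#' @return Object of class `structure_summary` with `n_pos`, `n_neg`,
#'   `n_zero`, `frac_pos`, `frac_neg`, `pct_neg`, `n_hidden`.
#' @export
weight_sign_distribution <- function(params) {
  if (inherits(params, "drnn_model")) params <- params$params
  stopifnot(inherits(params, "drnn_params"))
  w <- params$W
  n_pos <- sum(w > 0); n_neg <- sum(w < 0); n_zero <- sum(w == 0)
  denom <- n_pos + n_neg
  structure(
    list(n_pos = n_pos, n_neg = n_neg, n_zero = n_zero,
         frac_pos = n_pos / denom, frac_neg = n_neg / denom,
         pct_neg = 100 * n_neg / denom,
         n_hidden = params$n_hidden),
    class = "structure_summary")
}

#' Time-constant distribution of a trained network
#'
#' @param params a `drnn_params` or `drnn_model`.
#' @return Object of class `structure_summary` with `median`, `quartiles`,
#'   `range`, the full vector `T` and `n_hidden`.
#' @export
time_constant_stats <- function(params) {
  if (inherits(params, "drnn_model")) params <- params$params
  stopifnot(inherits(params, "drnn_params"))
  Tc <- params$T
  structure(
    list(median = median(Tc),
         quartiles = quantile(Tc, c(0.25, 0.75), names = FALSE),
         range = range(Tc), T = Tc, n_hidden = params$n_hidden),
    class = "structure_summary")
}

#' @export
print.structure_summary <- function(x, ...) {
  if (!is.null(x$pct_neg)) {
    cat(sprintf("<structure_summary> %d+ / %d- / %d zero weights (%.1f%% negative)\n",
                x$n_pos, x$n_neg, x$n_zero, x$pct_neg))
  } else {
    cat(sprintf("<structure_summary> time constants: median %.3g s, IQR [%.3g, %.3g] s\n",
                x$median, x$quartiles[1], x$quartiles[2]))
  }
  invisible(x)
}
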