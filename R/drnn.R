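#' Initialize network parameters
#'
#' The network is fully connected: 6 input units (one per oscillator
#' channel), `n_hidden` hidden units and 6 output units (one per elevation
#' angle). Unit `i` obeys `T_i dy_i/dt = -y_i + F(x_i) + I_i` with
#' `F(a) = 1 / (1 + exp(-a))` and `x_i = sum_j w_ij y_j`. Weights are drawn
#' i.i.d. uniform on `[-weight_scale, weight_scale]`; time constants
#' log-uniform on `T_range` (seconds); biases start at zero. Input units
#' receive the oscillator signals through their external input `I_i(t)`.
#'
#' @param n_hidden number of hidden units.
#' @param seed integer seed for the random draw (`NULL`: use current RNG).
#' @param weight_scale half-width of the uniform weight initialization.
#' @param T_range range of initial time constants (s), sampled log-uniformly.
#' @param n_in,n_out input/output unit counts (6 each for gait work).
#' @return An object of class `drnn_params`: list with `W` (n x n), `T` (s),
#'   `I` (bias vector), `roles` (character), `n_in`, `n_hidden`, `n_out`.
#' @export
drnn_init <- function(n_hidden, seed = NULL, weight_scale = 0.5,
                      T_range = c(0.1, 1), n_in = 6L, n_out = 6L) {
  stopifnot(n_hidden >= 1, weight_scale > 0, all(T_range > 0))
  n <- n_in + n_hidden + n_out
  with_seed(seed, {
    W <- matrix(runif(n * n, -weight_scale, weight_scale), n, n)
    Tc <- exp(runif(n, log(T_range[1]), log(T_range[2])))
    structure(
      list(W = W, T = Tc, I = rep(0, n),
           roles = rep(c("input", "hidden", "output"),
                       c(n_in, n_hidden, n_out)),
           n_in = as.integer(n_in), n_hidden = as.integer(n_hidden),
           n_out = as.integer(n_out)),
      class = "drnn_params")
  })
}

#' @export
print.drnn_params <- function(x, ...) {
  cat(sprintf("<drnn_params> %d units (%d in / %d hidden / %d out), %d weights\n",
              length(x$T), x$n_in, x$n_hidden, x$n_out, length(x$W)))
  cat(sprintf("time constants: median %.3g s, range [%.3g, %.3g] s\n",
              median(x$T), min(x$T), max(x$T)))
  invisible(x)
}

output_units <- function(params) {
  which(params$roles == "output")
}

# Assemble the n x (K+1) external-input matrix: oscillator signals on the
# input units plus the constant bias vector.
build_iext <- function(params, inputs) {
  sig <- if (inherits(inputs, "sine_input_set")) inputs$signals else as.matrix(inputs)
  if (ncol(sig) != params$n_in)
    stop("inputs must have ", params$n_in, " channels")
  n <- length(params$T)
  Iext <- matrix(params$I, n, nrow(sig))
  Iext[seq_len(params$n_in), ] <- t(sig)
  Iext
}

input_dt <- function(inputs, dt) {
  if (!is.null(dt)) return(dt)
  if (inherits(inputs, "sine_input_set")) {
    d <- diff(inputs$time)
    return(mean(d))
  }
  stop("dt must be supplied when inputs carry no time grid")
}

#' Integrate the network forward
#'
#' Explicit-Euler integration of the unit dynamics over the input grid:
#' `y_i <- y_i + (dt / T_i) (-y_i + F(x_i) + I_i)`. All units start at the
#' sigmoid midpoint `y(0) = 0.5`. `dt` must be smaller than every time
#' constant for stability.
#'
#' @param params a [drnn_init()] parameter set.
#' @param inputs a [build_sine_inputs()] set, or a samples x `n_in` matrix.
#' @param dt integration step (s); defaults to the input grid spacing.
#' @param y0 initial activation (scalar or length-n vector).
#' @return List with `Y` (samples x units activation trajectories), `X`
#'   (effective inputs, one column fewer) and `dt`.
#' @export
drnn_forward <- function(params, inputs, dt = NULL, y0 = 0.5) {
  stopifnot(inherits(params, "drnn_params"))
  dt <- input_dt(inputs, dt)
  if (dt >= min(params$T))
    stop("stability error: dt = ", dt, " must be below the smallest time constant ",
         min(params$T))
  Iext <- build_iext(params, inputs)
  n <- length(params$T)
  y0 <- rep_len(y0, n)
  res <- cpg_forward_cpp(params$W, params$T, y0, Iext, dt)
  if (isTRUE(res$diverged))
    stop("divergence error: non-finite state at step ", res$step)
  list(Y = t(res$Y), X = t(res$X), dt = dt)
}

#' Tracking cost by direct summation
#'
#' `E = dt * sum_t sum_o 0.5 (y_o(t) - target_o(t))^2` over all grid points
#' after the initial condition, output units only. Plain R summation; the
#' training loop computes the same quantity internally in compiled code.
#'
#' @param outputs samples x `n_out` matrix of output-unit trajectories.
#' @param targets matrix of the same shape.
#' @param dt grid spacing (s).
#' @param settle_s cost onset `t0` in seconds.
#' @return Scalar cost `E >= 0`.
#' @export
drnn_cost <- function(outputs, targets, dt, settle_s = 0) {
  outputs <- as.matrix(outputs); targets <- as.matrix(targets)
  if (!all(dim(outputs) == dim(targets)))
    stop("shape error: outputs and targets must be on the same grid")
  idx <- seq(2L + round(settle_s / dt), nrow(outputs))
  sum(0.5 * (outputs[idx, , drop = FALSE] - targets[idx, , drop = FALSE])^2) * dt
}

#' Adjoint backward pass: cost and exact gradients
#'
#' Integrates the adjoint variables `p_i` backward from the terminal
#' condition `p_i(t1) = 0` and accumulates the gradients of the integrated
#' cost with respect to every weight `w_ij` and time constant `T_i`. The
#' discrete form is the exact adjoint of the Euler update, so gradients
#' match finite differences of [drnn_cost()] to machine precision.
#'
#' @param params a [drnn_init()] parameter set.
#' @param fwd result of [drnn_forward()] for the same inputs.
#' @param inputs the inputs used in the forward pass.
#' @param targets samples x `n_out` matrix of desired output activations
#'   (same grid and activation units as `fwd$Y`).
#' @param dt integration step; defaults to `fwd$dt`.
#' @param settle_s cost onset `t0` in seconds (0: cost from the first step).
#' @return List with `E` (cost), `gW` (dE/dw, n x n), `gT` (dE/dT, length n)
#'   and `P` (adjoint trajectories, samples x units; last row exactly zero).
#' @export
drnn_backward <- function(params, fwd, inputs, targets, dt = NULL,
                          settle_s = 0) {
  stopifnot(inherits(params, "drnn_params"))
  dt <- dt %||% fwd$dt
  targets <- as.matrix(targets)
  if (nrow(targets) != nrow(fwd$Y) || ncol(targets) != params$n_out)
    stop("shape error: targets must be samples x n_out on the forward grid")
  Iext <- build_iext(params, inputs)
  res <- cpg_backward_cpp(params$W, params$T, t(fwd$Y), t(fwd$X), Iext,
                          t(targets), output_units(params) - 1L, dt,
                          keep_adjoint = TRUE,
                          skip = as.integer(round(settle_s / dt)))
  list(E = res$E, gW = res$gW, gT = as.numeric(res$gT), P = t(res$P))
}

#' Training configuration
#'
#' Defaults are desk-scale: the full-size protocol (100 restarts,
#' 50,000 iterations) is exposed through the same knobs but is not the
#' default. Rates adapt per parameter (Almeida scheme): multiplied by `up`
#' while successive gradient signs agree, by `down` on reversal, clamped to
#' `rate_clamp`. Time constants are optimized as `log T` (positivity by
#' construction) with a floor at the integration step.
#'
#' @param n_iterations gradient iterations per restart.
#' @param n_restarts independent random initializations.
#' @param dt integration step (s); `NULL` to use each pattern's grid spacing.
#' @param rate_w,rate_t initial learning rates for weights and log-T.
#' @param up,down Almeida rate factors (`up > 1 > down > 0`).
#' @param rate_clamp allowed per-parameter rate range.
#' @param weight_scale,T_range initialization spread, see [drnn_init()].
#' @param target_range activation interval the `[-1, 1]` targets are mapped
#'   into during optimization (the sigmoid confines activations near (0,1)).
#' @param settle_s cost onset `t0` (s): the tracking cost starts this long
#'   after pattern onset, so the startup transient (all units begin at the
#'   sigmoid midpoint, off the gait orbit) is not penalized.
#' @param seed master seed for initialization draws.
#' @return List of class `training_config`.
#' @export
training_config <- function(n_iterations = 5000, n_restarts = 10, dt = NULL,
                            rate_w = 0.01, rate_t = 0.0025,
                            up = 1.1, down = 0.5,
                            rate_clamp = c(1e-7, 1),
                            weight_scale = 0.5, T_range = c(0.1, 1),
                            target_range = c(0.1, 0.9), settle_s = 0.5,
                            seed = NULL) {
  stopifnot(n_iterations >= 1, n_restarts >= 1, up > 1, down > 0, down < 1,
            rate_clamp[1] > 0, rate_clamp[2] > rate_clamp[1],
            target_range[1] < target_range[2], settle_s >= 0)
  structure(
    list(n_iterations = as.integer(n_iterations),
         n_restarts = as.integer(n_restarts), dt = dt,
         rate_w = rate_w, rate_t = rate_t, up = up, down = down,
         rate_clamp = rate_clamp, weight_scale = weight_scale,
         T_range = T_range, target_range = target_range,
         settle_s = settle_s, seed = seed),
    class = "training_config")
}

# Map [-1, 1] target waveforms into the activation interval and back.
targets_to_activation <- function(targets, target_range) {
  mid <- mean(target_range); half <- diff(target_range) / 2
  mid + half * as.matrix(targets)
}

activation_to_targets <- function(act, target_range) {
  mid <- mean(target_range); half <- diff(target_range) / 2
  (as.matrix(act) - mid) / half
}

# Normalize a patterns argument into a list of lists with elements
# inputs (sine_input_set or matrix), targets (samples x 6, in [-1, 1]),
# and optional Tc (s) used for similarity scoring.
check_patterns <- function(patterns, n_in = 6L, n_out = 6L) {
  if (!is.list(patterns) || length(patterns) == 0)
    stop("at least one (inputs, targets) pattern is required")
  if (!is.null(patterns$inputs)) patterns <- list(patterns)
  for (p in patterns) {
    if (is.null(p$inputs) || is.null(p$targets))
      stop("each pattern needs elements `inputs` and `targets`")
    sig <- if (inherits(p$inputs, "sine_input_set")) p$inputs$signals else p$inputs
    if (nrow(sig) != nrow(as.matrix(p$targets)))
      stop("shape error: inputs and targets must share the time grid")
  }
  patterns
}

#' Train the network on one or more input-output patterns
#'
#' One gradient step per iteration: adjoint gradients are summed over all
#' patterns, then every weight and (log) time constant moves against its
#' gradient by its own adaptive rate. Targets supplied in `[-1, 1]` are
#' mapped to `target_range` for optimization; [drnn_predict()] maps network
#' output back. If the cost turns non-finite, the previous parameters are
#' restored with all rates shrunk; training fails after 20 such recoveries.
#'
#' @param patterns one pattern or a list of patterns; each pattern is a list
#'   with `inputs` (a [build_sine_inputs()] set or matrix), `targets`
#'   (samples x 6 matrix in `[-1, 1]`) and optionally `Tc` (cycle period, s).
#' @param n_hidden hidden-unit count.
#' @param config a [training_config()].
#' @param init optional [drnn_init()] parameter set overriding the draw.
#' @return An object of class `drnn_model`: `params` (trained
#'   [drnn_init()]-shaped set at the best recorded loss), `loss` (per
#'   iteration), `E_best`, `recoveries`, `config`, `n_hidden`.
#' @export
drnn_train <- function(patterns, n_hidden, config = training_config(),
                       init = NULL) {
  patterns <- check_patterns(patterns)
  params <- init %||% drnn_init(n_hidden, seed = config$seed,
                                weight_scale = config$weight_scale,
                                T_range = config$T_range)
  inputs <- lapply(patterns, function(p) build_iext(params, p$inputs))
  dts <- vapply(patterns, function(p) input_dt(p$inputs, config$dt), numeric(1))
  if (any(dts >= min(params$T)))
    stop("stability error: dt must be below the smallest initial time constant")
  tgts <- lapply(patterns, function(p)
    t(targets_to_activation(p$targets, config$target_range)))
  n <- length(params$T)
  skip <- as.integer(round((config$settle_s %||% 0) / max(dts)))
  res <- cpg_train_cpp(params$W, params$T, rep(0.5, n), inputs, tgts,
                       output_units(params) - 1L, dts,
                       config$n_iterations, config$rate_w, config$rate_t,
                       config$up, config$down,
                       config$rate_clamp[1], config$rate_clamp[2],
                       max_recoveries = 20L, skip = skip)
  if (isTRUE(res$failed))
    stop("divergence error: training failed after repeated rate reductions")
  params$W <- res$W
  params$T <- as.numeric(res$T)
  structure(
    list(params = params, loss = as.numeric(res$loss), E_best = res$E_best,
         recoveries = res$recoveries, config = config,
         n_hidden = as.integer(n_hidden)),
    class = "drnn_model")
}

#' @export
print.drnn_model <- function(x, ...) {
  cat(sprintf("<drnn_model> %d hidden units, best cost %.4g after %d iterations\n",
              x$n_hidden, x$E_best, length(x$loss)))
  invisible(x)
}

#' Run a trained network on (possibly unlearned) oscillator inputs
#'
#' Pure forward pass; parameters are not modified. Output-unit activations
#' are mapped back from the training activation interval to the `[-1, 1]`
#' normalized-angle space.
#'
#' @param model a [drnn_train()] result (or a `drnn_params` set, in which
#'   case `target_range` defaults to `c(0.1, 0.9)`).
#' @param inputs a [build_sine_inputs()] set or samples x 6 matrix.
#' @param dt integration step; defaults to the input grid spacing.
#' @return samples x 6 matrix of predicted normalized elevation angles.
#' @export
drnn_predict <- function(model, inputs, dt = NULL) {
  if (inherits(model, "drnn_model")) {
    params <- model$params
    target_range <- model$config$target_range
  } else {
    params <- model
    target_range <- c(0.1, 0.9)
  }
  fwd <- drnn_forward(params, inputs, dt = dt)
  out <- fwd$Y[, output_units(params), drop = FALSE]
  colnames(out) <- elevation_channels()
  activation_to_targets(out, target_range)
}

# Mean similarity index of a model's predictions over a pattern list.
mean_pattern_si <- function(model, patterns, dt = NULL) {
  sis <- vapply(patterns, function(p) {
    pred <- drnn_predict(model, p$inputs, dt = dt)
    dtp <- input_dt(p$inputs, dt %||% model$config$dt)
    Tc <- p$Tc %||% ((nrow(pred) - 1) * dtp / 2)
    mean(vapply(seq_len(ncol(pred)), function(j)
      similarity_index(p$targets[, j], pred[, j], Tc, dtp), numeric(1)))
  }, numeric(1))
  mean(sis)
}

#' Train with independent restarts, keeping the most similar network
#'
#' Repeats [drnn_train()] from `n_restarts` independent random
#' initializations (seeds derived from `config$seed`) and selects the
#' network with the highest mean similarity index over all patterns and
#' output channels; ties break toward lower cost.
#'
#' @inheritParams drnn_train
#' @param n_restarts number of restarts (defaults to `config$n_restarts`).
#' @return The best `drnn_model`, with an extra element `restarts`: a
#'   data.frame logging seed, final cost, mean SI and divergence recoveries
#'   for every restart.
#' @export
drnn_train_restarts <- function(patterns, n_hidden,
                                config = training_config(),
                                n_restarts = NULL) {
  patterns <- check_patterns(patterns)
  n_restarts <- n_restarts %||% config$n_restarts
  stopifnot(n_restarts >= 1)
  seeds <- derive_seeds(config$seed %||% 1L, n_restarts)
  log_df <- data.frame(restart = seq_len(n_restarts),
                       seed = vapply(seeds, as.numeric, numeric(1)),
                       E = NA_real_, mean_si = NA_real_, recoveries = NA_integer_)
  best <- NULL; best_si <- -Inf; best_E <- Inf
  for (r in seq_len(n_restarts)) {
    cfg <- config; cfg$seed <- seeds[[r]]
    model <- tryCatch(drnn_train(patterns, n_hidden, cfg),
                      error = function(e) e)
    if (inherits(model, "error")) next
    si <- mean_pattern_si(model, patterns, dt = config$dt)
    log_df$E[r] <- model$E_best
    log_df$mean_si[r] <- si
    log_df$recoveries[r] <- model$recoveries
    if (si > best_si || (si == best_si && model$E_best < best_E)) {
      best <- model; best_si <- si; best_E <- model$E_best
    }
  }
  if (is.null(best))
    stop("all restarts diverged; see the per-restart log for diagnostics")
  best$restarts <- log_df
  best$mean_si <- best_si
  best
}

#' Save / load trained parameters
#'
#' Single-file JSON checkpoint holding the weight matrix, time constants,
#' biases, unit roles and a config echo, with a format-version stamp.
#' Numbers are written at full precision so a load-save cycle is
#' byte-identical and forward trajectories are unchanged.
#'
#' @param model a `drnn_model` or `drnn_params` object.
#' @param path file path.
#' @return `save_drnn` returns `path` invisibly; `load_drnn` returns a
#'   `drnn_model` (with `params`, and `config` when present in the file).
#' @export
save_drnn <- function(model, path) {
  params <- if (inherits(model, "drnn_model")) model$params else model
  stopifnot(inherits(params, "drnn_params"))
  payload <- list(
    format = "cpgdrnn-params", version = 1L,
    n_in = params$n_in, n_hidden = params$n_hidden, n_out = params$n_out,
    W = as.numeric(params$W), T = as.numeric(params$T),
    I = as.numeric(params$I), roles = params$roles)
  if (inherits(model, "drnn_model")) {
    cfg <- model$config
    cfg$dt <- cfg$dt %||% NA_real_
    payload$config <- cfg[!vapply(cfg, is.function, logical(1))]
    payload$E_best <- model$E_best
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_drnn
#' @export
load_drnn <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e)
                        stop("format error: cannot parse checkpoint: ",
                             conditionMessage(e)))
  if (!identical(payload$format, "cpgdrnn-params"))
    stop("format error: not a cpgdrnn parameter checkpoint")
  n <- payload$n_in + payload$n_hidden + payload$n_out
  if (length(payload$W) != n * n || length(payload$T) != n)
    stop("format error: parameter array lengths are inconsistent")
  params <- structure(
    list(W = matrix(payload$W, n, n), T = payload$T, I = payload$I,
         roles = payload$roles,
         n_in = as.integer(payload$n_in),
         n_hidden = as.integer(payload$n_hidden),
         n_out = as.integer(payload$n_out)),
    class = "drnn_params")
  out <- list(params = params, n_hidden = params$n_hidden)
  if (!is.null(payload$config)) {
    cfg <- payload$config
    if (!is.null(cfg$dt) && is.na(cfg$dt)) cfg$dt <- NULL
    out$config <- cfg
    out$E_best <- payload$E_best
  } else {
    out$config <- list(target_range = c(0.1, 0.9))
  }
  structure(out, class = "drnn_model")
}
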