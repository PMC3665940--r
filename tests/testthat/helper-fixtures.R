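# Noiseless, jitter-free trial: deterministic three-harmonic waveforms.
clean_trial <- function(velocity_kmh = 3, duration_s = 10, seed = 1,
                        sample_rate_hz = 100) {
  generate_trial(gait_config(velocity_kmh = velocity_kmh,
                             duration_s = duration_s,
                             sample_rate_hz = sample_rate_hz,
                             noise_sd = 0, cycle_jitter = 0, seed = seed))
}

# Tiny network + pattern for fast training tests: learn to reproduce the
# fundamental oscillation on all six outputs.
tiny_pattern <- function(f1 = 0.8, duration = 2.5, dt = 0.01) {
  tt <- seq(0, duration, by = dt)
  spec <- list(f1 = f1, f2 = 2 * f1, f3 = 3 * f1, a1 = 1, a2 = 0.4, a3 = 0.1)
  inputs <- build_sine_inputs(spec, "SEA", tt)
  targets <- matrix(rep(sin(2 * pi * f1 * tt), 6), ncol = 6)
  list(inputs = inputs, targets = targets, Tc = 1 / f1)
}

# Small unlabelled network for gradient tests.
tiny_net <- function(n_hidden, seed, n_in = 2, n_out = 2) {
  drnn_init(n_hidden, seed = seed, n_in = n_in, n_out = n_out)
}

# Central finite-difference gradients of the tracking cost, the independent
# oracle against the adjoint pass.
fd_gradients <- function(params, inputs, targets, dt, eps = 1e-5,
                         w_idx, t_idx) {
  cost_of <- function(p) {
    fwd <- drnn_forward(p, inputs, dt = dt)
    drnn_cost(fwd$Y[, which(p$roles == "output"), drop = FALSE], targets, dt)
  }
  gW <- vapply(w_idx, function(k) {
    p <- params
    p$W[k] <- p$W[k] + eps; Ep <- cost_of(p)
    p$W[k] <- p$W[k] - 2 * eps; Em <- cost_of(p)
    (Ep - Em) / (2 * eps)
  }, numeric(1))
  gT <- vapply(t_idx, function(i) {
    p <- params
    p$T[i] <- p$T[i] + eps; Ep <- cost_of(p)
    p$T[i] <- p$T[i] - 2 * eps; Em <- cost_of(p)
    (Ep - Em) / (2 * eps)
  }, numeric(1))
  list(gW = gW, gT = gT)
}
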