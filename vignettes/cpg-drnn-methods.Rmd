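---
title: "Modelling a locomotor central pattern generator with a dynamic recurrent network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a locomotor central pattern generator with a dynamic recurrent network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpgdrnn)
```

## The scientific problem

During human walking the sagittal elevation angles of the thigh, shank and
foot are dominated by the first harmonics of the stride frequency, and when
the three angles of one leg are plotted against each other they trace an
elliptic loop that lies almost exactly on a plane (the planar covariation
rule). Both observations suggest that the spinal central pattern generator
(CPG) could be driven by a small set of oscillatory inputs. `cpgdrnn`
models this hypothesis computationally: a fully connected continuous-time
recurrent neural network with trainable per-unit time constants (a DRNN) is
taught to transform six sinusoidal oscillators — built from the first three
harmonics of the gait spectrum — into the six elevation-angle trajectories
of both legs, across walking speeds. After training, the network is probed
like a physiological preparation: how faithfully it reproduces kinematics
(similarity index), whether its outputs respect planar covariation, and
what connectivity emerges (excitatory/inhibitory balance, time-constant
distributions).

## Network model

Each of the $n$ units obeys

$$T_i \frac{dy_i}{dt} = -y_i + F(x_i) + I_i, \qquad
  x_i = \sum_j w_{ij} y_j, \qquad F(a) = \frac{1}{1+e^{-a}},$$

with trainable weights $w_{ij}$ (fully connected, self-connections
included) and time constants $T_i$. Six input units carry the oscillator
signals through their external input $I_i(t)$; six output units are read
out; the hidden layer size is a parameter (1–80 in the experiments). The
propagation sum runs over the presynaptic index, $x_i = \sum_j w_{ij}
y_j$, the standard form for this network class.

Training minimizes the integrated quadratic tracking error
$E = \int_{t_0}^{t_1} \tfrac12 \sum_{o} (y_o(t) - d_o(t))^2\,dt$ on the
output units. The lower limit $t_0$ is a tunable *settle window*
(`settle_s`, default 0.5 s): all units start at the sigmoid midpoint
$y(0)=0.5$, a state off the gait orbit, and the first half second of
transient is excluded from the cost so the optimizer shapes the limit
cycle rather than the unfittable initial jump.

### Integration and gradients

The dynamics are integrated by explicit Euler with the kinematic sample
interval ($dt = 0.01$ s); the scheme is first-order convergent (verified by
grid refinement in the tests) and stable provided $dt < \min_i T_i$, which
is enforced. Gradients come from adjoint variables $p_i(t)$ integrated
backward from $p_i(t_1) = 0$. Rather than discretizing the continuous
adjoint ODE, the package computes the *exact discrete adjoint* of the Euler
update (backpropagation through the recursion). In the continuous limit
this coincides with the standard adjoint system for these dynamics: the
coupling sum carries $1/T_j$ with the transposed weight, $\sum_j (1/T_j)
w_{ji} F'(x_j) p_j$ (printed variants of this equation sometimes carry the
receiving unit's $1/T_i$ instead; the implemented form is the one that
passes a central finite-difference check to relative error below
$10^{-6}$ on small networks, an acceptance property of the package). The
error signal $e_i$ is $\partial q/\partial y_i$ of the pointwise squared
error.

### Optimization

Updates are sign-based with per-parameter adaptive rates (the Almeida
family): each weight moves by $-\eta_{ij}\,\mathrm{sign}(\partial E/\partial
w_{ij})$, and $\eta_{ij}$ is multiplied by 1.1 while successive gradient
signs agree and by 0.5 on reversal, clamped to $[10^{-7}, 1]$. Initial
rates are 0.01 for weights and 0.0025 for time constants — chosen once by a
pilot grid on the multi-velocity task and frozen. Time constants are
optimized as $\log T_i$ (chain rule applied to the time-constant gradient),
which keeps $T_i > 0$ by construction; a floor at $dt$ preserves Euler
stability. Weights start i.i.d. uniform on $[-0.5, 0.5]$, time constants
log-uniform on $[0.1, 1]$ s, biases of non-input units at zero and
untrained (a package choice; bias training is exposed nowhere because the
oscillator inputs already supply the only external drive). If the cost
ever turns non-finite the previous parameters are restored with all rates
shrunk tenfold; training aborts cleanly after 20 such recoveries. The
returned network is the one at the best recorded loss.

Because the sigmoid confines activations near $(0,1)$ while the normalized
targets live in $[-1,1]$, targets are mapped affinely to $[0.1, 0.9]$ for
optimization and predictions are mapped back before any similarity or
covariation analysis, which always happens in the original normalized
space.

### Restarts

Training is non-convex, so each experiment repeats training from
`n_restarts` independent initializations (seeds derived reproducibly from
the configuration seed) and keeps the network with the highest mean
similarity index over all patterns and output channels, ties broken by
lower cost. Desk-scale defaults are 10 restarts for the single-pattern
experiment and 5 for the multi-velocity sweep, versus 100 in the
full-size protocol; the full budget remains available through the
configuration.

## Synthetic gait generator

No recordings are distributed, so the package generates elevation-angle
trials with the structure the analysis assumes. Each channel is

$$\theta(t) = \sum_{k=1}^{3} A_k \sin\!\big(k\,\phi(t) + \varphi_k\big)
  + \varepsilon(t),$$

where $\phi(t)$ is the gait phase at fundamental $f_1$, right-side channels
are delayed by half a cycle, $\varepsilon$ is i.i.d. Gaussian noise
(default 0.3°), and an optional per-cycle period jitter (default 2%)
emulates stride-to-stride variability. Defaults, frozen once:

* fundamental $f_1(v) = 0.52 + 0.08\,v$ Hz — 0.6 Hz at 1 km/h to 1.0 Hz at
  6 km/h, plausible stride rates with the printed increasing trend;
* first-harmonic amplitudes 20°, 35°, 45° (thigh, shank, foot) at 3 km/h,
  scaled by $1 + 0.06\,(v-3)$ so amplitudes grow with speed;
* harmonic ratios $(1, 0.15, 0.05)$, $(1, 0.22, 0.08)$, $(1, 0.28, 0.10)$
  per segment, so the first two harmonics carry ≥ 98% of each channel's
  variance (the third stays a small shape correction, as in adult gait);
* segment phase offsets (thigh 0, shank −1.1, foot −1.45 rad on the
  fundamental; shared phases on harmonics 2–3) — tuned once against the
  planarity target (≥ 98% of variance in the first two principal
  components) and frozen. Sharing the higher-harmonic phases across
  segments is what keeps the loop planar: the fundamental components of
  three phase-shifted sinusoids always span a plane, and aligned
  higher-harmonic components mostly stay inside it.

The generator enforces $f_2 = 2 f_1$ and $f_3 = 3 f_1$, the harmonic lock
observed in gait elevation-angle spectra. (Gait studies also describe an
$f_3$ *decreasing* with speed, which cannot hold simultaneously with an
increasing $f_1$; the generator follows the harmonic lock and leaves the
discrepancy documented here.)

What the generator does **not** emulate: stance/swing asymmetries beyond
three harmonics, inter-subject morphology, soft-tissue and marker noise
structure, treadmill drift, or fatigue. Tests passing on these synthetic
trials therefore validate the pipeline's mechanics and the model's
capacity on idealized gait spectra — not clinical-grade fidelity on real
recordings.

## Feature extraction

Cycle boundaries are successive maxima of the lightly smoothed right-thigh
angle (the most sinusoidal channel; the cycle convention is a package
choice). The representative two-cycle segment is the consecutive pair whose
FFT peak triplets (frequencies and amplitudes) are closest to those of the
full recording — summed relative errors, equal weights, earliest pair on
ties (with a $10^{-9}$ tolerance so floating noise cannot break exact
symmetry).

Harmonic read-out uses a rectangular window with fourfold zero-padding for
peak localization. Long records are first truncated to an integer number of
fundamental periods — the fundamental refined to sub-bin accuracy by
maximizing the variance explained by a quadrature sin/cos pair, which is
unbiased by the negative-frequency mirror — making the rectangular window
leakage-free. Harmonic amplitudes are read at pre-padding bins only
(between-bin samples of a padded spectrum carry kernel skirts, not
harmonic energy) within ±2 bins of $k f_1$, capped so a window can never
reach a neighbouring harmonic. Per-channel results are aggregated as the
median of frequencies and mean of amplitudes across the six channels, for
robustness to one noisy channel. Amplitudes are linear magnitudes (a pure
$A \sin$ tone reads back as $A$); the alternative power-amplitude reading
is not used, and the choice is recorded here.

Oscillator inputs come in four variants: `SEA` uses $(f_1, 2f_1, 3f_1)$
with unit amplitudes; `SEB`/`SEC` shift the fundamental by ±0.25 Hz before
tripling; `AM` keeps extracted frequencies and scales each channel pair by
its extracted amplitude. Each harmonic contributes an exact anti-phase pair
($y_{i,2} = -y_{i,1}$). For multi-velocity training the amplitudes (in
degrees) are rescaled by one common factor chosen so the mean first-harmonic
amplitude over the learned velocities is 1 — the velocity modulation of the
inputs is preserved while the oscillators stay in the sigmoid's useful
range.

## Evaluation

The similarity index of two waveforms is their normalized inner product
over exactly one cycle period after synchronizing their maxima, computed
over the **last** full period of the comparison window (an integrated
trajectory has settled onto its limit cycle there; the time origin of the
integration limits is a free convention, fixed here once). Alignment maxima are
located on quarter-period moving-average copies so that sample noise on a
flat peak cannot slip the synchronization, while the inner product itself
uses the raw waveforms; the shift is circular at sample resolution, with no
sub-sample interpolation (error $O(dt)$, deterministic). The cycle period
comes from the reference pattern. Identical patterns score exactly 1;
waveforms at different harmonics of the period score 0.

Planar covariation is assessed by covariance PCA of the mean-centered
(thigh, shank, foot) trajectory; the planarity index is the variance
fraction of the first two components. Structure summaries count positive
and negative entries of the full weight matrix (self-connections included;
exact zeros — measure zero after training — are excluded from the sign
percentages) and report median and quartiles of the time constants.

## Experiments

`run_experiment1()` is the proof of concept: one velocity (3 km/h),
30 hidden units, 10,000 iterations per restart, and the three input
variants; synthetic generator seeds play the role of individual subjects.
Matched-frequency inputs (`SEA`) are expected to outperform the shifted
variants. `run_experiment2()` trains one network per hidden-unit count on
five velocities simultaneously (1.5–5.5 km/h) and predicts the four
intermediate unlearned velocities, whose inputs are built from harmonics
extracted from trials at those velocities — not by interpolating the
learned parameters. Per-cell failures are logged as `NA` without aborting
the sweep, and every result table is reproducible bit for bit under a fixed
seed (restart and generator seeds are derived deterministically from the
configuration).

Desk-scale problem sizes used throughout the shipped tests and the
acceptance script: 20 s trials at 100 Hz, two-cycle patterns (~250 samples),
5,000–10,000 iterations, 5–10 restarts, and 1–5 generator seeds. These are
the package's default operating conditions; the full-size protocol (40 s
trials, 100 restarts, 50,000 iterations, 17-point hidden sweep) is
reachable through the same configuration objects.

## Known limitations

* **Inhibitory dominance is not reproduced at desk scale on this synthetic
  task.** Studies of this network class trained on multi-subject treadmill
  recordings report predominantly inhibitory connectivity after learning
  (about 70% negative weights at 80 hidden units). In this package's
  scaled-down synthetic replication the best 80-unit
  networks hover near an even split (the acceptance script reports the
  measured percentage). This is not an artifact of weights staying at
  their symmetric initialization — trained weight magnitudes grow roughly
  tenfold — but a property of the solutions the smooth three-harmonic
  synthetic task admits: idealized targets are markedly easier than
  multi-subject recordings, so a balanced excitatory/inhibitory solution
  suffices. The strong inhibitory dominance appears to require real data
  or additional unstated conditions, and is reported as measured, not
  asserted.
* No sensory feedback or closed-loop testing: the network is a pure
  feedforward-in-time transformer of oscillator inputs.
* The Euler scheme and sample-resolution circular shifts bound accuracy at
  $O(dt)$; all headline quantities are insensitive to halving $dt$.
* Maximum-based synchronization is ill-conditioned for waveforms with
  nearly flat extrema; the quarter-period smoothing mitigates but does not
  eliminate this.

## A worked example

```{r example, eval = FALSE}
trial <- generate_trial(gait_config(velocity_kmh = 3, seed = 7))
segment <- select_representative_cycles(trial)
spec <- extract_harmonics(segment)
targets <- normalize_targets(segment)
inputs <- build_sine_inputs(spec, "SEA", segment$time)

model <- drnn_train_restarts(
  list(list(inputs = inputs, targets = targets$signals, Tc = segment$Tc)),
  n_hidden = 30,
  training_config(n_iterations = 10000, n_restarts = 10, seed = 1))

pred <- drnn_predict(model, inputs)
evaluate_fit(pred, targets$signals, Tc = segment$Tc, dt = 0.01)
fit_covariation_plane(pred[, c("left_thigh", "left_shank", "left_foot")])
```
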