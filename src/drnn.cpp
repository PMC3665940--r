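// Core numerics for the continuous-time recurrent network:
// forward Euler integration of T_i dy_i/dt = -y_i + F(x_i) + I_i,
// exact discrete adjoint (backprop through the Euler update), and the
// Almeida-style per-parameter adaptive-rate training loop.
//
// The discrete adjoint is used instead of discretizing the continuous
// adjoint ODE so that gradients match finite differences of the discrete
// cost to machine precision; in the continuous limit it coincides with
// the standard adjoint system for these dynamics.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::vec sigmoid(const arma::vec& a) {
  return 1.0 / (1.0 + arma::exp(-a));
}

// Integrate the network over the grid implied by Iext (n x (K+1) columns,
// column t is the external input used on the step t -> t+1; column K unused).
// Returns activations Y (n x (K+1)) and effective inputs X (n x K).
// [[Rcpp::export]]
List cpg_forward_cpp(const arma::mat& W, const arma::vec& Tc,
                     const arma::vec& y0, const arma::mat& Iext,
                     double dt) {
  const arma::uword n = W.n_rows;
  const arma::uword K = Iext.n_cols - 1;
  arma::vec a = dt / Tc;

  arma::mat Y(n, K + 1), X(n, K);
  Y.col(0) = y0;
  for (arma::uword t = 0; t < K; ++t) {
    arma::vec x = W * Y.col(t);
    X.col(t) = x;
    Y.col(t + 1) = (1.0 - a) % Y.col(t) + a % (sigmoid(x) + Iext.col(t));
    if (!Y.col(t + 1).is_finite()) {
      return List::create(_["Y"] = Y, _["X"] = X, _["diverged"] = true,
                          _["step"] = (int)(t + 1));
    }
  }
  return List::create(_["Y"] = Y, _["X"] = X, _["diverged"] = false,
                      _["step"] = (int)K);
}

// Quadratic tracking cost over grid points 1..K on the output units:
//   E = dt * sum_t sum_o 0.5 * (y_o(t) - target_o(t))^2
static double cost_from_Y(const arma::mat& Y, const arma::mat& targets,
                          const arma::uvec& out_idx, double dt,
                          arma::uword skip = 0) {
  const arma::uword K = Y.n_cols - 1;
  double E = 0.0;
  for (arma::uword t = skip + 1; t <= K; ++t) {
    arma::vec d = Y.submat(out_idx, arma::uvec{t}) - targets.col(t);
    E += 0.5 * arma::dot(d, d);
  }
  return E * dt;
}

// Backward sweep. targets is n_out x (K+1) (column 0 ignored), out_idx are
// 0-based indices of the output units. Returns E, dE/dW, dE/dT and the
// adjoint trajectory P (n x (K+1)) with terminal column exactly zero.
// [[Rcpp::export]]
List cpg_backward_cpp(const arma::mat& W, const arma::vec& Tc,
                      const arma::mat& Y, const arma::mat& X,
                      const arma::mat& Iext, const arma::mat& targets,
                      const arma::uvec& out_idx, double dt,
                      bool keep_adjoint = true, int skip = 0) {
  const arma::uword n = W.n_rows;
  const arma::uword K = X.n_cols;
  arma::vec a = dt / Tc;

  arma::mat P;
  if (keep_adjoint) P.zeros(n, K + 1);

  arma::vec p(n, arma::fill::zeros);      // dE_{>t}/dy(t), p(K) = 0
  arma::vec gT(n, arma::fill::zeros);
  arma::mat M(n, K);                      // columns a * F'(x_t) * lambda(t+1)
  const arma::uword uskip = (arma::uword)std::max(skip, 0);
  double E = cost_from_Y(Y, targets, out_idx, dt, uskip);

  for (arma::uword s = K; s >= 1; --s) {
    const arma::uword t = s - 1;          // step t -> t+1
    arma::vec lam = p;                    // lambda(t+1) = p(t+1) + dt*e(t+1)
    if (s > uskip) {
      arma::vec d = Y.submat(out_idx, arma::uvec{s}) - targets.col(s);
      lam(out_idx) += dt * d;
    }

    arma::vec Fx = sigmoid(X.col(t));
    arma::vec Fp = Fx % (1.0 - Fx);
    arma::vec m = a % Fp % lam;
    M.col(t) = m;

    // dy_i(t+1)/dT_i = (-dt/T_i^2) * (-y_i(t) + F(x_i(t)) + I_i(t))
    gT += lam % (-dt / arma::square(Tc)) %
          (-Y.col(t) + Fx + Iext.col(t));

    p = (1.0 - a) % lam + W.t() * m;
    if (keep_adjoint) P.col(t) = p;
  }

  arma::mat gW = M * Y.cols(0, K - 1).t();

  List out = List::create(_["E"] = E, _["gW"] = gW, _["gT"] = gT);
  if (keep_adjoint) out["P"] = P;
  return out;
}

// Accumulate cost and gradients for one pattern into gW/gT (in log-T space
// conversion happens in the caller). Returns the pattern cost, or NaN on
// divergence.
static double pattern_grad(const arma::mat& W, const arma::vec& Tc,
                           const arma::vec& y0, const arma::mat& Iext,
                           const arma::mat& targets, const arma::uvec& out_idx,
                           double dt, arma::uword skip,
                           arma::mat& gW, arma::vec& gT) {
  const arma::uword n = W.n_rows;
  const arma::uword K = Iext.n_cols - 1;
  arma::vec a = dt / Tc;

  arma::mat Y(n, K + 1), X(n, K);
  Y.col(0) = y0;
  for (arma::uword t = 0; t < K; ++t) {
    arma::vec x = W * Y.col(t);
    X.col(t) = x;
    Y.col(t + 1) = (1.0 - a) % Y.col(t) + a % (sigmoid(x) + Iext.col(t));
  }
  if (!Y.is_finite()) return arma::datum::nan;

  double E = cost_from_Y(Y, targets, out_idx, dt, skip);

  arma::vec p(n, arma::fill::zeros);
  arma::mat M(n, K);
  for (arma::uword s = K; s >= 1; --s) {
    const arma::uword t = s - 1;
    arma::vec lam = p;
    if (s > skip) {
      arma::vec d = Y.submat(out_idx, arma::uvec{s}) - targets.col(s);
      lam(out_idx) += dt * d;
    }
    arma::vec Fx = sigmoid(X.col(t));
    arma::vec Fp = Fx % (1.0 - Fx);
    arma::vec m = a % Fp % lam;
    M.col(t) = m;
    gT += lam % (-dt / arma::square(Tc)) % (-Y.col(t) + Fx + Iext.col(t));
    p = (1.0 - a) % lam + W.t() * m;
  }
  gW += M * Y.cols(0, K - 1).t();
  return E;
}

// Sign-based Almeida adaptive-rate training on one or more patterns.
// inputs / targets are lists of matrices (n x (K_p+1) and n_out x (K_p+1));
// T is optimized as log T with a lower clamp at log(dt) for Euler stability.
// Each parameter moves by -rate * sign(gradient); per-parameter rates grow
// by `up` while successive gradient signs agree and shrink by `down` on
// reversal, clamped to [rate_min, rate_max]. On a non-finite cost the
// previous parameters are restored and all rates are scaled down; training
// aborts after max_recoveries such events.
// [[Rcpp::export]]
List cpg_train_cpp(const arma::mat& W0, const arma::vec& T0,
                   const arma::vec& y0, const List& inputs,
                   const List& targets, const arma::uvec& out_idx,
                   const arma::vec& dts, int n_iter,
                   double rate_w, double rate_t,
                   double up, double down,
                   double rate_min, double rate_max,
                   int max_recoveries = 20, int skip = 0) {
  const arma::uword n = W0.n_rows;
  const int n_pat = inputs.size();

  std::vector<arma::mat> Ins(n_pat), Tgt(n_pat);
  for (int pidx = 0; pidx < n_pat; ++pidx) {
    Ins[pidx] = as<arma::mat>(inputs[pidx]);
    Tgt[pidx] = as<arma::mat>(targets[pidx]);
  }

  arma::mat W = W0;
  arma::vec logT = arma::log(T0);
  const double logT_floor = std::log(dts.max());

  arma::mat rW(n, n, arma::fill::value(rate_w));
  arma::vec rT(n, arma::fill::value(rate_t));
  arma::mat prev_gW(n, n, arma::fill::zeros);
  arma::vec prev_gT(n, arma::fill::zeros);

  arma::mat W_prev = W, W_best = W;
  arma::vec logT_prev = logT, logT_best = logT;
  double E_best = arma::datum::inf;
  int recoveries = 0;
  bool failed = false;

  arma::vec loss(n_iter, arma::fill::value(arma::datum::nan));

  for (int it = 0; it < n_iter; ++it) {
    arma::vec Tc = arma::exp(logT);
    arma::mat gW(n, n, arma::fill::zeros);
    arma::vec gT(n, arma::fill::zeros);
    double E = 0.0;
    bool bad = false;
    for (int pidx = 0; pidx < n_pat; ++pidx) {
      double Ep = pattern_grad(W, Tc, y0, Ins[pidx], Tgt[pidx], out_idx,
                               dts(pidx), (arma::uword)std::max(skip, 0),
                               gW, gT);
      if (!std::isfinite(Ep)) { bad = true; break; }
      E += Ep;
    }

    if (bad || !gW.is_finite() || !gT.is_finite()) {
      // divergence: rewind one step and shrink every rate
      ++recoveries;
      if (recoveries > max_recoveries) { failed = true; break; }
      W = W_prev; logT = logT_prev;
      rW *= 0.1; rT *= 0.1;
      rW.clamp(rate_min, rate_max);
      rT.clamp(rate_min, rate_max);
      prev_gW.zeros(); prev_gT.zeros();
      continue;
    }

    loss(it) = E;
    if (E < E_best) { E_best = E; W_best = W; logT_best = logT; }

    // chain rule to log-T space
    arma::vec glogT = gT % Tc;

    // sign-agreement rate adaptation
    if (it > 0) {
      arma::mat sW = gW % prev_gW;
      rW.elem(arma::find(sW > 0)) *= up;
      rW.elem(arma::find(sW < 0)) *= down;
      arma::vec sT = glogT % prev_gT;
      rT.elem(arma::find(sT > 0)) *= up;
      rT.elem(arma::find(sT < 0)) *= down;
      rW.clamp(rate_min, rate_max);
      rT.clamp(rate_min, rate_max);
    }
    prev_gW = gW;
    prev_gT = glogT;

    W_prev = W; logT_prev = logT;
    W -= rW % arma::sign(gW);
    logT -= rT % arma::sign(glogT);
    logT.clamp(logT_floor, 10.0);
  }

  return List::create(
    _["W"] = W_best, _["T"] = arma::exp(logT_best),
    _["E_best"] = E_best, _["loss"] = loss,
    _["recoveries"] = recoveries, _["failed"] = failed);
}
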