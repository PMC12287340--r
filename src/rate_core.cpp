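#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Fresh standard-normal vector drawn from R's RNG so that set.seed() at the
// R level controls every stochastic element of a run.
static arma::vec rnorm_vec(arma::uword n) {
  arma::vec v(n);
  for (arma::uword i = 0; i < n; ++i) v[i] = R::norm_rand();
  return v;
}

// Core integrator + online plasticity loop for the rate network
//
//   tau dx/dt = -x + (G + M) r + W_in I + sigma xi   [+ Q z when feedback]
//   r = tanh(x),  z = W r
//
// rule: 0 = predictive alignment (M) + LMS (W)
//       1 = FORCE: W by recursive least squares, readout fed back as Q z,
//           M static
//       2 = no plasticity (pure simulation / autonomous test)
//
// Per-step order: read state (r, z at time t) -> log -> weight updates with
// the current (r, z, f) -> Euler step of x. Targets/inputs columns are
// aligned with the state at the same step.
//
// [[Rcpp::export]]
List rate_run_cpp(const arma::sp_mat& G, arma::mat M, arma::mat W,
                  const arma::mat& Q, const arma::mat& Win,
                  const arma::mat& I, const arma::mat& F,
                  arma::vec x, double dt, double tau, double sigma,
                  double eta_m, double eta_w, double alpha,
                  int rule,
                  const LogicalVector& learnM, const LogicalVector& learnW,
                  bool feedback, int n_seg, int record_every, bool record_r,
                  bool sde_noise, double lambda_reg, double x_abort) {
  const arma::uword N = x.n_elem;
  const arma::uword T = F.n_cols;
  const arma::uword K = W.n_rows;
  const bool has_input = (Win.n_cols > 0 && I.n_rows > 0);
  const double noise_scale = sde_noise ? std::sqrt(tau / dt) : 1.0;

  arma::vec err_out_ss(n_seg, arma::fill::zeros);
  arma::vec erec_ss(n_seg, arma::fill::zeros);
  arma::vec corr_seg(n_seg, arma::fill::zeros);
  arma::vec seg_steps(n_seg, arma::fill::zeros);
  arma::vec norm_M(n_seg, arma::fill::zeros);
  arma::vec norm_W(n_seg, arma::fill::zeros);

  arma::uword n_rec = 0;
  if (record_every > 0) n_rec = (T + record_every - 1) / record_every;
  arma::mat Zrec(K, n_rec);
  arma::mat Rrec(record_r ? N : 0, record_r ? n_rec : 0);

  arma::mat P;
  if (rule == 1) P = arma::eye<arma::mat>(N, N) / lambda_reg;

  int diverged = 0;  // 1-based step index at which divergence was detected
  arma::uword j = 0;
  int last_seg = -1;

  for (arma::uword t = 0; t < T; ++t) {
    arma::vec r = arma::tanh(x);
    arma::vec Gr = G * r;
    arma::vec Mr = M * r;
    arma::vec z = W * r;
    arma::vec f = F.col(t);

    int s = (int)((t * (arma::uword)n_seg) / T);
    if (s != last_seg) {
      // segment boundary: store entering weight norms (overwritten below at
      // the end of the run so the logged value is the end-of-segment norm)
      last_seg = s;
    }
    arma::vec eo = f - z;
    err_out_ss[s] += arma::dot(eo, eo);
    arma::vec pred_err = (Mr - alpha * Gr) - Q * z;  // Jhat r - Q z
    erec_ss[s] += arma::dot(pred_err, pred_err);
    corr_seg[s] += dt * arma::dot(Gr, Mr);
    seg_steps[s] += 1.0;

    if (record_every > 0 && (t % (arma::uword)record_every) == 0) {
      Zrec.col(j) = z;
      if (record_r) Rrec.col(j) = r;
      ++j;
    }

    if (rule == 0) {
      if (learnW[t]) W += eta_w * (f - z) * r.t();
      if (learnM[t]) M += eta_m * (Q * z - (Mr - alpha * Gr)) * r.t();
    } else if (rule == 1 && learnW[t]) {
      arma::vec Pr = P * r;
      double c = 1.0 / (1.0 + arma::dot(r, Pr));
      P -= c * (Pr * Pr.t());
      W += (f - z) * (c * Pr).t();
    }

    arma::vec dx = -x + Gr + Mr;
    if (has_input) dx += Win * I.col(t);
    if (feedback) dx += Q * z;
    if (sigma > 0.0) dx += sigma * noise_scale * rnorm_vec(N);
    x += (dt / tau) * dx;

    norm_M[s] = arma::norm(M, "fro");
    norm_W[s] = arma::norm(W, "fro");

    if (!x.is_finite() || arma::abs(x).max() > x_abort) {
      diverged = (int)(t + 1);
      break;
    }
  }

  if (record_every > 0 && j < n_rec) {
    Zrec = Zrec.cols(0, j == 0 ? 0 : j - 1);
    if (record_r) Rrec = Rrec.cols(0, j == 0 ? 0 : j - 1);
  }

  return List::create(
      _["M"] = M, _["W"] = W, _["x"] = x,
      _["err_out_ss"] = err_out_ss, _["erec_ss"] = erec_ss,
      _["corr_seg"] = corr_seg, _["seg_steps"] = seg_steps,
      _["norm_M"] = norm_M, _["norm_W"] = norm_W,
      _["z_rec"] = Zrec, _["r_rec"] = Rrec,
      _["diverged"] = diverged);
}

// Twin-trajectory estimate of the leading Lyapunov exponent for the rate
// network: perturb by gamma0 along a random direction, renormalize the
// separation back to gamma0 at every step while preserving its direction,
// and average log(gamma_k / gamma0) over the measurement window.
// Returns the exponent per millisecond (log-growth per step divided by dt).
//
// [[Rcpp::export]]
double lyap_rate_cpp(const arma::sp_mat& G, const arma::mat& M, arma::vec x1,
                     double dt, double tau, int n_warm, int n_meas,
                     double gamma0) {
  const arma::uword N = x1.n_elem;
  arma::vec u = rnorm_vec(N);
  u /= arma::norm(u);
  arma::vec x2 = x1 + gamma0 * u;
  double acc = 0.0;
  const int n_total = n_warm + n_meas;
  for (int k = 0; k < n_total; ++k) {
    arma::vec r1 = arma::tanh(x1);
    arma::vec r2 = arma::tanh(x2);
    x1 += (dt / tau) * (-x1 + G * r1 + M * r1);
    x2 += (dt / tau) * (-x2 + G * r2 + M * r2);
    double gamma = arma::norm(x2 - x1);
    if (gamma <= 0.0)
      stop("degenerate perturbation: twin trajectories collapsed at step %d",
           k + 1);
    if (k >= n_warm) acc += std::log(gamma / gamma0);
    x2 = x1 + (gamma0 / gamma) * (x2 - x1);
  }
  return acc / (double)n_meas / dt;
}

// Fixed-step RK4 integrator for the Lorenz system, used as the target
// generator. Output columns are successive states (x1, x2, x3).
//
// [[Rcpp::export]]
arma::mat lorenz_rk4_cpp(arma::vec y, int n_steps, double h, double s,
                         double rho, double b, int thin) {
  auto deriv = [&](const arma::vec& u) {
    arma::vec d(3);
    d[0] = s * (u[1] - u[0]);
    d[1] = rho * u[0] - u[1] - u[0] * u[2];
    d[2] = u[0] * u[1] - b * u[2];
    return d;
  };
  int n_out = n_steps / thin + 1;
  arma::mat out(3, n_out);
  out.col(0) = y;
  int j = 1;
  for (int k = 1; k <= n_steps; ++k) {
    arma::vec k1 = deriv(y);
    arma::vec k2 = deriv(y + 0.5 * h * k1);
    arma::vec k3 = deriv(y + 0.5 * h * k2);
    arma::vec k4 = deriv(y + h * k3);
    y += (h / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (!y.is_finite()) stop("Lorenz integration diverged at step %d", k);
    if (k % thin == 0 && j < n_out) out.col(j++) = y;
  }
  return out.cols(0, j - 1);
}
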