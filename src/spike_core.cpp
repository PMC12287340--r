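#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Leaky integrate-and-fire recurrent network with exponentially filtered
// spike trains:
//
//   tau_m dv/dt = -v + (G + M) r + I_bias
//   dr_i/dt     = -r_i / tau_s + (1/tau_s) sum_j delta(t - t_ij)
//
// A neuron fires when v >= v_th (and is not refractory); v is reset to
// v_reset and clamped there for tau_ref ms. On the Euler grid a spike adds
// 1/tau_s to the neuron's synaptic trace. Readout and plasticity are the
// same LMS / predictive-alignment rules as in the rate network, operating
// on the filtered traces r.
//
// rule: 0 = predictive alignment + LMS, 2 = no plasticity.
//
// [[Rcpp::export]]
List spike_run_cpp(const arma::sp_mat& G, arma::mat M, arma::mat W,
                   const arma::mat& Q, const arma::vec& I_bias,
                   const arma::mat& F,
                   arma::vec v, arma::vec r, arma::vec refr,
                   double dt, double tau_m, double tau_s,
                   double v_th, double v_reset, double tau_ref,
                   double eta_m, double eta_w, double alpha, int rule,
                   const LogicalVector& learnM, const LogicalVector& learnW,
                   int n_seg, int record_every, bool record_r,
                   bool record_spikes, double v_abort) {
  const arma::uword N = v.n_elem;
  const arma::uword T = F.n_cols;
  const arma::uword K = W.n_rows;

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
  std::vector<double> spike_t;
  std::vector<int> spike_id;

  int diverged = 0;
  arma::uword j = 0;

  // Gr and Mr are maintained incrementally: the plasticity update of M is
  // rank-one in r (so M r changes by a known vector), and between spikes r
  // only decays by a scalar factor while each spike adds a single weight
  // column.  They are recomputed exactly every 1000 steps to stop rounding
  // drift.
  arma::vec Gr = G * r;
  arma::vec Mr = M * r;
  const double decay = 1.0 - dt / tau_s;

  for (arma::uword t = 0; t < T; ++t) {
    if (t % 1000 == 999) {
      Gr = G * r;
      Mr = M * r;
    }
    arma::vec z = W * r;
    arma::vec f = F.col(t);

    int s = (int)((t * (arma::uword)n_seg) / T);
    arma::vec eo = f - z;
    err_out_ss[s] += arma::dot(eo, eo);
    arma::vec pred_err = (Mr - alpha * Gr) - Q * z;
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
      if (learnM[t]) {
        arma::vec err = Q * z - (Mr - alpha * Gr);
        double rr = arma::dot(r, r);
        M += eta_m * err * r.t();
        Mr += eta_m * rr * err;  // rank-one image of the M update
      }
    }

    // membrane integration: refractory neurons stay clamped at v_reset
    arma::vec input = Gr + Mr + I_bias;
    for (arma::uword i = 0; i < N; ++i) {
      if (refr[i] > 0.0) {
        refr[i] -= dt;
        v[i] = v_reset;
      } else {
        v[i] += (dt / tau_m) * (-v[i] + input[i]);
      }
    }
    // spike detection and trace update (spikes add 1/tau_s)
    r *= decay;
    Gr *= decay;
    Mr *= decay;
    for (arma::uword i = 0; i < N; ++i) {
      if (refr[i] <= 0.0 && v[i] >= v_th) {
        v[i] = v_reset;
        refr[i] = tau_ref;
        r[i] += 1.0 / tau_s;
        Gr += G.col(i) / tau_s;
        Mr += M.col(i) / tau_s;
        if (record_spikes) {
          spike_t.push_back((double)(t + 1) * dt);
          spike_id.push_back((int)i + 1);
        }
      }
    }

    norm_M[s] = arma::norm(M, "fro");
    norm_W[s] = arma::norm(W, "fro");
    if (!v.is_finite() || arma::abs(v).max() > v_abort) {
      diverged = (int)(t + 1);
      break;
    }
  }

  if (record_every > 0 && j < n_rec) {
    Zrec = Zrec.cols(0, j == 0 ? 0 : j - 1);
    if (record_r) Rrec = Rrec.cols(0, j == 0 ? 0 : j - 1);
  }

  return List::create(
      _["M"] = M, _["W"] = W, _["v"] = v, _["r"] = r, _["refr"] = refr,
      _["err_out_ss"] = err_out_ss, _["erec_ss"] = erec_ss,
      _["corr_seg"] = corr_seg, _["seg_steps"] = seg_steps,
      _["norm_M"] = norm_M, _["norm_W"] = norm_W,
      _["z_rec"] = Zrec, _["r_rec"] = Rrec,
      _["spike_t"] = wrap(spike_t), _["spike_id"] = wrap(spike_id),
      _["diverged"] = diverged);
}

// Two-population (excitatory / inhibitory) LIF network. All weight blocks
// are element-wise non-negative; inhibition enters the membrane equation
// with an explicit minus sign. Plastic blocks M_XY follow the
// predictive-alignment gradient for the signed recurrent prediction
//   p_X = M_XE r_E - M_XI r_I
// and are rectified at zero after every update so Dale's sign constraint
// is never violated.
//
// [[Rcpp::export]]
List two_pop_run_cpp(const arma::mat& G_EE, const arma::mat& G_EI,
                     const arma::mat& G_IE, const arma::mat& G_II,
                     arma::mat M_EE, arma::mat M_EI,
                     arma::mat M_IE, arma::mat M_II,
                     arma::mat W_E, arma::mat W_I,
                     const arma::mat& Q_E, const arma::mat& Q_I,
                     const arma::vec& bias_E, const arma::vec& bias_I,
                     const arma::mat& F,
                     arma::vec v_E, arma::vec v_I,
                     arma::vec r_E, arma::vec r_I,
                     arma::vec refr_E, arma::vec refr_I,
                     double dt, double tau_m, double tau_s,
                     double v_th, double v_reset, double tau_ref,
                     double eta_m, double eta_w, double alpha, bool plastic,
                     int record_every, double v_abort) {
  const arma::uword NE = v_E.n_elem, NI = v_I.n_elem;
  const arma::uword T = F.n_cols;
  const arma::uword K = W_E.n_rows;

  arma::uword n_rec = 0;
  if (record_every > 0) n_rec = (T + record_every - 1) / record_every;
  arma::mat Zrec(K, n_rec);
  arma::mat VErec(record_every > 0 ? NE : 0, record_every > 0 ? n_rec : 0);
  arma::mat VIrec(record_every > 0 ? NI : 0, record_every > 0 ? n_rec : 0);
  arma::uword j = 0;
  int diverged = 0;

  auto lif_step = [&](arma::vec& v, arma::vec& r, arma::vec& refr,
                      const arma::vec& input) {
    const arma::uword n = v.n_elem;
    for (arma::uword i = 0; i < n; ++i) {
      if (refr[i] > 0.0) {
        refr[i] -= dt;
        v[i] = v_reset;
      } else {
        v[i] += (dt / tau_m) * (-v[i] + input[i]);
      }
    }
    r *= (1.0 - dt / tau_s);
    for (arma::uword i = 0; i < n; ++i) {
      if (refr[i] <= 0.0 && v[i] >= v_th) {
        v[i] = v_reset;
        refr[i] = tau_ref;
        r[i] += 1.0 / tau_s;
      }
    }
  };

  for (arma::uword t = 0; t < T; ++t) {
    arma::vec z = W_E * r_E + W_I * r_I;
    arma::vec f = F.col(t);

    if (record_every > 0 && (t % (arma::uword)record_every) == 0) {
      Zrec.col(j) = z;
      VErec.col(j) = v_E;
      VIrec.col(j) = v_I;
      ++j;
    }

    arma::vec in_E = (G_EE + M_EE) * r_E - (G_EI + M_EI) * r_I + bias_E;
    arma::vec in_I = (G_IE + M_IE) * r_E - (G_II + M_II) * r_I + bias_I;

    if (plastic) {
      W_E += eta_w * (f - z) * r_E.t();
      W_I += eta_w * (f - z) * r_I.t();
      arma::vec phat_E =
          (M_EE - alpha * G_EE) * r_E - (M_EI - alpha * G_EI) * r_I;
      arma::vec phat_I =
          (M_IE - alpha * G_IE) * r_E - (M_II - alpha * G_II) * r_I;
      arma::vec err_E = Q_E * z - phat_E;
      arma::vec err_I = Q_I * z - phat_I;
      M_EE += eta_m * err_E * r_E.t();
      M_EI -= eta_m * err_E * r_I.t();
      M_IE += eta_m * err_I * r_E.t();
      M_II -= eta_m * err_I * r_I.t();
      M_EE.clamp(0.0, arma::datum::inf);
      M_EI.clamp(0.0, arma::datum::inf);
      M_IE.clamp(0.0, arma::datum::inf);
      M_II.clamp(0.0, arma::datum::inf);
    }

    lif_step(v_E, r_E, refr_E, in_E);
    lif_step(v_I, r_I, refr_I, in_I);

    if (!v_E.is_finite() || !v_I.is_finite() ||
        std::max(arma::abs(v_E).max(), arma::abs(v_I).max()) > v_abort) {
      diverged = (int)(t + 1);
      break;
    }
  }

  if (record_every > 0 && j < n_rec) {
    Zrec = Zrec.cols(0, j == 0 ? 0 : j - 1);
    VErec = VErec.cols(0, j == 0 ? 0 : j - 1);
    VIrec = VIrec.cols(0, j == 0 ? 0 : j - 1);
  }

  return List::create(
      _["M_EE"] = M_EE, _["M_EI"] = M_EI, _["M_IE"] = M_IE, _["M_II"] = M_II,
      _["W_E"] = W_E, _["W_I"] = W_I,
      _["v_E"] = v_E, _["v_I"] = v_I, _["r_E"] = r_E, _["r_I"] = r_I,
      _["refr_E"] = refr_E, _["refr_I"] = refr_I,
      _["z_rec"] = Zrec, _["vE_rec"] = VErec, _["vI_rec"] = VIrec,
      _["diverged"] = diverged);
}

// Twin-trajectory Lyapunov estimate for the LIF network; the separation is
// measured on the membrane-potential vector.
//
// [[Rcpp::export]]
double lyap_spike_cpp(const arma::sp_mat& G, const arma::mat& M,
                      const arma::vec& I_bias,
                      arma::vec v1, arma::vec r1, arma::vec refr1,
                      double dt, double tau_m, double tau_s,
                      double v_th, double v_reset, double tau_ref,
                      int n_warm, int n_meas, double gamma0) {
  const arma::uword N = v1.n_elem;
  arma::vec u(N);
  for (arma::uword i = 0; i < N; ++i) u[i] = R::norm_rand();
  u /= arma::norm(u);
  arma::vec v2 = v1 + gamma0 * u;
  arma::vec r2 = r1, refr2 = refr1;

  auto lif_step = [&](arma::vec& v, arma::vec& r, arma::vec& refr) {
    arma::vec input = G * r + M * r + I_bias;
    for (arma::uword i = 0; i < N; ++i) {
      if (refr[i] > 0.0) {
        refr[i] -= dt;
        v[i] = v_reset;
      } else {
        v[i] += (dt / tau_m) * (-v[i] + input[i]);
      }
    }
    r *= (1.0 - dt / tau_s);
    for (arma::uword i = 0; i < N; ++i) {
      if (refr[i] <= 0.0 && v[i] >= v_th) {
        v[i] = v_reset;
        refr[i] = tau_ref;
        r[i] += 1.0 / tau_s;
      }
    }
  };

  double acc = 0.0;
  const int n_total = n_warm + n_meas;
  for (int k = 0; k < n_total; ++k) {
    lif_step(v1, r1, refr1);
    lif_step(v2, r2, refr2);
    double gamma = arma::norm(v2 - v1);
    if (gamma <= 0.0)
      stop("degenerate perturbation: twin trajectories collapsed at step %d",
           k + 1);
    if (k >= n_warm) acc += std::log(gamma / gamma0);
    v2 = v1 + (gamma0 / gamma) * (v2 - v1);
  }
  return acc / (double)n_meas / dt;
}
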