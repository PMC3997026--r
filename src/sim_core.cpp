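// Whole-trial integrator for the coupled latching system.
//
// The sparse-Hopfield + episodic recurrent matrix is rank P + L, so it is
// held in factored form J_max = A * B^T - diag(c) (c = rowSums(A % B)
// restores the zero diagonal). Synaptic depression with presynaptic resource
// consumption factorises per presynaptic unit: J(t) = J_max * diag(d) with
// d' = (1 - d)/tau_r - U * xmax * x * d, so one step costs a handful of
// N x K products instead of dense N x N updates. The dense R reference path
// (step_system) computes the same algebra; equivalence is asserted in tests.

#include <RcppArmadillo.h>
#include <random>

using namespace Rcpp;
using arma::vec;
using arma::mat;

namespace {

struct Layer {
  int N;
  double p, T, tau_n, theta, lambda, theta_ext;
  double dep_coef;   // U * x_max / 1000  [1/ms]
  double tau_r;
  double eta_amp;    // current amplitude (policy may switch it)
  double rho, base_tau_corr;
  int dep_variant;   // 0 presynaptic, 1 postsynaptic
  mat Xi;            // N x P binary patterns
  mat A, B;          // low-rank factors of J_max
  vec cdiag;
  int baseline;      // 0-based column of Xi

  // state
  vec h, x, d, noise;

  // correlation precomputations
  vec kact, ss_xi;

  void setup(const List& L, double dt) {
    N = as<int>(L["n_units"]);
    p = as<double>(L["sparseness"]);
    T = as<double>(L["gain"]);
    tau_n = as<double>(L["tau_n"]);
    theta = as<double>(L["theta"]);
    lambda = as<double>(L["lambda"]);
    theta_ext = as<double>(L["theta_ext"]);
    dep_coef = as<double>(L["U"]) * as<double>(L["x_max"]) / 1000.0;
    tau_r = as<double>(L["tau_r"]);
    eta_amp = as<double>(L["eta_amp"]);
    base_tau_corr = as<double>(L["tau_corr"]);
    rho = std::exp(-dt / base_tau_corr);
    dep_variant = L.containsElementNamed("dep_variant")
                      ? as<int>(L["dep_variant"]) : 0;
    Xi = as<mat>(L["Xi"]);
    A = as<mat>(L["A"]);
    B = as<mat>(L["B"]);
    cdiag = as<vec>(L["cdiag"]);
    baseline = as<int>(L["baseline"]);
    kact = arma::sum(Xi, 0).t();
    ss_xi = kact - arma::square(kact) / double(N);
  }

  void init_on(int col, double relax_ms, double dt) {
    const double eps = 1e-6;
    x = (col >= 0) ? Xi.col(col) : vec(N, arma::fill::zeros);
    vec xc = arma::clamp(x, eps, 1.0 - eps);
    h = T * arma::log(xc / (1.0 - xc));
    x = 1.0 / (1.0 + arma::exp(-h / T));
    d = vec(N, arma::fill::ones);
    noise = vec(N, arma::fill::zeros);
    // deterministic relaxation: undepressed weights, no input, no noise
    int nrel = (int)std::ceil(relax_ms / dt);
    vec zero(N, arma::fill::zeros);
    for (int i = 0; i < nrel; ++i) step_core(zero, dt, false, false);
    d.ones();
    noise.zeros();
  }

  vec recurrent() const {
    if (dep_variant == 0) {
      vec y = d % x;
      return A * (B.t() * y) - cdiag % y;
    }
    return d % (A * (B.t() * x) - cdiag % x);
  }

  // afferent: raw external-origin input, rectified here against theta_ext
  void step_core(const vec& afferent, double dt, bool with_noise,
                 bool with_depression, std::mt19937_64* rng = nullptr,
                 std::normal_distribution<double>* N01 = nullptr) {
    vec drive = recurrent();
    drive -= lambda * (arma::mean(x) - p) + theta;
    drive += arma::clamp(afferent - theta_ext, 0.0, arma::datum::inf);
    if (with_noise && eta_amp > 0.0) {
      double sig = eta_amp * std::sqrt(1.0 - rho * rho);
      for (int i = 0; i < N; ++i)
        noise[i] = rho * noise[i] + sig * (*N01)(*rng);
      drive += noise;
    } else if (with_noise) {
      noise *= rho;
    }
    h += dt / tau_n * (-h + drive);
    x = 1.0 / (1.0 + arma::exp(-h / T));
    if (with_depression && dep_coef > 0.0)
      d += dt * ((1.0 - d) / tau_r - dep_coef * (x % d));
  }

  // Pearson correlations of x with every stored pattern; returns the index
  // of the maximally correlated pattern if it reaches threshold, else -1
  int converged(double threshold, double* best_corr = nullptr) const {
    double mx = arma::mean(x);
    double ssx = arma::dot(x, x) - N * mx * mx;
    if (ssx <= 0) return -1;
    vec num = Xi.t() * x - kact * mx;
    int best = -1;
    double bc = -2.0;
    for (arma::uword m = 0; m < num.n_elem; ++m) {
      double c = num[m] / std::sqrt(ss_xi[m] * ssx);
      if (c > bc) { bc = c; best = (int)m; }
    }
    if (best_corr) *best_corr = bc;
    return (bc >= threshold) ? best : -1;
  }

  double corr_with(int col) const {
    double mx = arma::mean(x);
    double ssx = arma::dot(x, x) - N * mx * mx;
    if (ssx <= 0) return NA_REAL;
    double num = arma::dot(Xi.col(col), x) - kact[col] * mx;
    return num / std::sqrt(ss_xi[col] * ssx);
  }
};

double ramp(double t, double tau) {
  return (t <= 0) ? 0.0 : 1.0 - std::exp(-t / tau);
}

} // namespace

// [[Rcpp::export(name = ".sim_trial_cpp")]]
List sim_trial_cpp(List semL, List lexL, List couplingL, List orthL,
                   List schedule, List policy, double dt,
                   double conv_threshold, double relax_ms, int seed,
                   int record_every) {
  Layer sem, lex;
  sem.setup(semL, dt);
  lex.setup(lexL, dt);

  // inter-layer factors: W_l2s = U1 * V1^T (depressing), W_s2l = gain * U2 * V2^T
  mat L2S_U = as<mat>(couplingL["L2S_U"]);
  mat L2S_V = as<mat>(couplingL["L2S_V"]);
  mat S2L_U = as<mat>(couplingL["S2L_U"]);
  mat S2L_V = as<mat>(couplingL["S2L_V"]);
  double b_coef = as<double>(couplingL["U_between"]) *
                  as<double>(couplingL["x_max"]) / 1000.0;
  double b_tau_r = as<double>(couplingL["tau_r_between"]);
  double ext_gain = as<double>(couplingL["ext_gain_lex"]);
  vec d_b(lex.N, arma::fill::ones);

  bool has_orth = orthL.length() > 0;
  double o_tau_n = 0, o_theta = 0, o_T = 0, o_vis = 0, o_g_l2o = 0, o_g_o2l = 0;
  vec h_o, x_o;
  if (has_orth) {
    o_tau_n = as<double>(orthL["tau_n"]);
    o_theta = as<double>(orthL["theta"]);
    o_T = as<double>(orthL["gain"]);
    o_vis = as<double>(orthL["visual_gain"]);
    o_g_l2o = as<double>(orthL["gain_lex_to_orth"]);
    o_g_o2l = as<double>(orthL["gain_orth_to_lex"]);
    h_o = vec(lex.N, arma::fill::value(-o_theta));
    x_o = 1.0 / (1.0 + arma::exp(-h_o / o_T));
  }

  int prime = as<int>(schedule["prime"]);     // 0-based lexical col, -1 neutral
  double prime_dur = as<double>(schedule["prime_dur"]);
  double soa = as<double>(schedule["soa"]);
  int target = as<int>(schedule["target"]);
  double timeout = as<double>(schedule["timeout"]);
  double tau_prime = as<double>(schedule["tau_ext_prime"]);
  double tau_target = as<double>(schedule["tau_ext_target"]);

  double eta_pre = as<double>(policy["eta_pre"]);
  double eta_post = as<double>(policy["eta_post"]);
  double gain = as<double>(policy["gain"]);
  double gain_post = as<double>(policy["gain_post"]);   // NaN: unchanged

  sem.eta_amp = eta_pre;
  sem.init_on(sem.baseline, relax_ms, dt);
  lex.init_on(lex.baseline, relax_ms, dt);

  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> N01(0.0, 1.0);

  int n_steps = (int)std::ceil((soa + timeout) / dt);
  int last_conv = sem.baseline;
  int n_trans = 0;
  bool first_done = false;
  std::vector<int> seq_id;
  std::vector<double> seq_t;
  double rt = NA_REAL;
  bool timed_out = true;

  std::vector<double> rec_t;
  std::vector<double> rec_lex;
  std::vector<std::vector<double>> rec_sem;

  vec vis_units(lex.N, arma::fill::zeros);

  for (int s = 0; s < n_steps; ++s) {
    double t = s * dt;

    // current visual stimulus
    int stim = -1;
    double amp = 0.0, tau = tau_prime;
    if (t >= soa && target >= 0) {
      stim = target;
      amp = ramp(t - soa, tau_target);
    } else if (t < prime_dur && prime >= 0) {
      stim = prime;
      amp = ramp(t, tau_prime);
    }

    vec x_lex_prev = lex.x;
    vec x_sem_prev = sem.x;

    // semantic afferent: bottom-up through depressing weights
    vec aff_sem = L2S_U * (L2S_V.t() * (d_b % x_lex_prev));
    // lexical afferent: visual (direct or via relays) + top-down feedback
    vec aff_lex = gain * (S2L_U * (S2L_V.t() * x_sem_prev));
    if (has_orth) {
      aff_lex += o_g_o2l * x_o;
      vec vis(lex.N, arma::fill::zeros);
      if (stim >= 0) vis = o_vis * amp * lex.Xi.col(stim);
      vec drive_o = vis + o_g_l2o * x_lex_prev - o_theta;
      h_o += dt / o_tau_n * (-h_o + drive_o);
      x_o = 1.0 / (1.0 + arma::exp(-h_o / o_T));
    } else if (stim >= 0) {
      aff_lex += ext_gain * amp * lex.Xi.col(stim);
    }

    sem.step_core(aff_sem, dt, true, true, &rng, &N01);
    lex.step_core(aff_lex, dt, true, true, &rng, &N01);
    d_b += dt * ((1.0 - d_b) / b_tau_r - b_coef * (x_lex_prev % d_b));

    double tnow = (s + 1) * dt;

    // online semantic transition detection: latching transitions are
    // spontaneous pattern-to-pattern jumps during the prime-target interval;
    // the externally driven baseline departure and the post-target
    // convergence are not transitions
    int cur = sem.converged(conv_threshold);
    if (cur >= 0 && cur != last_conv) {
      if (last_conv >= 0 && last_conv != sem.baseline && tnow < soa) {
        ++n_trans;
        if (!first_done) {
          first_done = true;
          sem.eta_amp = eta_post;
          if (arma::is_finite(gain_post)) gain = gain_post;
        }
      }
      seq_id.push_back(cur);
      seq_t.push_back(tnow);
      last_conv = cur;
    } else if (cur >= 0) {
      last_conv = cur;
    }

    if (record_every > 0 && s % record_every == 0) {
      rec_t.push_back(tnow);
      rec_lex.push_back(target >= 0 ? lex.corr_with(target) : NA_REAL);
      std::vector<double> row(sem.Xi.n_cols);
      double mx = arma::mean(sem.x);
      double ssx = arma::dot(sem.x, sem.x) - sem.N * mx * mx;
      for (arma::uword m = 0; m < sem.Xi.n_cols; ++m) {
        double num = arma::dot(sem.Xi.col(m), sem.x) - sem.kact[m] * mx;
        row[m] = num / std::sqrt(sem.ss_xi[m] * ssx);
      }
      rec_sem.push_back(row);
    }

    if (tnow >= soa && target >= 0 && lex.corr_with(target) >= conv_threshold) {
      rt = tnow - soa;
      timed_out = false;
      break;
    }
  }

  List rec = R_NilValue;
  if (record_every > 0) {
    int nr = rec_t.size(), np = sem.Xi.n_cols;
    NumericMatrix M(nr, np);
    for (int i = 0; i < nr; ++i)
      for (int j = 0; j < np; ++j) M(i, j) = rec_sem[i][j];
    rec = List::create(_["t"] = rec_t, _["sem_corr"] = M,
                       _["lex_target_corr"] = rec_lex);
  }

  return List::create(
      _["rt"] = rt, _["timeout"] = timed_out,
      _["seq_id"] = seq_id, _["seq_t"] = seq_t,
      _["n_transitions"] = n_trans,
      _["eta_used"] = NumericVector::create(eta_pre, eta_post),
      _["gain_final"] = gain,
      _["record"] = rec);
}

// Free run of the semantic layer alone: start converged on the cue, apply
// the cue input for cue_dur ms, then run freely; report the transition
// sequence and the minimum correlation with the cue.
// [[Rcpp::export(name = ".sim_free_cpp")]]
List sim_free_cpp(List semL, int cue, double cue_gain, double cue_dur,
                  double run_length, double dt, double conv_threshold,
                  double relax_ms, int seed) {
  Layer sem;
  sem.setup(semL, dt);
  sem.init_on(cue, relax_ms, dt);

  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> N01(0.0, 1.0);

  int n_steps = (int)std::ceil(run_length / dt);
  int last_conv = cue;
  int n_trans = 0;
  std::vector<int> seq_id;
  std::vector<double> seq_t;
  double min_cue_corr = 1.0;
  vec cue_drive = cue_gain * sem.Xi.col(cue);
  vec zero(sem.N, arma::fill::zeros);

  for (int s = 0; s < n_steps; ++s) {
    double t = s * dt;
    sem.step_core(t < cue_dur ? cue_drive : zero, dt, true, true, &rng, &N01);
    double cc = sem.corr_with(cue);
    if (R_finite(cc) && cc < min_cue_corr) min_cue_corr = cc;
    int cur = sem.converged(conv_threshold);
    if (cur >= 0 && cur != last_conv) {
      if (last_conv >= 0) {
        ++n_trans;
        seq_id.push_back(cur);
        seq_t.push_back((s + 1) * dt);
      }
      last_conv = cur;
    } else if (cur >= 0) {
      last_conv = cur;
    }
  }

  return List::create(_["seq_id"] = seq_id, _["seq_t"] = seq_t,
                      _["n_transitions"] = n_trans,
                      _["min_cue_corr"] = min_cue_corr);
}
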