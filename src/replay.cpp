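#include <Rcpp.h>
using namespace Rcpp;

// Trial-by-trial belief replay shared by the likelihood and trajectory
// exports. Learner codes: 0 = 1alpha, 1 = 2alpha, 2 = select_reject,
// 3 = relative, 4 = range, 5 = kalman. States are per-option values q and
// variances s2, plus per-context trackers v / r_max / r_min. Beliefs at
// decision time (before the update) drive the choice probability.

struct ReplayState {
  std::vector<double> q, s2, v, rmax, rmin;
  double s20;
  ReplayState(int n_options, int n_ctx, double q0, double s20_)
      : q(n_options, q0), s2(n_options, s20_), v(n_ctx, 0.0),
        rmax(n_ctx, 0.0), rmin(n_ctx, 0.0), s20(s20_) {}
};

static inline void step(ReplayState& st, int learner, bool track_sigma,
                        int c, int o, int k, double R,
                        const double* a) {
  double d;
  switch (learner) {
  case 0:  // constant-rate Q-learning
    st.q[c] += a[0] * (R - st.q[c]);
    break;
  case 1:  // dual-rate
    d = R - st.q[c];
    if (d > 0) st.q[c] += a[0] * d; else if (d < 0) st.q[c] += a[1] * d;
    break;
  case 2:  // selected / rejected
    d = R - st.q[c];
    st.q[c] += a[0] * d;
    st.q[o] += a[1] * (-d);
    break;
  case 3: {  // relative (context centring); option update precedes V_c
    d = R - st.v[k] - st.q[c];
    st.q[c] += a[0] * d;
    double dc = (R + st.q[o]) / 2.0 - st.v[k];
    st.v[k] += a[1] * dc;
    break;
  }
  case 4: {  // range normalization, current trackers first
    double rran = (R - st.rmin[k]) / (1.0 + st.rmax[k] - st.rmin[k]);
    st.q[c] += a[0] * (rran - st.q[c]);
    if (R > st.rmax[k]) st.rmax[k] += a[1] * (R - st.rmax[k]);
    if (R < st.rmin[k]) st.rmin[k] += a[1] * (R - st.rmin[k]);
    break;
  }
  case 5: {  // Kalman filter: dynamic rate, shrinking variance
    double al = st.s2[c] / (st.s2[c] + st.s20);
    st.q[c] += al * (R - st.q[c]);
    st.s2[c] -= al * st.s2[c];
    break;
  }
  }
  if (track_sigma && learner != 5) {
    double al = st.s2[c] / (st.s2[c] + st.s20);
    st.s2[c] -= al * st.s2[c];
  }
}

static inline double neg_log_logistic(double d) {
  // -log(plogis(d)) without overflow
  if (d > 0) return std::log1p(std::exp(-d));
  return -d + std::log1p(std::exp(d));
}

// [[Rcpp::export]]
double replay_negll_cpp(int learner, bool qu, bool track_sigma,
                        IntegerVector chosen, IntegerVector other,
                        IntegerVector ctx, NumericVector outcome,
                        LogicalVector update, LogicalVector score,
                        int n_options, int n_ctx, double q0, double s20,
                        NumericVector alphas, double beta_q, double beta_u) {
  ReplayState st(n_options, n_ctx, q0, s20);
  const double* a = alphas.size() > 0 ? &alphas[0] : nullptr;
  double nll = 0.0;
  int n = chosen.size();
  for (int t = 0; t < n; ++t) {
    int c = chosen[t], o = other[t], k = ctx[t];
    if (score[t]) {
      double ud = beta_q * (st.q[c] - st.q[o]);
      if (qu) ud += beta_u * (std::sqrt(st.s2[c]) - std::sqrt(st.s2[o]));
      nll += neg_log_logistic(ud);
    }
    if (update[t]) step(st, learner, track_sigma, c, o, k, outcome[t], a);
  }
  return nll;
}

// [[Rcpp::export]]
NumericMatrix replay_traj_cpp(int learner, bool track_sigma,
                              IntegerVector chosen, IntegerVector other,
                              IntegerVector ctx, NumericVector outcome,
                              LogicalVector update,
                              int n_options, int n_ctx, double q0,
                              double s20, NumericVector alphas) {
  ReplayState st(n_options, n_ctx, q0, s20);
  const double* a = alphas.size() > 0 ? &alphas[0] : nullptr;
  int n = chosen.size();
  NumericMatrix out(n, 4);
  colnames(out) = CharacterVector::create("q_chosen", "q_other",
                                          "sigma_chosen", "sigma_other");
  for (int t = 0; t < n; ++t) {
    int c = chosen[t], o = other[t], k = ctx[t];
    out(t, 0) = st.q[c];
    out(t, 1) = st.q[o];
    out(t, 2) = std::sqrt(st.s2[c]);
    out(t, 3) = std::sqrt(st.s2[o]);
    if (update[t]) step(st, learner, track_sigma, c, o, k, outcome[t], a);
  }
  return out;
}
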