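// Compiled AEIF network integrator: classical RK4 with delayed
// presynaptic conductance traces. Mirrors the plain-R reference step
// (aeif_rk4_step) exactly; the R tests compare the two.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// cap on the exponential argument (matches EXP_ARG_MAX on the R side);
// only relevant for the overshoot between threshold crossing and reset
static const double EXP_ARG_MAX = 50.0;

// [[Rcpp::export]]
List aeif_run_cpp(NumericVector V0, NumericVector w0, NumericVector s0,
                  NumericVector a, NumericVector b,
                  double C_m, double g_L, double E_L, double Delta_T,
                  double V_T, double tau_w, double tau_s, double V_r,
                  double I_const, double V_thres,
                  IntegerVector exc_ptr, IntegerVector exc_pre,
                  NumericVector exc_w,
                  IntegerVector inh_ptr, IntegerVector inh_pre,
                  NumericVector inh_w,
                  double dt, int n_steps, int d_exc_steps, int d_inh_steps,
                  int record_every, double v_rev_exc, double v_rev_inh) {
  const int N = V0.size();
  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> s(s0.begin(), s0.end());

  const int depth = std::max(d_exc_steps, d_inh_steps) + 1;
  // ring buffer of the trace vector over the last `depth` steps;
  // zeros encode the empty history before t = 0
  std::vector<double> hist((size_t)depth * N, 0.0);

  std::vector<double> Aexc(N), Ainh(N);
  std::vector<double> Vs(N), ws(N), ss(N);
  std::vector<double> kV(N), kw(N), ks(N);
  std::vector<double> sumV(N), sumw(N), sums(N);

  std::vector<int> spike_id;
  std::vector<double> spike_t;
  std::vector<double> rec_t, rec_I;

  auto deriv = [&](const std::vector<double>& Vx,
                   const std::vector<double>& wx,
                   const std::vector<double>& sx) {
    for (int j = 0; j < N; ++j) {
      double Ic = (v_rev_exc - Vx[j]) * Aexc[j] +
                  (v_rev_inh - Vx[j]) * Ainh[j];
      double arg = (Vx[j] - V_T) / Delta_T;
      if (arg > EXP_ARG_MAX) arg = EXP_ARG_MAX;
      kV[j] = (-g_L * (Vx[j] - E_L) + g_L * Delta_T * std::exp(arg) -
               wx[j] + I_const + Ic) / C_m;
      kw[j] = (a[j] * (Vx[j] - E_L) - wx[j]) / tau_w;
      ks[j] = -sx[j] / tau_s;
    }
  };

  for (int i = 0; i < n_steps; ++i) {
    const double t = i * dt;
    // store s(t); slots for steps i-depth+1 .. i remain readable
    std::copy(s.begin(), s.end(), hist.begin() + (size_t)(i % depth) * N);

    // delayed trace sums per postsynaptic neuron, frozen for this step
    if (i >= d_exc_steps) {
      const double* h = &hist[(size_t)((i - d_exc_steps) % depth) * N];
      for (int j = 0; j < N; ++j) {
        double acc = 0.0;
        for (int m = exc_ptr[j]; m < exc_ptr[j + 1]; ++m)
          acc += exc_w[m] * h[exc_pre[m]];
        Aexc[j] = acc;
      }
    } else {
      std::fill(Aexc.begin(), Aexc.end(), 0.0);
    }
    if (i >= d_inh_steps) {
      const double* h = &hist[(size_t)((i - d_inh_steps) % depth) * N];
      for (int j = 0; j < N; ++j) {
        double acc = 0.0;
        for (int m = inh_ptr[j]; m < inh_ptr[j + 1]; ++m)
          acc += inh_w[m] * h[inh_pre[m]];
        Ainh[j] = acc;
      }
    } else {
      std::fill(Ainh.begin(), Ainh.end(), 0.0);
    }

    if (record_every > 0 && i % record_every == 0) {
      double acc = 0.0;
      for (int j = 0; j < N; ++j)
        acc += (v_rev_exc - V[j]) * Aexc[j] + (v_rev_inh - V[j]) * Ainh[j];
      rec_t.push_back(t);
      rec_I.push_back(acc / N);
    }

    // RK4 with the delayed sums held at their value for time t
    deriv(V, w, s); // k1
    for (int j = 0; j < N; ++j) {
      sumV[j] = kV[j]; sumw[j] = kw[j]; sums[j] = ks[j];
      Vs[j] = V[j] + 0.5 * dt * kV[j];
      ws[j] = w[j] + 0.5 * dt * kw[j];
      ss[j] = s[j] + 0.5 * dt * ks[j];
    }
    deriv(Vs, ws, ss); // k2
    for (int j = 0; j < N; ++j) {
      sumV[j] += 2.0 * kV[j]; sumw[j] += 2.0 * kw[j]; sums[j] += 2.0 * ks[j];
      Vs[j] = V[j] + 0.5 * dt * kV[j];
      ws[j] = w[j] + 0.5 * dt * kw[j];
      ss[j] = s[j] + 0.5 * dt * ks[j];
    }
    deriv(Vs, ws, ss); // k3
    for (int j = 0; j < N; ++j) {
      sumV[j] += 2.0 * kV[j]; sumw[j] += 2.0 * kw[j]; sums[j] += 2.0 * ks[j];
      Vs[j] = V[j] + dt * kV[j];
      ws[j] = w[j] + dt * kw[j];
      ss[j] = s[j] + dt * ks[j];
    }
    deriv(Vs, ws, ss); // k4
    const double t_next = (i + 1) * dt;
    for (int j = 0; j < N; ++j) {
      V[j] += dt / 6.0 * (sumV[j] + kV[j]);
      w[j] += dt / 6.0 * (sumw[j] + kw[j]);
      s[j] += dt / 6.0 * (sums[j] + ks[j]);
      if (!std::isfinite(V[j]) || !std::isfinite(w[j])) {
        stop("non-finite state for neuron %d at t = %.4f ms", j + 1, t_next);
      }
      if (V[j] > V_thres) { // detect/reset after the full step
        V[j] = V_r;
        w[j] += b[j];
        s[j] += 1.0;
        spike_id.push_back(j + 1);
        spike_t.push_back(t_next);
      }
    }
    if (i % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  // close the recorded series at t = T_total using the final state
  if (record_every > 0) {
    const int i = n_steps;
    double acc = 0.0;
    std::copy(s.begin(), s.end(), hist.begin() + (size_t)(i % depth) * N);
    for (int j = 0; j < N; ++j) {
      double ae = 0.0, ai = 0.0;
      if (i >= d_exc_steps) {
        const double* h = &hist[(size_t)((i - d_exc_steps) % depth) * N];
        for (int m = exc_ptr[j]; m < exc_ptr[j + 1]; ++m)
          ae += exc_w[m] * h[exc_pre[m]];
      }
      if (i >= d_inh_steps) {
        const double* h = &hist[(size_t)((i - d_inh_steps) % depth) * N];
        for (int m = inh_ptr[j]; m < inh_ptr[j + 1]; ++m)
          ai += inh_w[m] * h[inh_pre[m]];
      }
      acc += (v_rev_exc - V[j]) * ae + (v_rev_inh - V[j]) * ai;
    }
    rec_t.push_back(n_steps * dt);
    rec_I.push_back(acc / N);
  }

  return List::create(
    _["spike_id"] = wrap(spike_id), _["spike_t"] = wrap(spike_t),
    _["rec_t"] = wrap(rec_t), _["rec_I"] = wrap(rec_I),
    _["V"] = wrap(V), _["w"] = wrap(w), _["s"] = wrap(s));
}
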