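// Time-stepped co-simulation of two delay-coupled conductance-based
// populations. Gating rates are supplied from R as a voltage lookup table so
// the R-level rate functions remain the single definition of the kinetics.
// Integration is the Heun predictor-corrector; synapses are
// difference-of-exponentials states updated by exact exponential decay
// between spike-delivery events; per-edge conduction delays are realised
// with a ring buffer in units of the integration step. All randomness draws
// from R's RNG so a set.seed() on the R side makes trials bit-reproducible.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct RateTab {
  double vmin, dv;
  int n;
  const double *r[6]; // alpha_n beta_n alpha_m beta_m alpha_h beta_h

  inline void lookup(double V, double out[6]) const {
    double u = (V - vmin) / dv;
    if (u < 0) u = 0;
    if (u > n - 1.000001) u = n - 1.000001;
    int i = (int)u;
    double w = u - i;
    for (int k = 0; k < 6; ++k)
      out[k] = r[k][i] * (1.0 - w) + r[k][i + 1] * w;
  }
};

// ionic + synaptic drift of one neuron; returns dV, dn, dh
static inline void membrane_rhs(double V, double n, double h,
                                const double *np, double g_exc, double g_inh,
                                double g_ext, double E_ampa, double E_gaba,
                                const RateTab &tab, double out[3]) {
  double rt[6];
  tab.lookup(V, rt);
  double m = rt[2] / (rt[2] + rt[3]);
  double I_ion = -np[1] * m * m * m * h * (V - np[4])  // Na
               - np[2] * n * n * n * n * (V - np[5])   // K
               - np[3] * (V - np[6]);                  // leak
  double I_syn = (g_exc + g_ext) * (E_ampa - V) + g_inh * (E_gaba - V);
  out[0] = (I_ion + I_syn) / np[0];
  out[1] = rt[0] * (1.0 - n) - rt[1] * n;
  out[2] = rt[4] * (1.0 - h) - rt[5] * h;
}

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(int N, IntegerVector exc, NumericMatrix nparams,
              NumericVector syn_tau_d, NumericVector syn_tau_r,
              NumericVector syn_w, NumericVector syn_E,
              IntegerVector edge_pre, IntegerVector edge_post,
              IntegerVector edge_delay_steps, IntegerVector edge_class,
              NumericMatrix rate_pop, IntegerVector pop_of,
              IntegerVector stim_ids, int stim_on, int stim_off,
              double stim_inc, double dt, int n_steps, int record_every,
              double v_thresh, int refract_steps, NumericVector V0,
              NumericVector n0, NumericVector h0, double tab_vmin,
              double tab_dv, NumericMatrix tab_rates, bool independent_ou,
              double ou_nu0, double ou_sigma, double ou_a, double ou_s,
              bool ou_clip, double inh_drive_gain,
              IntegerVector record_v_ids) {
  RateTab tab;
  tab.vmin = tab_vmin;
  tab.dv = tab_dv;
  tab.n = tab_rates.nrow();
  std::vector<std::vector<double>> tabcol(6);
  for (int k = 0; k < 6; ++k) {
    tabcol[k].assign(tab_rates.begin() + (size_t)k * tab.n,
                     tab_rates.begin() + (size_t)(k + 1) * tab.n);
    tab.r[k] = tabcol[k].data();
  }

  const double E_ampa = syn_E[0], E_gaba = syn_E[1];
  // per-class decay multipliers
  double fd[3], fr[3];
  for (int c = 0; c < 3; ++c) {
    fd[c] = std::exp(-dt / syn_tau_d[c]);
    fr[c] = std::exp(-dt / syn_tau_r[c]);
  }

  // CSR over presynaptic neuron
  int n_edges = edge_pre.size();
  std::vector<int> deg(N, 0), off(N + 1, 0);
  for (int e = 0; e < n_edges; ++e) deg[edge_pre[e]]++;
  for (int i = 0; i < N; ++i) off[i + 1] = off[i] + deg[i];
  std::vector<int> csr_tgt(n_edges), csr_del(n_edges), csr_cls(n_edges),
      fill(off.begin(), off.end() - 1);
  int max_del = 1;
  for (int e = 0; e < n_edges; ++e) {
    int p = edge_pre[e], slot = fill[p]++;
    csr_tgt[slot] = edge_post[e];
    csr_del[slot] = edge_delay_steps[e];
    csr_cls[slot] = edge_class[e];
    if (edge_delay_steps[e] > max_del) max_del = edge_delay_steps[e];
  }
  int L = max_del + 2; // ring-buffer length

  // event increments waiting for delivery: [slot][class][neuron]
  std::vector<double> ring((size_t)L * 2 * N, 0.0);
  auto ring_at = [&](int slot, int cls, int i) -> double & {
    return ring[((size_t)slot * 2 + cls) * N + i];
  };

  // synapse states A (decay) and B (rise) per class
  std::vector<double> A0(N, 0), B0(N, 0), A1(N, 0), B1(N, 0), A2(N, 0),
      B2(N, 0);
  std::vector<double> V(V0.begin(), V0.end()), n(n0.begin(), n0.end()),
      h(h0.begin(), h0.end());
  std::vector<int> last_spike(N, -refract_steps - 1);
  std::vector<std::vector<double>> spikes(N);

  std::vector<int> is_stim(N, 0), pend_ext(N, 0);
  for (int k = 0; k < stim_ids.size(); ++k) is_stim[stim_ids[k]] = 1;

  // per-neuron OU state (independent mode)
  std::vector<double> nu(N, ou_nu0);
  if (independent_ou)
    for (int i = 0; i < N; ++i) nu[i] = ou_nu0 + ou_sigma * R::norm_rand();
  long n_clipped = 0;

  int n_rec = n_steps / record_every;
  NumericMatrix I_exc_abs(n_rec, 2), I_inh_abs(n_rec, 2);
  int n_vrec = record_v_ids.size();
  NumericMatrix V_rec(n_vrec > 0 ? n_rec : 0, n_vrec);
  std::vector<double> acc_exc(2, 0), acc_inh(2, 0);
  std::vector<double> acc_v(n_vrec, 0);
  std::vector<int> n_exc_pop(2, 0);
  for (int i = 0; i < N; ++i)
    if (exc[i]) n_exc_pop[pop_of[i]]++;

  double d1[3], d2[3];
  for (int step = 0; step < n_steps; ++step) {
    int slot = step % L;
    // deliver events scheduled for this step
    for (int i = 0; i < N; ++i) {
      double wa = ring_at(slot, 0, i);
      if (wa != 0) {
        A0[i] += wa;
        B0[i] += wa;
        ring_at(slot, 0, i) = 0;
      }
      double wg = ring_at(slot, 1, i);
      if (wg != 0) {
        A1[i] += wg;
        B1[i] += wg;
        ring_at(slot, 1, i) = 0;
      }
    }

    bool in_window = (step >= stim_on && step < stim_off);
    for (int i = 0; i < N; ++i) {
      double g_exc = A0[i] - B0[i];
      double g_inh = A1[i] - B1[i];
      double g_ext = A2[i] - B2[i];
      // conductances after one decay step, for the corrector stage
      double g_exc2 = A0[i] * fd[0] - B0[i] * fr[0];
      double g_inh2 = A1[i] * fd[1] - B1[i] * fr[1];
      double g_ext2 = A2[i] * fd[2] - B2[i] * fr[2];
      const double *np = &nparams(0, i); // nparams is 7 x N
      membrane_rhs(V[i], n[i], h[i], np, g_exc, g_inh, g_ext, E_ampa,
                   E_gaba, tab, d1);
      double Vp = V[i] + dt * d1[0];
      double np_ = n[i] + dt * d1[1];
      double hp = h[i] + dt * d1[2];
      membrane_rhs(Vp, np_, hp, np, g_exc2, g_inh2, g_ext2, E_ampa, E_gaba,
                   tab, d2);
      double Vn = V[i] + 0.5 * dt * (d1[0] + d2[0]);
      double nn = n[i] + 0.5 * dt * (d1[1] + d2[1]);
      double hn = h[i] + 0.5 * dt * (d1[2] + d2[2]);
      if (!std::isfinite(Vn) || Vn < -150 || Vn > 100)
        stop("integration failure: neuron %d diverged at t = %g ms", i + 1,
             (step + 1) * dt);
      if (nn < 0) nn = 0;
      if (nn > 1) nn = 1;
      if (hn < 0) hn = 0;
      if (hn > 1) hn = 1;

      // LFP accumulators: |excitatory| + |inhibitory| current onto E cells
      if (exc[i]) {
        int p = pop_of[i];
        acc_exc[p] += std::fabs((g_exc + g_ext) * (E_ampa - V[i]));
        acc_inh[p] += std::fabs(g_inh * (E_gaba - V[i]));
      }

      // spike detection: upward crossing with refractory lockout
      if (Vn >= v_thresh && V[i] < v_thresh &&
          step - last_spike[i] > refract_steps) {
        last_spike[i] = step;
        double t_sp = (step + 1) * dt;
        spikes[i].push_back(t_sp);
        for (int s = off[i]; s < off[i + 1]; ++s) {
          int dslot = (step + csr_del[s]) % L;
          ring_at(dslot, csr_cls[s], csr_tgt[s]) += syn_w[csr_cls[s]];
        }
      }
      V[i] = Vn;
      n[i] = nn;
      h[i] = hn;

      // external Poisson drive, delivered at the next step
      double rate;
      if (independent_ou) {
        nu[i] = ou_nu0 + ou_a * (nu[i] - ou_nu0) + ou_s * R::norm_rand();
        rate = nu[i];
        if (ou_clip && rate < 0) {
          rate = 0;
          ++n_clipped;
        }
      } else {
        rate = rate_pop(step, pop_of[i]);
      }
      if (in_window && is_stim[i]) rate += stim_inc;
      if (!exc[i]) rate *= inh_drive_gain;
      double p_ev = rate * dt * 1e-3;
      if (p_ev >= 1.0)
        stop("external drive: rate * dt >= 1; decrease dt");
      // the event increments the ext synapse after this step's decay,
      // i.e. the PSP onset is at the next step (drive arrives undelayed)
      pend_ext[i] = (p_ev > 0 && unif_rand() < p_ev) ? 1 : 0;
    }

    // decay synapse states, then inject the external events drawn above
    for (int i = 0; i < N; ++i) {
      A0[i] *= fd[0];
      B0[i] *= fr[0];
      A1[i] *= fd[1];
      B1[i] *= fr[1];
      A2[i] *= fd[2];
      B2[i] *= fr[2];
      if (pend_ext[i]) {
        A2[i] += syn_w[2];
        B2[i] += syn_w[2];
        pend_ext[i] = 0;
      }
    }

    for (int k = 0; k < n_vrec; ++k) acc_v[k] += V[record_v_ids[k]];

    if ((step + 1) % record_every == 0) {
      int r = (step + 1) / record_every - 1;
      for (int p = 0; p < 2; ++p) {
        I_exc_abs(r, p) = acc_exc[p] / record_every;
        I_inh_abs(r, p) = acc_inh[p] / record_every;
        acc_exc[p] = 0;
        acc_inh[p] = 0;
      }
      for (int k = 0; k < n_vrec; ++k) {
        V_rec(r, k) = acc_v[k] / record_every;
        acc_v[k] = 0;
      }
    }
    if (step % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  List spk(N);
  for (int i = 0; i < N; ++i) spk[i] = NumericVector(spikes[i].begin(),
                                                     spikes[i].end());
  return List::create(_["spikes"] = spk, _["I_exc_abs"] = I_exc_abs,
                      _["I_inh_abs"] = I_inh_abs, _["V_rec"] = V_rec,
                      _["n_ou_clipped"] = (double)n_clipped);
}
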