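// Compartmental cable solver: branched passive cable + Hodgkin-Huxley Na/K
// currents + dual-exponential AMPA/NMDA synapses with instantaneous
// voltage-dependent Mg block. Voltage step is Crank-Nicolson with conductances
// frozen over the step (second order, unconditionally stable); the linear tree
// system is solved exactly per step by Hines elimination. Gating states are
// advanced by exponential Euler using the start-of-step voltage.
//
// Units: mV, ms, nF, uS, nA (1 uS * 1 mV = 1 nA; 1 nF * 1 mV/ms = 1 nA).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// x / (1 - exp(-x/y)), safe near x = 0 (limit y)
static inline double vtrap(double x, double y) {
  if (std::fabs(x / y) < 1e-6) return y * (1.0 + x / (2.0 * y));
  return x / (1.0 - std::exp(-x / y));
}

struct Gates {
  std::vector<double> m, h, n;
};

// na_shift depolarizes the Na activation curve (mV); inactivation is shifted
// by an additional na_inact_shift (cortical Na channels inactivate at more
// depolarized potentials than the classical squid constants, which keeps
// channels available near spike threshold under sustained bias). The
// delayed-rectifier n gate is left in place.
static inline void gate_rates(double v, double na_shift, double na_inact_shift,
                              double* am, double* bm,
                              double* ah, double* bh, double* an, double* bn) {
  const double vna = v - na_shift;
  const double vh = v - na_shift - na_inact_shift;
  *am = 0.1 * vtrap(vna + 40.0, 10.0);
  *bm = 4.0 * std::exp(-(vna + 65.0) / 18.0);
  *ah = 0.07 * std::exp(-(vh + 65.0) / 20.0);
  *bh = 1.0 / (1.0 + std::exp(-(vh + 35.0) / 10.0));
  *an = 0.01 * vtrap(v + 55.0, 10.0);
  *bn = 0.125 * std::exp(-(v + 65.0) / 80.0);
}

// [[Rcpp::export]]
List cable_core(IntegerVector parent, NumericVector cm_nF,
                NumericVector g_leak_uS, NumericVector e_leak,
                NumericVector g_ax_uS, NumericVector gbar_na_uS,
                NumericVector gbar_k_uS, double e_na, double e_k,
                double q10, int k_exp, double na_shift, double na_inact_shift,
                IntegerVector syn_comp, NumericVector syn_onset,
                NumericVector syn_gmax_uS, NumericVector syn_tau_r,
                NumericVector syn_tau_f, NumericVector syn_erev,
                LogicalVector syn_nmda, NumericVector syn_mg_half,
                NumericVector syn_mg_slope,
                IntegerVector inj_comp, NumericVector inj_amp_nA,
                NumericVector inj_start, NumericVector inj_stop,
                int noise_comp, double noise_mean, double noise_sd,
                double noise_interval,
                double dt, double duration, double pre_ms,
                IntegerVector record_comp) {
  const int nc = parent.size();
  const int ns = syn_comp.size();
  const int nrec = record_comp.size();
  const int nt = (int)std::lround(duration / dt);
  const int npre = (int)std::lround(pre_ms / dt);

  std::vector<double> v(nc), diag(nc), rhs(nc);
  Gates g; g.m.resize(nc); g.h.resize(nc); g.n.resize(nc);

  // initial condition: leak reversal, gates at steady state
  for (int i = 0; i < nc; ++i) {
    v[i] = e_leak[i];
    double am, bm, ah, bh, an, bn;
    gate_rates(v[i], na_shift, na_inact_shift, &am, &bm, &ah, &bh, &an, &bn);
    g.m[i] = am / (am + bm);
    g.h[i] = ah / (ah + bh);
    g.n[i] = an / (an + bn);
  }

  // precompute synaptic waveform normalization factors and cutoff
  std::vector<double> syn_norm(ns), syn_cut(ns);
  for (int s = 0; s < ns; ++s) {
    double tr = syn_tau_r[s], tf = syn_tau_f[s];
    double tp = std::log(tf / tr) * tr * tf / (tf - tr);
    syn_norm[s] = std::exp(-tp / tf) - std::exp(-tp / tr);
    syn_cut[s] = 12.0 * tf;
  }

  NumericMatrix vout(nt + 1, nrec);
  double noise_cur = 0.0;
  double next_noise_t = 0.0;

  for (int step = -npre; step < nt; ++step) {
    const bool pre = step < 0;
    const double t = pre ? 0.0 : step * dt;     // start-of-step time
    if (step == 0) {
      for (int r = 0; r < nrec; ++r) vout(0, r) = v[record_comp[r]];
      next_noise_t = 0.0;
    }

    // gating update (exponential Euler at start-of-step voltage)
    for (int i = 0; i < nc; ++i) {
      if (gbar_na_uS[i] == 0.0 && gbar_k_uS[i] == 0.0) continue;
      double am, bm, ah, bh, an, bn;
      gate_rates(v[i], na_shift, na_inact_shift, &am, &bm, &ah, &bh, &an, &bn);
      double sm = q10 * (am + bm), sh = q10 * (ah + bh), sn = q10 * (an + bn);
      g.m[i] += (am / (am + bm) - g.m[i]) * (1.0 - std::exp(-dt * sm));
      g.h[i] += (ah / (ah + bh) - g.h[i]) * (1.0 - std::exp(-dt * sh));
      g.n[i] += (an / (an + bn) - g.n[i]) * (1.0 - std::exp(-dt * sn));
    }

    // assemble diagonal and rhs
    for (int i = 0; i < nc; ++i) {
      double gion = g_leak_uS[i];
      double gE = g_leak_uS[i] * e_leak[i];
      if (gbar_na_uS[i] > 0.0) {
        double gna = gbar_na_uS[i] * g.m[i] * g.m[i] * g.m[i] * g.h[i];
        gion += gna; gE += gna * e_na;
      }
      if (gbar_k_uS[i] > 0.0) {
        double nk = (k_exp == 4) ? g.n[i] * g.n[i] * g.n[i] * g.n[i] : g.n[i];
        double gk = gbar_k_uS[i] * nk;
        gion += gk; gE += gk * e_k;
      }
      diag[i] = cm_nF[i] / dt + 0.5 * gion;
      // rhs = cm/dt*v + 0.5*Iion(v) + 0.5*g*E, with Iion(v) = gE - gion*v
      rhs[i] = (cm_nF[i] / dt) * v[i] + 0.5 * (gE - gion * v[i]) + 0.5 * gE;
    }

    // synaptic conductances at mid-step time
    if (!pre && ns > 0) {
      const double tm = t + 0.5 * dt;
      for (int s = 0; s < ns; ++s) {
        double trel = tm - syn_onset[s];
        if (trel <= 0.0 || trel > syn_cut[s]) continue;
        double gs = syn_gmax_uS[s] *
          (std::exp(-trel / syn_tau_f[s]) - std::exp(-trel / syn_tau_r[s])) /
          syn_norm[s];
        int i = syn_comp[s];
        if (syn_nmda[s]) {
          gs *= 1.0 / (1.0 + std::exp(-(v[i] + syn_mg_half[s]) / syn_mg_slope[s]));
        }
        diag[i] += 0.5 * gs;
        rhs[i] += 0.5 * gs * (syn_erev[s] - v[i]) + 0.5 * gs * syn_erev[s];
      }
    }

    // injected currents (constant pulses) and noisy bias
    if (!pre) {
      for (int k = 0; k < inj_comp.size(); ++k) {
        if (t >= inj_start[k] && t < inj_stop[k]) rhs[inj_comp[k]] += inj_amp_nA[k];
      }
      if (noise_comp >= 0) {
        if (t >= next_noise_t - 1e-9) {
          noise_cur = R::rnorm(noise_mean, noise_sd);
          next_noise_t += noise_interval;
        }
        rhs[noise_comp] += noise_cur;
      }
    }

    // axial terms: explicit half on rhs, implicit half into the tree matrix
    for (int i = 1; i < nc; ++i) {
      int p = parent[i];
      double ga = 0.5 * g_ax_uS[i];
      rhs[i] += ga * (v[p] - v[i]);
      rhs[p] += ga * (v[i] - v[p]);
      diag[i] += ga;
      diag[p] += ga;
    }

    // Hines elimination (parent[i] < i by construction)
    for (int i = nc - 1; i >= 1; --i) {
      int p = parent[i];
      double b = 0.5 * g_ax_uS[i];
      double f = b / diag[i];
      diag[p] -= f * b;
      rhs[p] += f * rhs[i];
    }
    v[0] = rhs[0] / diag[0];
    for (int i = 1; i < nc; ++i) {
      v[i] = (rhs[i] + 0.5 * g_ax_uS[i] * v[parent[i]]) / diag[i];
    }

    if (!pre) {
      for (int r = 0; r < nrec; ++r) vout(step + 1, r) = v[record_comp[r]];
    }
  }

  NumericVector times(nt + 1);
  for (int k = 0; k <= nt; ++k) times[k] = k * dt;
  return List::create(_["time"] = times, _["v"] = vout);
}
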