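// Core integrator for recurrent conductance-based LIF networks with
// spike-triggered plasticity, plus helpers shared with the R level
// (Poisson input generation, isolated spike-train rule application).
//
// Integration scheme (identical in the R reference stepper step_network()):
//   per step s (time t = s*dt, state refers to time t):
//     1. forward-Euler membrane update using start-of-step conductances
//        (refractory neurons are clamped, no integration);
//     2. threshold crossing -> spike, reset (Vogels: V_rest + refractory
//        clock; Zenke: V_reset + adaptive-threshold increment);
//     3. auxiliary low-pass variables (<V>, C_E, C_I) updated from the
//        just-updated membrane and start-of-step conductances;
//     4. exact exponential conductance decay (NMDA: Euler relaxation toward
//        start-of-step AMPA), exact exponential threshold relaxation;
//     5. spikes of this step (external events + emitted) increment target
//        conductances by the synaptic weight -> effective next step;
//     6. plasticity: all pre-triggered updates, then all post-triggered
//        updates; synaptic traces are read before any bump of this step
//        and bumped (+1) afterwards.  Weights are clipped to their block
//        bounds after every single update.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int SP_STATIC = 0, SP_SMALL = 1, SP_BIG = 2, SP_MLP = 3;

// --------------------------------------------------------------------------
// event-driven exact-exponential synaptic trace
struct Trace {
  std::vector<double> x;
  std::vector<int> last;
  double dt_over_tau;
  void init(int n, double tau, double dt) {
    x.assign(n, 0.0);
    last.assign(n, 0);
    dt_over_tau = dt / tau;
  }
  inline double get(int i, int s) {
    if (s != last[i]) {
      x[i] *= std::exp(-(s - last[i]) * dt_over_tau);
      last[i] = s;
    }
    return x[i];
  }
  inline void bump(int i, int s) {
    get(i, s);
    x[i] += 1.0;
  }
};

// --------------------------------------------------------------------------
// plasticity-rule increments (shared by the network integrator and the
// isolated spike-train driver so both run the same arithmetic)
static inline double small_pre_delta(const double* th, double x_post) {
  return th[0] + th[3] * x_post;           // alpha + kappa * x_post
}
static inline double small_post_delta(const double* th, double x_pre) {
  return th[1] + th[2] * x_pre;            // beta + gamma * x_pre
}
static inline double big_delta(const double* th, bool pre_event, double w,
                               double vavg, double ce, double ci,
                               double x_short_pre, double x_long_pre,
                               double x_short_post, double x_long_post) {
  if (pre_event) {
    return th[0]
      * (1.0 + th[1] + th[2] * w + th[3] * w * w)
      * (1.0 + th[4] * vavg)
      * (1.0 + th[5] * ce + th[6] * ce * ce)
      * (1.0 + th[7] * ci)
      * (1.0 + th[8] * x_long_pre)
      * (1.0 + th[9] * x_short_post);
  }
  return th[10]
    * (1.0 + th[11] + th[12] * w + th[13] * w * w)
    * (1.0 + th[14] * vavg)
    * (1.0 + th[15] * ce + th[16] * ce * ce)
    * (1.0 + th[17] * ci)
    * (1.0 + th[18] * x_short_pre)
    * (1.0 + th[19] * x_long_post + th[20] * x_long_post * x_long_post * x_long_post);
}
static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// theta layout for MLP space: w_pre[4], b_pre, w_post[4], b_post, lr  (11)
static inline double mlp_delta(const double* th, const double* W1,
                               const double* W2, bool pre_event,
                               const double* in6) {
  double h1[50], h2[4];
  for (int u = 0; u < 50; ++u) {
    double acc = 0.0;
    const double* row = W1 + 6 * u;      // row-major 50 x 6
    for (int k = 0; k < 6; ++k) acc += row[k] * in6[k];
    h1[u] = sigmoid(acc);
  }
  for (int u = 0; u < 4; ++u) {
    double acc = 0.0;
    const double* row = W2 + 50 * u;     // row-major 4 x 50
    for (int k = 0; k < 50; ++k) acc += row[k] * h1[k];
    h2[u] = sigmoid(acc);
  }
  const double* wo = pre_event ? th : th + 5;
  double out = wo[4];                    // bias
  for (int k = 0; k < 4; ++k) out += wo[k] * h2[k];
  return th[10] * out;                   // shared learning rate
}

// --------------------------------------------------------------------------
struct Block {
  int npre = 0, npost = 0;
  int pre_pop = 0, post_pop = 0;   // 0 = E, 1 = I, 2 = external
  std::vector<int> pre_loc;        // presynaptic index within its population
  std::vector<int> post_glob;      // postsynaptic global index (E first)
  std::vector<int> post_loc;
  std::vector<double> w;
  std::vector<int> out_ptr, out_syn;   // CSR by presynaptic neuron
  std::vector<int> in_ptr, in_syn;     // CSR by postsynaptic neuron
  int space = SP_STATIC;
  std::vector<double> th;
  double lo = 0.0, hi = 10.0;
  Trace xpre, xpost;               // small-poly learnable-tau traces
  std::vector<double> W1, W2;      // frozen MLP layers
  bool excitatory_pre = true;

  void build_csr() {
    int ns = (int)w.size();
    out_ptr.assign(npre + 1, 0);
    for (int s = 0; s < ns; ++s) out_ptr[pre_loc[s] + 1]++;
    for (int i = 0; i < npre; ++i) out_ptr[i + 1] += out_ptr[i];
    out_syn.assign(ns, 0);
    std::vector<int> cur(out_ptr.begin(), out_ptr.end() - 1);
    for (int s = 0; s < ns; ++s) out_syn[cur[pre_loc[s]]++] = s;
    in_ptr.assign(npost + 1, 0);
    for (int s = 0; s < ns; ++s) in_ptr[post_loc[s] + 1]++;
    for (int i = 0; i < npost; ++i) in_ptr[i + 1] += in_ptr[i];
    in_syn.assign(ns, 0);
    std::vector<int> cur2(in_ptr.begin(), in_ptr.end() - 1);
    for (int s = 0; s < ns; ++s) in_syn[cur2[post_loc[s]]++] = s;
  }
};

static Block parse_block(List bl, int n_exc, int n_inh, double dt) {
  Block b;
  std::string pre_pop = as<std::string>(bl["pre_pop"]);
  std::string post_pop = as<std::string>(bl["post_pop"]);
  b.pre_pop = pre_pop == "exc" ? 0 : (pre_pop == "inh" ? 1 : 2);
  b.post_pop = post_pop == "exc" ? 0 : 1;
  b.npre = as<int>(bl["npre"]);
  b.npost = as<int>(bl["npost"]);
  b.excitatory_pre = (b.pre_pop != 1);
  IntegerVector pre = bl["pre"], post = bl["post"];
  NumericVector w = bl["w"];
  int ns = w.size();
  b.pre_loc.resize(ns); b.post_loc.resize(ns);
  b.post_glob.resize(ns); b.w.resize(ns);
  int off = (b.post_pop == 1) ? n_exc : 0;
  for (int s = 0; s < ns; ++s) {
    b.pre_loc[s] = pre[s] - 1;
    b.post_loc[s] = post[s] - 1;
    b.post_glob[s] = post[s] - 1 + off;
    b.w[s] = w[s];
  }
  b.space = as<int>(bl["space"]);
  b.lo = as<double>(bl["lo"]);
  b.hi = as<double>(bl["hi"]);
  if (b.space != SP_STATIC) b.th = as<std::vector<double>>(bl["theta"]);
  if (b.space == SP_SMALL) {
    b.xpre.init(b.npre, as<double>(bl["tau_pre"]), dt);
    b.xpost.init(b.npost, as<double>(bl["tau_post"]), dt);
  }
  if (b.space == SP_MLP) {
    NumericMatrix W1 = bl["W1"], W2 = bl["W2"];   // 50 x 6, 4 x 50
    b.W1.resize(50 * 6); b.W2.resize(4 * 50);
    for (int u = 0; u < 50; ++u)
      for (int k = 0; k < 6; ++k) b.W1[6 * u + k] = W1(u, k);
    for (int u = 0; u < 4; ++u)
      for (int k = 0; k < 50; ++k) b.W2[50 * u + k] = W2(u, k);
  }
  b.build_csr();
  return b;
}

// [[Rcpp::export]]
List sim_episode_cpp(int variant, List prm, int n_exc, int n_inh,
                     List blocks, IntegerVector ext_step, IntegerVector ext_id,
                     int n_steps, double dt, double rate_bin_ms,
                     NumericMatrix eval_windows_ms, double freeze_after_ms,
                     bool record_spikes, int record_v, int n_weight_samples) {
  const int n = n_exc + n_inh;
  const double tau_m = prm["tau_m"], v_rest = prm["V_rest"];
  const double e_exc = prm["E_exc"], e_inh = prm["E_inh"];
  const double tau_ampa = prm["tau_AMPA"], tau_gaba = prm["tau_GABA"];
  const double dA = std::exp(-dt / tau_ampa), dG = std::exp(-dt / tau_gaba);
  const bool zenke = (variant == 1);
  // Vogels fixed threshold / refractory; Zenke adaptive threshold, NMDA
  double v_th = 0, tau_ref = 0; int ref_steps = 0;
  double v_reset = 0, v_th_base = 0, v_th_spike = 0, dTH = 1, a_frac = 0,
         tau_nmda = 1;
  if (!zenke) {
    v_th = as<double>(prm["V_th"]);
    tau_ref = as<double>(prm["tau_ref"]);
    ref_steps = (int)std::lround(tau_ref / dt);
  } else {
    v_reset = as<double>(prm["V_reset"]);
    v_th_base = as<double>(prm["V_th_base"]);
    v_th_spike = as<double>(prm["V_th_spike"]);
    dTH = std::exp(-dt / as<double>(prm["tau_th"]));
    a_frac = as<double>(prm["a_frac"]);
    tau_nmda = as<double>(prm["tau_NMDA"]);
  }

  std::vector<Block> B;
  CharacterVector bn = blocks.names();
  std::vector<std::string> names;
  for (int i = 0; i < blocks.size(); ++i) {
    B.push_back(parse_block(blocks[i], n_exc, n_inh, dt));
    names.push_back(as<std::string>(bn[i]));
  }
  // block role lookup: pre-event blocks / post-event blocks per population
  std::vector<int> pre_blocks_E, pre_blocks_I, post_blocks_E, post_blocks_I,
      prop_blocks_E, prop_blocks_I, prop_blocks_X;
  bool any_plastic = false, need_aux = false;
  for (size_t bi = 0; bi < B.size(); ++bi) {
    Block& b = B[bi];
    if (b.pre_pop == 0) prop_blocks_E.push_back(bi);
    else if (b.pre_pop == 1) prop_blocks_I.push_back(bi);
    else prop_blocks_X.push_back(bi);
    if (b.space != SP_STATIC) {
      any_plastic = true;
      if (b.space >= SP_BIG) need_aux = true;
      if (b.pre_pop == 0) pre_blocks_E.push_back(bi);
      if (b.pre_pop == 1) pre_blocks_I.push_back(bi);
      if (b.post_pop == 0) post_blocks_E.push_back(bi);
      if (b.post_pop == 1) post_blocks_I.push_back(bi);
    }
  }

  std::vector<double> V(n, v_rest), gA(n, 0.0), gG(n, 0.0);
  std::vector<double> gN, Vth;
  std::vector<int> refr;
  if (zenke) { gN.assign(n, 0.0); Vth.assign(n, v_th_base); }
  else refr.assign(n, 0);

  Trace xs, xl;                      // fixed 10 / 100 ms traces (big/MLP)
  std::vector<double> vavg, ce, ci;
  const double tau_vavg = 100.0, tau_ce = 10.0, tau_ci = 100.0;
  if (need_aux) {
    xs.init(n, 10.0, dt); xl.init(n, 100.0, dt);
    vavg.assign(n, v_rest); ce.assign(n, 0.0); ci.assign(n, 0.0);
  }

  // recording
  const int steps_per_bin = std::max(1, (int)std::lround(rate_bin_ms / dt));
  const int nbins = (n_steps + steps_per_bin - 1) / steps_per_bin;
  std::vector<int> cntE(nbins, 0), cntI(nbins, 0);
  const int nwin = eval_windows_ms.nrow();
  std::vector<long> win_cnt(nwin, 0);
  std::vector<int> win_lo(nwin), win_hi(nwin);
  for (int k = 0; k < nwin; ++k) {
    win_lo[k] = (int)std::lround(eval_windows_ms(k, 0) / dt);
    win_hi[k] = (int)std::lround(eval_windows_ms(k, 1) / dt);
  }
  std::vector<int> rast_id, rast_step;
  std::vector<double> vtrace;
  if (record_v >= 0) vtrace.reserve(n_steps);
  const long rast_cap = 6000000;
  long nsp_E = 0, nsp_I = 0;
  // weight-statistic sampling
  int ws_every = n_weight_samples > 0
      ? std::max(1, n_steps / n_weight_samples) : n_steps + 1;
  std::vector<double> ws_time;
  std::vector<std::vector<double>> ws_mean(B.size()), ws_min(B.size()),
      ws_max(B.size());
  const int freeze_step = freeze_after_ms >= n_steps * dt
      ? n_steps + 1 : (int)std::lround(freeze_after_ms / dt);

  bool diverged = false;
  std::vector<int> spikers; spikers.reserve(n);
  int ext_ptr = 0; const int n_ext_ev = ext_step.size();

  for (int s = 0; s < n_steps && !diverged; ++s) {
    spikers.clear();
    // 1-2: membrane update + spike detection
    for (int i = 0; i < n; ++i) {
      if (!zenke && refr[i] > 0) { refr[i]--; V[i] = v_rest; continue; }
      double ge = zenke ? (a_frac * gA[i] + (1 - a_frac) * gN[i]) : gA[i];
      double v = V[i];
      v += dt / tau_m * (-(v - v_rest) - ge * (v - e_exc) - gG[i] * (v - e_inh));
      if (!std::isfinite(v)) { diverged = true; break; }
      double th = zenke ? Vth[i] : v_th;
      if (v >= th) {
        spikers.push_back(i);
        v = zenke ? v_reset : v_rest;
        if (!zenke) refr[i] = ref_steps;
      }
      V[i] = v;
    }
    if (diverged) break;
    // 3: auxiliary low-pass variables
    if (need_aux) {
      for (int i = 0; i < n; ++i) {
        double ge = zenke ? (a_frac * gA[i] + (1 - a_frac) * gN[i]) : gA[i];
        vavg[i] += dt / tau_vavg * (V[i] - vavg[i]);
        ce[i] += dt / tau_ce * (ge * (e_exc - V[i]) - ce[i]);
        ci[i] += dt / tau_ci * (gG[i] * (e_inh - V[i]) - ci[i]);
      }
    }
    // 4: conductance / threshold decay
    if (zenke) {
      for (int i = 0; i < n; ++i) {
        gN[i] += dt / tau_nmda * (gA[i] - gN[i]);
        gA[i] *= dA; gG[i] *= dG;
        Vth[i] = v_th_base + (Vth[i] - v_th_base) * dTH;
      }
      for (int k : spikers) Vth[k] += v_th_spike;
    } else {
      for (int i = 0; i < n; ++i) { gA[i] *= dA; gG[i] *= dG; }
    }
    // 5: spike delivery (external, then recurrent)
    while (ext_ptr < n_ext_ev && ext_step[ext_ptr] == s) {
      int xi = ext_id[ext_ptr] - 1;
      for (int bi : prop_blocks_X) {
        Block& b = B[bi];
        for (int q = b.out_ptr[xi]; q < b.out_ptr[xi + 1]; ++q) {
          int syn = b.out_syn[q];
          gA[b.post_glob[syn]] += b.w[syn];
        }
      }
      ext_ptr++;
    }
    for (int k : spikers) {
      const std::vector<int>& pb = (k < n_exc) ? prop_blocks_E : prop_blocks_I;
      int loc = (k < n_exc) ? k : k - n_exc;
      for (int bi : pb) {
        Block& b = B[bi];
        for (int q = b.out_ptr[loc]; q < b.out_ptr[loc + 1]; ++q) {
          int syn = b.out_syn[q];
          if (b.excitatory_pre) gA[b.post_glob[syn]] += b.w[syn];
          else gG[b.post_glob[syn]] += b.w[syn];
        }
      }
    }
    // 6: plasticity (pre-triggered first, then post-triggered)
    if (any_plastic && s < freeze_step && !spikers.empty()) {
      for (int k : spikers) {
        const std::vector<int>& pb = (k < n_exc) ? pre_blocks_E : pre_blocks_I;
        int loc = (k < n_exc) ? k : k - n_exc;
        for (int bi : pb) {
          Block& b = B[bi];
          const double* th = b.th.data();
          for (int q = b.out_ptr[loc]; q < b.out_ptr[loc + 1]; ++q) {
            int syn = b.out_syn[q];
            double dw;
            if (b.space == SP_SMALL) {
              dw = small_pre_delta(th, b.xpost.get(b.post_loc[syn], s));
            } else {
              int jg = b.post_glob[syn];
              int ig = (b.pre_pop == 0) ? loc : n_exc + loc;
              if (b.space == SP_BIG) {
                dw = big_delta(th, true, b.w[syn], vavg[jg], ce[jg], ci[jg],
                               xs.get(ig, s), xl.get(ig, s),
                               xs.get(jg, s), xl.get(jg, s));
              } else {
                double in6[6] = {xl.get(ig, s), xs.get(jg, s), b.w[syn],
                                 vavg[jg], ce[jg], ci[jg]};
                dw = mlp_delta(th, b.W1.data(), b.W2.data(), true, in6);
              }
              if (!std::isfinite(dw)) { diverged = true; dw = 0.0; }
            }
            double w = b.w[syn] + dw;
            b.w[syn] = w < b.lo ? b.lo : (w > b.hi ? b.hi : w);
          }
        }
      }
      for (int k : spikers) {
        const std::vector<int>& pb = (k < n_exc) ? post_blocks_E : post_blocks_I;
        int loc = (k < n_exc) ? k : k - n_exc;
        for (int bi : pb) {
          Block& b = B[bi];
          const double* th = b.th.data();
          for (int q = b.in_ptr[loc]; q < b.in_ptr[loc + 1]; ++q) {
            int syn = b.in_syn[q];
            double dw;
            if (b.space == SP_SMALL) {
              dw = small_post_delta(th, b.xpre.get(b.pre_loc[syn], s));
            } else {
              int jg = b.post_glob[syn];
              int ig = (b.pre_pop == 0) ? b.pre_loc[syn]
                                        : n_exc + b.pre_loc[syn];
              if (b.space == SP_BIG) {
                dw = big_delta(th, false, b.w[syn], vavg[jg], ce[jg], ci[jg],
                               xs.get(ig, s), xl.get(ig, s),
                               xs.get(jg, s), xl.get(jg, s));
              } else {
                double in6[6] = {xs.get(ig, s), xl.get(jg, s), b.w[syn],
                                 vavg[jg], ce[jg], ci[jg]};
                dw = mlp_delta(th, b.W1.data(), b.W2.data(), false, in6);
              }
              if (!std::isfinite(dw)) { diverged = true; dw = 0.0; }
            }
            double w = b.w[syn] + dw;
            b.w[syn] = w < b.lo ? b.lo : (w > b.hi ? b.hi : w);
          }
        }
      }
    }
    // trace bumps after all updates of this step
    if (any_plastic && !spikers.empty()) {
      for (int k : spikers) {
        if (need_aux) { xs.bump(k, s); xl.bump(k, s); }
        int pop = (k < n_exc) ? 0 : 1;
        int loc = (k < n_exc) ? k : k - n_exc;
        for (Block& b : B) {
          if (b.space != SP_SMALL) continue;
          if (b.pre_pop == pop) b.xpre.bump(loc, s);
          if (b.post_pop == pop) b.xpost.bump(loc, s);
        }
      }
    }
    // 7: recording
    int bin = s / steps_per_bin;
    for (int k : spikers) {
      if (k < n_exc) { cntE[bin]++; nsp_E++; } else { cntI[bin]++; nsp_I++; }
      if (record_spikes && (long)rast_id.size() < rast_cap) {
        rast_id.push_back(k + 1);
        rast_step.push_back(s);
      }
    }
    if (nwin > 0) {
      for (int kk = 0; kk < nwin; ++kk)
        if (s >= win_lo[kk] && s < win_hi[kk])
          for (int k : spikers) if (k < n_exc) win_cnt[kk]++;
    }
    if (record_v >= 0) vtrace.push_back(V[record_v]);
    if (n_weight_samples > 0 && ((s + 1) % ws_every == 0 || s == n_steps - 1)) {
      ws_time.push_back((s + 1) * dt);
      for (size_t bi = 0; bi < B.size(); ++bi) {
        const Block& b = B[bi];
        if (b.space == SP_STATIC) continue;
        double mn = R_PosInf, mx = R_NegInf, mean = 0;
        for (double wv : b.w) {
          mean += wv;
          if (wv < mn) mn = wv;
          if (wv > mx) mx = wv;
        }
        ws_mean[bi].push_back(mean / b.w.size());
        ws_min[bi].push_back(mn);
        ws_max[bi].push_back(mx);
      }
    }
  }

  // outputs
  NumericMatrix rates(nbins, 2);
  for (int b = 0; b < nbins; ++b) {
    int lo = b * steps_per_bin;
    int hi = std::min(n_steps, lo + steps_per_bin);
    double wsec = (hi - lo) * dt / 1000.0;
    rates(b, 0) = cntE[b] / (wsec * n_exc);
    rates(b, 1) = cntI[b] / (wsec * n_inh);
  }
  NumericVector win_rates(nwin);
  for (int k = 0; k < nwin; ++k) {
    double wsec = (win_hi[k] - win_lo[k]) * dt / 1000.0;
    win_rates[k] = wsec > 0 ? win_cnt[k] / (wsec * n_exc) : NA_REAL;
  }
  List wfin(B.size()), wstats(B.size());
  for (size_t bi = 0; bi < B.size(); ++bi) {
    wfin[bi] = NumericVector(B[bi].w.begin(), B[bi].w.end());
    if (B[bi].space != SP_STATIC && !ws_time.empty()) {
      wstats[bi] = DataFrame::create(
          _["time_ms"] = NumericVector(ws_time.begin(), ws_time.end()),
          _["mean"] = NumericVector(ws_mean[bi].begin(), ws_mean[bi].end()),
          _["min"] = NumericVector(ws_min[bi].begin(), ws_min[bi].end()),
          _["max"] = NumericVector(ws_max[bi].begin(), ws_max[bi].end()));
    } else {
      wstats[bi] = R_NilValue;
    }
  }
  wfin.names() = bn; wstats.names() = bn;
  List out = List::create(
      _["rates"] = rates, _["rate_bin_ms"] = steps_per_bin * dt,
      _["eval_rates"] = win_rates, _["w_final"] = wfin,
      _["w_stats"] = wstats, _["diverged"] = diverged,
      _["n_spikes_exc"] = (double)nsp_E, _["n_spikes_inh"] = (double)nsp_I,
      _["raster_id"] = IntegerVector(rast_id.begin(), rast_id.end()),
      _["raster_step"] = IntegerVector(rast_step.begin(), rast_step.end()));
  if (record_v >= 0)
    out["v_trace"] = NumericVector(vtrace.begin(), vtrace.end());
  return out;
}

// --------------------------------------------------------------------------
// Homogeneous Poisson input as per-bin Bernoulli events.  Implemented as a
// per-bin Binomial(n, p) count followed by a uniform draw of distinct
// neurons, which is distributionally identical to n independent Bernoulli
// draws per bin.  Uses R's RNG: reproducible under set.seed().
// [[Rcpp::export]]
List gen_poisson_cpp(IntegerVector ids, double p, int nbins) {
  int m = ids.size();
  std::vector<int> ev_bin, ev_id;
  std::vector<int> pick;
  for (int b = 0; b < nbins; ++b) {
    int k = (int)R::rbinom(m, p);
    if (k == 0) continue;
    pick.clear();
    while ((int)pick.size() < k) {        // k << m: rejection is cheap
      int c = (int)std::floor(R::unif_rand() * m);
      if (c == m) c = m - 1;
      bool dup = false;
      for (int q : pick) if (q == c) { dup = true; break; }
      if (!dup) pick.push_back(c);
    }
    std::sort(pick.begin(), pick.end());
    for (int q : pick) { ev_bin.push_back(b); ev_id.push_back(ids[q]); }
  }
  return List::create(
      _["step"] = IntegerVector(ev_bin.begin(), ev_bin.end()),
      _["id"] = IntegerVector(ev_id.begin(), ev_id.end()));
}

// --------------------------------------------------------------------------
// Step-based application of a plasticity rule to one prescribed pre/post
// spike-train pair on a single synapse (auxiliary variables clamped).  Runs
// the same trace bookkeeping and increment arithmetic as the network
// integrator; used for oracle-equivalence checks and pairing protocols.
// [[Rcpp::export]]
List forced_train_cpp(int space, NumericVector theta, IntegerVector pre_steps,
                      IntegerVector post_steps, int n_steps, double dt,
                      double w0, double lo, double hi, NumericVector clamps,
                      double tau_pre, double tau_post,
                      Nullable<NumericMatrix> W1_, Nullable<NumericMatrix> W2_) {
  std::vector<double> th = as<std::vector<double>>(theta);
  std::vector<double> W1, W2;
  if (space == SP_MLP) {
    NumericMatrix W1m(W1_), W2m(W2_);
    W1.resize(50 * 6); W2.resize(4 * 50);
    for (int u = 0; u < 50; ++u)
      for (int k = 0; k < 6; ++k) W1[6 * u + k] = W1m(u, k);
    for (int u = 0; u < 4; ++u)
      for (int k = 0; k < 50; ++k) W2[50 * u + k] = W2m(u, k);
  }
  double vavg = clamps[0], ce = clamps[1], ci = clamps[2];
  Trace xp, xq, xs_pre, xl_pre, xs_post, xl_post;
  xp.init(1, tau_pre, dt); xq.init(1, tau_post, dt);
  xs_pre.init(1, 10.0, dt); xl_pre.init(1, 100.0, dt);
  xs_post.init(1, 10.0, dt); xl_post.init(1, 100.0, dt);
  double w = w0;
  std::vector<double> w_after; std::vector<int> ev_step;
  int ip = 0, iq = 0, np = pre_steps.size(), nq = post_steps.size();
  for (int s = 0; s < n_steps; ++s) {
    while (ip < np && pre_steps[ip] < s) ip++;   // robustness to duplicates
    while (iq < nq && post_steps[iq] < s) iq++;
    bool pre = ip < np && pre_steps[ip] == s;
    bool post = iq < nq && post_steps[iq] == s;
    if (!pre && !post) continue;
    if (pre) {
      double dw;
      if (space == SP_SMALL) dw = small_pre_delta(th.data(), xq.get(0, s));
      else if (space == SP_BIG)
        dw = big_delta(th.data(), true, w, vavg, ce, ci, xs_pre.get(0, s),
                       xl_pre.get(0, s), xs_post.get(0, s), xl_post.get(0, s));
      else {
        double in6[6] = {xl_pre.get(0, s), xs_post.get(0, s), w, vavg, ce, ci};
        dw = mlp_delta(th.data(), W1.data(), W2.data(), true, in6);
      }
      w += dw;
      w = w < lo ? lo : (w > hi ? hi : w);
      w_after.push_back(w); ev_step.push_back(s);
    }
    if (post) {
      double dw;
      if (space == SP_SMALL) dw = small_post_delta(th.data(), xp.get(0, s));
      else if (space == SP_BIG)
        dw = big_delta(th.data(), false, w, vavg, ce, ci, xs_pre.get(0, s),
                       xl_pre.get(0, s), xs_post.get(0, s), xl_post.get(0, s));
      else {
        double in6[6] = {xs_pre.get(0, s), xl_post.get(0, s), w, vavg, ce, ci};
        dw = mlp_delta(th.data(), W1.data(), W2.data(), false, in6);
      }
      w += dw;
      w = w < lo ? lo : (w > hi ? hi : w);
      w_after.push_back(w); ev_step.push_back(s);
    }
    if (pre) { xp.bump(0, s); xs_pre.bump(0, s); xl_pre.bump(0, s); ip++; }
    if (post) { xq.bump(0, s); xs_post.bump(0, s); xl_post.bump(0, s); iq++; }
  }
  return List::create(
      _["w_final"] = w,
      _["w_after"] = NumericVector(w_after.begin(), w_after.end()),
      _["event_step"] = IntegerVector(ev_step.begin(), ev_step.end()));
}
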