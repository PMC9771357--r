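// Compiled per-trial runner for the cerebellar network. Mirrors, step for
// step, the R reference update in R/neuron.R: conductance decay + delivery of
// last step's spikes, forward-Euler membrane update, spike detection against
// the adaptive threshold, reset to the leak reversal, threshold decay + jump.
// All synapses deliver with a one-step (1 ms) delay. Mossy-fiber activity is
// Bernoulli with per-step probability rate * dt (capped at 1), drawn from R's
// RNG so R-level set.seed() governs reproducibility.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Pop {
  int n = 0;
  double el = 0, gl = 0, th0 = 0, dth = 0, tauth = 1, ereset = 0;
  std::vector<double> slot_tau, slot_e, slot_gain, slot_decay;
  std::vector<double> V, theta, g, pending; // g/pending: n * nslots, col-major
  std::vector<int> spiked; // this step
  double th_decay = 1;
  int nslots() const { return (int)slot_tau.size(); }
};

struct Proj {
  int src_pop = 0, tgt_pop = 0, slot = 0;
  // source-major CSR
  std::vector<int> offset;          // size n_src + 1
  std::vector<int> tgt;             // edge targets (0-based)
  std::vector<double> w;            // edge weights
};

const int N_DYN = 6; // grc, goc, pc, bc, sc, dcn ; mf = 6, cf = 7

Pop unpack_pop(const List& p, const List& st, double dt) {
  Pop out;
  out.n = as<int>(p["n"]);
  out.el = as<double>(p["e_leak"]);   out.gl = as<double>(p["g_leak"]);
  out.th0 = as<double>(p["theta0"]);  out.dth = as<double>(p["d_theta"]);
  out.tauth = as<double>(p["tau_theta"]);
  out.ereset = as<double>(p["e_reset"]);
  out.slot_tau = as<std::vector<double>>(p["slot_tau"]);
  out.slot_e = as<std::vector<double>>(p["slot_e"]);
  out.slot_gain = as<std::vector<double>>(p["slot_gain"]);
  out.th_decay = std::exp(-dt / out.tauth);
  for (double tau : out.slot_tau) out.slot_decay.push_back(std::exp(-dt / tau));
  int ns = out.nslots();
  out.V.assign(out.n, out.el);
  out.theta.assign(out.n, out.th0);
  out.g.assign((size_t)out.n * ns, 0.0);
  out.pending.assign((size_t)out.n * ns, 0.0);
  out.spiked.assign(out.n, 0);
  if (st.size() > 0) {
    NumericVector V = st["V"], th = st["theta"];
    NumericMatrix g = st["g"], pend = st["pending"];
    for (int i = 0; i < out.n; ++i) { out.V[i] = V[i]; out.theta[i] = th[i]; }
    for (int s = 0; s < ns; ++s)
      for (int i = 0; i < out.n; ++i) {
        out.g[(size_t)s * out.n + i] = g(i, s);
        out.pending[(size_t)s * out.n + i] = pend(i, s);
      }
  }
  return out;
}

Proj unpack_proj(const List& p, int n_src) {
  Proj out;
  out.src_pop = as<int>(p["src_pop"]);
  out.tgt_pop = as<int>(p["tgt_pop"]);
  out.slot = as<int>(p["slot"]);
  IntegerVector src = p["src"], tgt = p["tgt"];
  NumericVector w = p["weight"];
  int m = src.size();
  std::vector<int> count(n_src + 1, 0);
  for (int e = 0; e < m; ++e) count[src[e] + 1]++;
  out.offset.assign(n_src + 1, 0);
  for (int i = 0; i < n_src; ++i) out.offset[i + 1] = out.offset[i] + count[i + 1];
  std::vector<int> cur(out.offset.begin(), out.offset.end() - 1);
  out.tgt.assign(m, 0);
  out.w.assign(m, 0.0);
  for (int e = 0; e < m; ++e) {
    int pos = cur[src[e]]++;
    out.tgt[pos] = tgt[e];
    out.w[pos] = w[e];
  }
  return out;
}

struct Log {
  bool on = false;
  std::vector<int> id, t;
  void add(int i, int step) { if (on) { id.push_back(i + 1); t.push_back(step); } }
};

} // namespace

// [[Rcpp::export(name = ".sim_run_trial_cpp")]]
List sim_run_trial_cpp(List packed, List state, List drive, List opts) {
  const double dt = 1.0;
  List pop_list = packed["pops"];
  List proj_list = packed["projections"];
  int n_mf = as<int>(packed["n_mf"]);
  int n_cf = as<int>(packed["n_cf"]);

  std::vector<Pop> pops(N_DYN);
  for (int k = 0; k < N_DYN; ++k) {
    List st = (state.size() > 0) ? as<List>(state[k]) : List();
    pops[k] = unpack_pop(as<List>(pop_list[k]), st, dt);
  }

  std::vector<Proj> projs;
  for (int j = 0; j < proj_list.size(); ++j) {
    List pl = proj_list[j];
    int sp = as<int>(pl["src_pop"]);
    int ns = (sp == 6) ? n_mf : (sp == 7) ? n_cf : pops[sp].n;
    projs.push_back(unpack_proj(pl, ns));
  }

  // drive
  NumericMatrix mf_rate = drive["mf_rate"]; // n_mf x T (Hz)
  int T = mf_rate.ncol();
  IntegerVector coll_idx = drive["coll_idx"]; // 0-based mf indices
  double coll_base = as<double>(drive["coll_base"]);
  double coll_gain = as<double>(drive["coll_gain"]);
  double coll_cap = as<double>(drive["coll_cap"]);
  IntegerVector cf_id = drive["cf_id"], cf_t = drive["cf_t"]; // 0-based
  bool fixed_mf = drive.containsElementNamed("mf_spikes") &&
    !Rf_isNull(drive["mf_spikes"]);
  IntegerMatrix mf_fixed;
  if (fixed_mf) mf_fixed = as<IntegerMatrix>(drive["mf_spikes"]);

  double dcn_tau = as<double>(opts["dcn_tau"]);
  double dcn_decay = std::exp(-dt / dcn_tau);
  LogicalVector log_flags = opts["log"]; // named: grc goc pc bc sc dcn mf cf
  std::vector<Log> logs(8);
  for (int k = 0; k < 8; ++k) logs[k].on = log_flags[k];

  // per-CF spike schedule
  std::vector<std::vector<int>> cf_sched(n_cf);
  for (int e = 0; e < cf_id.size(); ++e)
    cf_sched[cf_id[e]].push_back(cf_t[e]);
  std::vector<size_t> cf_ptr(n_cf, 0);

  std::vector<int> mf_spike(n_mf, 0), cf_spike(n_cf, 0);
  NumericVector dcn_trace(T);
  double dcn_smooth = as<double>(opts["dcn_smooth0"]);

  for (int t = 0; t < T; ++t) {
    // external spikes emitted this step
    for (int i = 0; i < n_mf; ++i) {
      if (fixed_mf) {
        mf_spike[i] = mf_fixed(i, t);
      } else {
        double rate = mf_rate(i, t);
        double p = rate * dt * 1e-3;
        if (p > 1) p = 1;
        mf_spike[i] = (p > 0 && unif_rand() < p) ? 1 : 0;
      }
      if (mf_spike[i]) logs[6].add(i, t);
    }
    for (int c = 0; c < n_cf; ++c) {
      cf_spike[c] = 0;
      while (cf_ptr[c] < cf_sched[c].size() && cf_sched[c][cf_ptr[c]] < t)
        ++cf_ptr[c];
      if (cf_ptr[c] < cf_sched[c].size() && cf_sched[c][cf_ptr[c]] == t) {
        cf_spike[c] = 1;
        logs[7].add(c, t);
      }
    }
    // collateral mossy fibers follow smoothed DCN output
    if (!fixed_mf) {
      for (int j = 0; j < coll_idx.size(); ++j) {
        int i = coll_idx[j];
        double rate = coll_base + coll_gain * dcn_smooth;
        if (rate > coll_cap) rate = coll_cap;
        double p = rate * dt * 1e-3;
        if (p > 1) p = 1;
        mf_spike[i] = (p > 0 && unif_rand() < p) ? 1 : 0;
        if (mf_spike[i]) logs[6].add(i, t);
      }
    }

    // integrate each dynamic population
    for (int k = 0; k < N_DYN; ++k) {
      Pop& P = pops[k];
      int ns = P.nslots();
      for (int s = 0; s < ns; ++s) {
        double dec = P.slot_decay[s], gain = P.slot_gain[s];
        double* g = &P.g[(size_t)s * P.n];
        double* pend = &P.pending[(size_t)s * P.n];
        for (int i = 0; i < P.n; ++i) {
          g[i] = g[i] * dec + gain * pend[i];
          pend[i] = 0.0;
        }
      }
      for (int i = 0; i < P.n; ++i) {
        double syn = 0.0, gsum = 0.0;
        for (int s = 0; s < ns; ++s) {
          double gv = P.g[(size_t)s * P.n + i];
          syn += gv * P.slot_e[s];
          gsum += gv;
        }
        double V = P.V[i];
        V += dt * (P.gl * (P.el - V) + syn - V * gsum);
        if (!std::isfinite(V))
          stop("numerical failure in population %d neuron %d", k, i + 1);
        bool sp = V >= P.theta[i];
        P.theta[i] = P.th0 + (P.theta[i] - P.th0) * P.th_decay;
        if (sp) {
          P.theta[i] += P.dth;
          V = P.ereset;
          P.spiked[i] = 1;
          logs[k].add(i, t);
        } else {
          P.spiked[i] = 0;
        }
        P.V[i] = V;
      }
    }

    // smoothed DCN population rate (Hz) and trace
    {
      Pop& D = pops[5];
      int nsp = 0;
      for (int i = 0; i < D.n; ++i) nsp += D.spiked[i];
      double inst = 1000.0 * (double)nsp / (double)D.n; // Hz this ms
      dcn_smooth = dcn_smooth * dcn_decay + (1.0 - dcn_decay) * inst;
      dcn_trace[t] = dcn_smooth;
    }

    // queue this step's spikes for next-step delivery
    for (const Proj& pr : projs) {
      Pop& Tg = pops[pr.tgt_pop];
      double* pend = &Tg.pending[(size_t)pr.slot * Tg.n];
      if (pr.src_pop < N_DYN) {
        const Pop& S = pops[pr.src_pop];
        for (int i = 0; i < S.n; ++i) {
          if (!S.spiked[i]) continue;
          for (int e = pr.offset[i]; e < pr.offset[i + 1]; ++e)
            pend[pr.tgt[e]] += pr.w[e];
        }
      } else {
        const std::vector<int>& sp = (pr.src_pop == 6) ? mf_spike : cf_spike;
        int nsrc = (pr.src_pop == 6) ? n_mf : n_cf;
        for (int i = 0; i < nsrc; ++i) {
          if (!sp[i]) continue;
          for (int e = pr.offset[i]; e < pr.offset[i + 1]; ++e)
            pend[pr.tgt[e]] += pr.w[e];
        }
      }
    }
  }

  // repack state
  List state_out(N_DYN);
  for (int k = 0; k < N_DYN; ++k) {
    Pop& P = pops[k];
    int ns = P.nslots();
    NumericMatrix g(P.n, ns), pend(P.n, ns);
    for (int s = 0; s < ns; ++s)
      for (int i = 0; i < P.n; ++i) {
        g(i, s) = P.g[(size_t)s * P.n + i];
        pend(i, s) = P.pending[(size_t)s * P.n + i];
      }
    state_out[k] = List::create(_["V"] = wrap(P.V), _["theta"] = wrap(P.theta),
                                _["g"] = g, _["pending"] = pend);
  }

  List spikes(8);
  CharacterVector nm = CharacterVector::create("grc", "goc", "pc", "bc", "sc",
                                               "dcn", "mf", "cf");
  for (int k = 0; k < 8; ++k)
    spikes[k] = List::create(_["id"] = wrap(logs[k].id),
                             _["t"] = wrap(logs[k].t));
  spikes.attr("names") = nm;

  return List::create(_["spikes"] = spikes, _["state"] = state_out,
                      _["dcn_trace"] = dcn_trace,
                      _["dcn_smooth"] = dcn_smooth);
}
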