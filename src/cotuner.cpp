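#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Tsodyks-Markram short-term plasticity
// ---------------------------------------------------------------------------

// Per-spike synaptic efficacies for a set of spike trains (flattened).
// times are grouped by train via 0-based offsets (length n_trains + 1) and
// strictly increasing within a train. Depression-only when tau_facil <= 0.
// Efficacy of spike n is u_n * x_n in [0, 1]; it multiplies the unitary
// amplitude A. First spike of a train has efficacy U (full resources).
// [[Rcpp::export]]
NumericVector tm_efficacies_cpp(NumericVector times, IntegerVector offsets,
                                double U, double tau_rec, double tau_facil) {
  int n_trains = offsets.size() - 1;
  NumericVector eff(times.size());
  bool facil = tau_facil > 0.0;
  for (int tr = 0; tr < n_trains; ++tr) {
    double x = 1.0, u = U, t_last = R_NegInf;
    for (int k = offsets[tr]; k < offsets[tr + 1]; ++k) {
      double t = times[k];
      if (R_finite(t_last)) {
        double dt = t - t_last;
        if (dt <= 0) stop("spike times must be strictly increasing within a train");
        x = 1.0 - (1.0 - x) * std::exp(-dt / tau_rec);
        if (facil) {
          u = U + u * (1.0 - U) * std::exp(-dt / tau_facil);
        }
      }
      double e = u * x;
      eff[k] = e;
      x -= e;           // resources consumed by release
      t_last = t;
    }
  }
  return eff;
}

// ---------------------------------------------------------------------------
// Gaussian distance-dependent wiring
// ---------------------------------------------------------------------------

// Sample a directed adjacency from presynaptic cells at arbitrary coordinates
// onto a regular postsynaptic grid, with connection probability
// peak * exp(-d^2 / (2 sigma^2)). One Bernoulli draw per ordered pair within
// a cutoff of `cutoff_sd` standard deviations (tail mass beyond is negligible).
// `self_offset` >= 0 marks pre cell i as identical to post cell i + self_offset
// (self-connections excluded); use -1 when the populations are distinct.
// Returns 1-based pre/post index vectors.
// [[Rcpp::export]]
List sample_adjacency_cpp(NumericVector pre_x, NumericVector pre_y,
                          double post_x0, double post_y0, double post_pitch,
                          int post_nx, int post_ny,
                          double peak, double sigma, int self_offset,
                          double cutoff_sd) {
  RNGScope scope;
  std::vector<int> pre_out, post_out;
  double cut = cutoff_sd * sigma;
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  int npre = pre_x.size();
  for (int i = 0; i < npre; ++i) {
    double xi = pre_x[i], yi = pre_y[i];
    int ix0 = (int)std::floor((xi - cut - post_x0) / post_pitch);
    int ix1 = (int)std::ceil((xi + cut - post_x0) / post_pitch);
    int iy0 = (int)std::floor((yi - cut - post_y0) / post_pitch);
    int iy1 = (int)std::ceil((yi + cut - post_y0) / post_pitch);
    if (ix0 < 0) ix0 = 0; if (iy0 < 0) iy0 = 0;
    if (ix1 > post_nx - 1) ix1 = post_nx - 1;
    if (iy1 > post_ny - 1) iy1 = post_ny - 1;
    for (int iy = iy0; iy <= iy1; ++iy) {
      double dy = post_y0 + iy * post_pitch - yi;
      for (int ix = ix0; ix <= ix1; ++ix) {
        int j = iy * post_nx + ix;
        if (self_offset >= 0 && j == i + self_offset) continue;
        double dx = post_x0 + ix * post_pitch - xi;
        double d2 = dx * dx + dy * dy;
        if (d2 > cut * cut) continue;
        double p = peak * std::exp(-d2 * inv2s2);
        if (unif_rand() < p) {
          pre_out.push_back(i + 1);
          post_out.push_back(j + 1);
        }
      }
    }
  }
  return List::create(_["pre"] = wrap(pre_out), _["post"] = wrap(post_out));
}

// ---------------------------------------------------------------------------
// aEIF single neuron
// ---------------------------------------------------------------------------

struct Nrn {
  double C, gL, EL, VT, DT, a, tau_w, b, Vreset, Vcut, tref;
};

static Nrn as_nrn(const List& p) {
  Nrn n;
  n.C = p["C"]; n.gL = p["gL"]; n.EL = p["EL"]; n.VT = p["VT"];
  n.DT = p["DT"]; n.a = p["a"]; n.tau_w = p["tau_w"]; n.b = p["b"];
  n.Vreset = p["Vreset"]; n.Vcut = p["Vcut"]; n.tref = p["tref"];
  return n;
}

// exponential spike-initiation term, evaluated with V clamped at the cutoff
static inline double exp_term(const Nrn& n, double V) {
  double Ve = V > n.Vcut ? n.Vcut : V;
  return n.gL * n.DT * std::exp((Ve - n.VT) / n.DT);
}

// One forward-Euler step. state = (V, w, refr_ms). Returns spike flag.
static inline bool aeif_step(const Nrn& n, double dt, double I,
                             double& V, double& w, double& refr) {
  if (refr > 0.0) {
    refr -= dt;
    V = n.Vreset;
    w += dt * (n.a * (V - n.EL) - w) / n.tau_w;
    return false;
  }
  double dV = dt * (-n.gL * (V - n.EL) + exp_term(n, V) - w + I) / n.C;
  double dw = dt * (n.a * (V - n.EL) - w) / n.tau_w;
  V += dV;
  w += dw;
  if (V >= n.Vcut) {
    V = n.Vreset;
    w += n.b;
    refr = n.tref;
    return true;
  }
  return false;
}

// [[Rcpp::export]]
List aeif_step_cpp(List params, double V, double w, double refr,
                   double I, double dt) {
  Nrn n = as_nrn(params);
  bool sp = aeif_step(n, dt, I, V, w, refr);
  return List::create(_["V"] = V, _["w"] = w, _["refr"] = refr,
                      _["spike"] = sp);
}

// Clock-driven single-cell run with an arbitrary injected-current vector
// (pA, one value per step). Returns membrane trace and spike times.
// [[Rcpp::export]]
List simulate_cell_cpp(List params, NumericVector I, double dt) {
  Nrn n = as_nrn(params);
  int nstep = I.size();
  NumericVector V(nstep);
  std::vector<double> spikes;
  double v = n.EL, w = 0.0, refr = 0.0;
  for (int s = 0; s < nstep; ++s) {
    if (aeif_step(n, dt, I[s], v, w, refr)) spikes.push_back((s + 1) * dt);
    V[s] = v;
  }
  return List::create(_["V"] = V, _["spikes"] = wrap(spikes));
}

// ---------------------------------------------------------------------------
// Full-sheet network sweep
// ---------------------------------------------------------------------------

struct Syn {
  double A, tau, Erev, U, tau_rec, tau_facil, delay, scale;
};

static Syn as_syn(const List& p) {
  Syn s;
  s.A = p["A"]; s.tau = p["tau"]; s.Erev = p["Erev"]; s.U = p["U"];
  s.tau_rec = p["tau_rec"]; s.tau_facil = p["tau_facil"];
  s.delay = p["delay"]; s.scale = p["scale"];
  return s;
}

struct Pathway {
  Syn syn;
  const int* offsets;   // length npre + 1, 0-based
  const int* targets;   // 0-based post indices
  std::vector<double> x;      // TM resources per edge
  std::vector<double> u;      // TM utilization per edge
  std::vector<double> t_last; // last presynaptic spike per edge
  int delay_steps;
  std::vector< std::vector< std::pair<int, double> > > ring; // delayed events
};

static void init_pathway(Pathway& pw, const List& syn, const IntegerVector& off,
                         const IntegerVector& tgt, double dt) {
  pw.syn = as_syn(syn);
  pw.offsets = INTEGER(off);
  pw.targets = INTEGER(tgt);
  int ne = tgt.size();
  pw.x.assign(ne, 1.0);
  pw.u.assign(ne, pw.syn.U);
  pw.t_last.assign(ne, R_NegInf);
  pw.delay_steps = (int)std::max(1.0, std::round(pw.syn.delay / dt));
  pw.ring.assign(pw.delay_steps + 1, std::vector< std::pair<int, double> >());
}

// presynaptic spike of cell `pre` at time t: queue TM-scaled conductance
// increments onto all its targets
static void pre_spike(Pathway& pw, int pre, double t, int step) {
  bool facil = pw.syn.tau_facil > 0.0;
  int slot = (step + pw.delay_steps) % (pw.delay_steps + 1);
  for (int e = pw.offsets[pre]; e < pw.offsets[pre + 1]; ++e) {
    double& x = pw.x[e];
    double& u = pw.u[e];
    double& tl = pw.t_last[e];
    if (R_finite(tl)) {
      double d = t - tl;
      x = 1.0 - (1.0 - x) * std::exp(-d / pw.syn.tau_rec);
      if (facil) u = pw.syn.U + u * (1.0 - pw.syn.U) * std::exp(-d / pw.syn.tau_facil);
    }
    double eff = u * x;
    x -= eff;
    tl = t;
    pw.ring[slot].push_back(std::make_pair(pw.targets[e],
                                           eff * pw.syn.A * pw.syn.scale));
  }
}

// Run one sweep of the two-population sheet. Thalamic spikes are pre-realized
// (time-sorted, with TM efficacies already applied to their weights, in nS).
// Conductance traces onto P cells are accumulated (added) into acc_* matrices
// (nP x nrec) so repeated sweeps average cheaply on the R side.
// [[Rcpp::export]]
List run_sweep_cpp(int nP, int nFS,
                   List nrn_p, List nrn_fs,
                   List syn_pp, List syn_pfs, List syn_fsp,
                   IntegerVector pp_off, IntegerVector pp_tgt,
                   IntegerVector pfs_off, IntegerVector pfs_tgt,
                   IntegerVector fsp_off, IntegerVector fsp_tgt,
                   NumericVector thp_t, IntegerVector thp_cell, NumericVector thp_w,
                   double thp_tau, double thp_erev,
                   NumericVector thf_t, IntegerVector thf_cell, NumericVector thf_w,
                   double thf_tau, double thf_erev,
                   double dt, double duration,
                   double noise_p, double noise_fs,
                   int rec_every, double rec_tmax,
                   NumericMatrix acc_thal, NumericMatrix acc_rec, NumericMatrix acc_inh,
                   double rate_ceiling) {
  RNGScope scope;
  Nrn np = as_nrn(nrn_p), nf = as_nrn(nrn_fs);
  Pathway PP, PFS, FSP;
  init_pathway(PP, syn_pp, pp_off, pp_tgt, dt);
  init_pathway(PFS, syn_pfs, pfs_off, pfs_tgt, dt);
  init_pathway(FSP, syn_fsp, fsp_off, fsp_tgt, dt);

  int nstep = (int)std::round(duration / dt);
  int nrec = acc_thal.ncol();

  // membrane state
  std::vector<double> Vp(nP, np.EL), wp(nP, 0.0), rp(nP, 0.0);
  std::vector<double> Vf(nFS, nf.EL), wf(nFS, 0.0), rf(nFS, 0.0);

  // alpha-conductance state pairs (g, h) per postsynaptic cell per pathway
  std::vector<double> g_thp(nP, 0), h_thp(nP, 0);   // thal -> P
  std::vector<double> g_pp(nP, 0), h_pp(nP, 0);     // P -> P
  std::vector<double> g_fsp(nP, 0), h_fsp(nP, 0);   // FS -> P
  std::vector<double> g_thf(nFS, 0), h_thf(nFS, 0); // thal -> FS
  std::vector<double> g_pf(nFS, 0), h_pf(nFS, 0);   // P -> FS

  double dec_thp = std::exp(-dt / thp_tau), r_thp = dt / thp_tau;
  double dec_pp = std::exp(-dt / PP.syn.tau), r_pp = dt / PP.syn.tau;
  double dec_fsp = std::exp(-dt / FSP.syn.tau), r_fsp = dt / FSP.syn.tau;
  double dec_thf = std::exp(-dt / thf_tau), r_thf = dt / thf_tau;
  double dec_pf = std::exp(-dt / PFS.syn.tau), r_pf = dt / PFS.syn.tau;
  const double E = M_E;
  double inv_sqrt_dt = 1.0 / std::sqrt(dt);

  std::vector<double> sp_t_p, sp_t_f;
  std::vector<int> sp_c_p, sp_c_f;
  int thp_ptr = 0, thf_ptr = 0, n_thp = thp_t.size(), n_thf = thf_t.size();
  bool runaway = false;
  int ceiling_count = (int)(rate_ceiling * (nP + nFS) * dt / 1000.0) + 1;

  for (int s = 0; s < nstep; ++s) {
    double t = s * dt;

    // thalamic deliveries (events at times <= t)
    while (thp_ptr < n_thp && thp_t[thp_ptr] <= t + 1e-9) {
      h_thp[thp_cell[thp_ptr]] += thp_w[thp_ptr] * E;
      ++thp_ptr;
    }
    while (thf_ptr < n_thf && thf_t[thf_ptr] <= t + 1e-9) {
      h_thf[thf_cell[thf_ptr]] += thf_w[thf_ptr] * E;
      ++thf_ptr;
    }
    // delayed intracortical deliveries
    {
      int slot = s % (PP.delay_steps + 1);
      for (size_t k = 0; k < PP.ring[slot].size(); ++k)
        h_pp[PP.ring[slot][k].first] += PP.ring[slot][k].second * E;
      PP.ring[slot].clear();
      slot = s % (PFS.delay_steps + 1);
      for (size_t k = 0; k < PFS.ring[slot].size(); ++k)
        h_pf[PFS.ring[slot][k].first] += PFS.ring[slot][k].second * E;
      PFS.ring[slot].clear();
      slot = s % (FSP.delay_steps + 1);
      for (size_t k = 0; k < FSP.ring[slot].size(); ++k)
        h_fsp[FSP.ring[slot][k].first] += FSP.ring[slot][k].second * E;
      FSP.ring[slot].clear();
    }

    // record conductances (before update, at time t)
    if (rec_every > 0 && s % rec_every == 0 && t <= rec_tmax + 1e-9) {
      int col = s / rec_every;
      if (col < nrec) {
        for (int i = 0; i < nP; ++i) {
          acc_thal(i, col) += g_thp[i];
          acc_rec(i, col) += g_pp[i];
          acc_inh(i, col) += g_fsp[i];
        }
      }
    }

    int step_spikes = 0;
    // P population
    for (int i = 0; i < nP; ++i) {
      double I = g_thp[i] * (thp_erev - Vp[i]) + g_pp[i] * (PP.syn.Erev - Vp[i]) +
                 g_fsp[i] * (FSP.syn.Erev - Vp[i]);
      if (noise_p > 0) I += noise_p * norm_rand() * inv_sqrt_dt;
      if (aeif_step(np, dt, I, Vp[i], wp[i], rp[i])) {
        sp_t_p.push_back(t + dt);
        sp_c_p.push_back(i + 1);
        pre_spike(PP, i, t + dt, s);
        pre_spike(PFS, i, t + dt, s);
        ++step_spikes;
      }
      if (!R_finite(Vp[i]))
        stop("non-finite membrane potential (P cell %d at t = %.2f ms)", i + 1, t);
      // conductance decay
      double hp = h_thp[i];
      g_thp[i] = (g_thp[i] + hp * r_thp) * dec_thp; h_thp[i] = hp * dec_thp;
      hp = h_pp[i];
      g_pp[i] = (g_pp[i] + hp * r_pp) * dec_pp; h_pp[i] = hp * dec_pp;
      hp = h_fsp[i];
      g_fsp[i] = (g_fsp[i] + hp * r_fsp) * dec_fsp; h_fsp[i] = hp * dec_fsp;
    }
    // FS population
    for (int i = 0; i < nFS; ++i) {
      double I = g_thf[i] * (thf_erev - Vf[i]) + g_pf[i] * (PFS.syn.Erev - Vf[i]);
      if (noise_fs > 0) I += noise_fs * norm_rand() * inv_sqrt_dt;
      if (aeif_step(nf, dt, I, Vf[i], wf[i], rf[i])) {
        sp_t_f.push_back(t + dt);
        sp_c_f.push_back(i + 1);
        pre_spike(FSP, i, t + dt, s);
        ++step_spikes;
      }
      if (!R_finite(Vf[i]))
        stop("non-finite membrane potential (FS cell %d at t = %.2f ms)", i + 1, t);
      double hp = h_thf[i];
      g_thf[i] = (g_thf[i] + hp * r_thf) * dec_thf; h_thf[i] = hp * dec_thf;
      hp = h_pf[i];
      g_pf[i] = (g_pf[i] + hp * r_pf) * dec_pf; h_pf[i] = hp * dec_pf;
    }
    if (step_spikes > ceiling_count) runaway = true;
  }

  return List::create(_["p_t"] = wrap(sp_t_p), _["p_cell"] = wrap(sp_c_p),
                      _["fs_t"] = wrap(sp_t_f), _["fs_cell"] = wrap(sp_c_f),
                      _["runaway"] = runaway);
}
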