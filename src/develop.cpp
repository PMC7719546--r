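#include <Rcpp.h>
#include <vector>
#include <map>
using namespace Rcpp;

// Tau-leap development core.  Mirrors the regulatory algebra defined in
// R/development.R (effective_signal, site_occupancy, transcription_rate);
// the R functions are the tested reference for one step, this loop runs
// the full trajectory.

namespace {

struct Params {
  double tau, r_max, K0, lambda, tf_in, transl, d_m, d_p, k_P, K_hill;
  int tf_motif, n_steps;
};

Params read_params(List par) {
  Params p;
  p.tau = as<double>(par["tau"]);
  p.r_max = as<double>(par["r_max"]);
  p.K0 = as<double>(par["K0"]);
  p.lambda = as<double>(par["lambda_mismatch"]);
  p.tf_in = as<double>(par["basic_tf_input"]);
  p.tf_motif = as<int>(par["basic_tf_motif"]);
  p.transl = as<double>(par["translation_rate"]);
  p.d_m = as<double>(par["mrna_decay"]);
  p.d_p = as<double>(par["protein_decay"]);
  p.k_P = as<double>(par["k_P"]);
  p.K_hill = as<double>(par["K_hill"]);
  p.n_steps = as<int>(par["n_steps"]);
  return p;
}

// A genotype flattened for the inner loop, with per-site dissociation
// constants and per-motif regulator lists precomputed.
struct Prep {
  int n, n_sites;
  std::vector<int> kind, target;
  std::vector<int> site_motif;      // n_sites x n, column-major
  std::vector<double> site_effect;  // n_sites x n
  std::vector<double> inherent, phen_effect, hill_n;
  std::vector<double> Kd;           // K0 * lambda^mismatch per site
  std::vector<std::vector<int> > by_motif; // regulators per motif; n = basic TF
};

Prep prepare(List gt, const Params& p) {
  Prep g;
  g.n = as<int>(gt["n"]);
  IntegerVector kind = as<IntegerVector>(gt["kind"]);
  IntegerMatrix sm = as<IntegerMatrix>(gt["site_motif"]);
  NumericMatrix se = as<NumericMatrix>(gt["site_effect"]);
  IntegerMatrix sx = as<IntegerMatrix>(gt["site_mismatch"]);
  NumericVector inh = as<NumericVector>(gt["inherent"]);
  IntegerVector tg = as<IntegerVector>(gt["target"]);
  NumericVector pe = as<NumericVector>(gt["phen_effect"]);
  NumericVector hn = as<NumericVector>(gt["hill_n"]);
  g.n_sites = g.n > 0 ? sm.nrow() : 20;
  g.kind.assign(kind.begin(), kind.end());
  g.target.assign(tg.begin(), tg.end());
  g.site_motif.assign(sm.begin(), sm.end());
  g.site_effect.assign(se.begin(), se.end());
  g.inherent.assign(inh.begin(), inh.end());
  g.phen_effect.assign(pe.begin(), pe.end());
  g.hill_n.assign(hn.begin(), hn.end());
  g.Kd.resize(g.n_sites * g.n);
  for (int j = 0; j < g.n; ++j)
    for (int b = 0; b < g.n_sites; ++b)
      g.Kd[j * g.n_sites + b] = p.K0 * std::pow(p.lambda, sx(b, j));
  g.by_motif.assign(20, std::vector<int>());
  for (int i = 0; i < g.n; ++i) g.by_motif[g.target[i]].push_back(i);
  g.by_motif[p.tf_motif].push_back(g.n);
  return g;
}

struct State {
  std::vector<double> m, p;
  double tf, S, P;
};

inline double hill(double S, double n, double K) {
  if (S <= 0.0) return 0.0;
  return 1.0 / (1.0 + std::pow(K / S, n));
}

// One full development; optionally records the state every record_every
// steps into traj (row-major rows of length 2n + 4).
void run_dev(const Prep& g, const Params& par, int mode, double Pe,
             State& st, int record_every, std::vector<double>* traj) {
  const int n = g.n;
  st.m.assign(n, 0.0);
  st.p.assign(n, 0.0);
  st.tf = 0.0; st.S = 0.0; st.P = 0.0;
  std::vector<double> X(n + 1), rate(n);

  for (int step = 0; step <= par.n_steps; ++step) {
    if (traj && (step % record_every == 0)) {
      traj->push_back(step * par.tau);
      for (int i = 0; i < n; ++i) traj->push_back(st.m[i]);
      for (int i = 0; i < n; ++i) traj->push_back(st.p[i]);
      traj->push_back(st.tf);
      traj->push_back(st.S);
      traj->push_back(st.P);
    }
    if (step == par.n_steps) break;

    // effective regulator copy numbers from the state at step start
    for (int i = 0; i < n; ++i)
      X[i] = (g.kind[i] == 2) ? hill(st.S, g.hill_n[i], par.K_hill) * st.p[i]
                              : st.p[i];
    X[n] = st.tf;

    // transcription rates
    for (int j = 0; j < n; ++j) {
      double A = 0.0, R = 0.0;
      const int* motif = &g.site_motif[j * g.n_sites];
      const double* ce = &g.site_effect[j * g.n_sites];
      const double* kd = &g.Kd[j * g.n_sites];
      for (int b = 0; b < g.n_sites; ++b) {
        if (ce[b] == 0.0) continue;
        const std::vector<int>& regs = g.by_motif[motif[b]];
        for (size_t k = 0; k < regs.size(); ++k) {
          const int r = regs[k];
          const double x = X[r];
          if (x <= 0.0) continue;
          const double theta = x / (x + kd[b]);
          const double s = ce[b] * ((r == n) ? 1.0 : g.inherent[r]) * theta;
          if (s > 0.0) A += s; else R -= s;
        }
      }
      rate[j] = (A > 0.0) ? par.r_max * A / (1.0 + A + R) : 0.0;
    }

    // deterministic phenotype growth from counts at step start
    double growth = 0.0;
    for (int i = 0; i < n; ++i)
      if (g.kind[i] == 1) growth += st.p[i] * g.phen_effect[i];
    st.P += par.tau * par.k_P * growth;

    // Poisson channel updates, simultaneous, clamped at zero
    for (int j = 0; j < n; ++j) {
      double dm = 0.0, dp = 0.0;
      if (rate[j] > 0.0) dm += R::rpois(rate[j] * par.tau);
      if (st.m[j] > 0.0) {
        dp += R::rpois(par.transl * st.m[j] * par.tau);
        dm -= R::rpois(par.d_m * st.m[j] * par.tau);
      }
      if (st.p[j] > 0.0) dp -= R::rpois(par.d_p * st.p[j] * par.tau);
      st.m[j] += dm; if (st.m[j] < 0.0) st.m[j] = 0.0;
      st.p[j] += dp; if (st.p[j] < 0.0) st.p[j] = 0.0;
    }
    {
      double dtf = 0.0;
      if (par.tf_in > 0.0) dtf += R::rpois(par.tf_in * par.tau);
      if (st.tf > 0.0) dtf -= R::rpois(par.d_p * st.tf * par.tau);
      st.tf += dtf; if (st.tf < 0.0) st.tf = 0.0;
    }
    if (mode != 0) {
      const double s_rate = (mode == 1) ? Pe : std::fabs(st.P - Pe);
      double dS = 0.0;
      if (s_rate > 0.0) dS += R::rpois(s_rate * par.tau);
      if (st.S > 0.0) dS -= R::rpois(par.d_p * st.S * par.tau);
      st.S += dS; if (st.S < 0.0) st.S = 0.0;
    }
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_develop(List gt, int mode, double Pe, int n_reps, List par,
                 int record_every) {
  const Params p = read_params(par);
  const Prep g = prepare(gt, p);
  NumericVector phen_out(n_reps), tf_out(n_reps), sig_out(n_reps);
  NumericMatrix mrna_out(g.n, n_reps), prot_out(g.n, n_reps);
  const bool record = record_every > 0 && n_reps == 1;
  std::vector<double> traj;
  State st;
  for (int rep = 0; rep < n_reps; ++rep) {
    run_dev(g, p, mode, Pe, st, record_every, record ? &traj : NULL);
    phen_out[rep] = st.P;
    tf_out[rep] = st.tf;
    sig_out[rep] = st.S;
    for (int i = 0; i < g.n; ++i) {
      mrna_out(i, rep) = st.m[i];
      prot_out(i, rep) = st.p[i];
    }
  }
  List out = List::create(
    _["phenotype"] = phen_out, _["mrna"] = mrna_out, _["protein"] = prot_out,
    _["basic_tf"] = tf_out, _["signal"] = sig_out);
  if (record) {
    const int ncol = 2 * g.n + 4;
    const int nrow = traj.size() / ncol;
    NumericMatrix tm(nrow, ncol);
    for (int r = 0; r < nrow; ++r)
      for (int c = 0; c < ncol; ++c) tm(r, c) = traj[r * ncol + c];
    out["trajectory"] = tm;
  }
  return out;
}

// Develop every individual of a population once; compiled genotypes are
// prepared once per distinct object (clones share the R object).
// [[Rcpp::export]]
NumericVector cpp_develop_population(List pop, int mode, NumericVector Pe,
                                     List par) {
  const Params p = read_params(par);
  const int N = pop.size();
  NumericVector out(N);
  std::map<SEXP, int> seen;
  std::vector<Prep> preps;
  State st;
  for (int i = 0; i < N; ++i) {
    SEXP gi = pop[i];
    std::map<SEXP, int>::iterator it = seen.find(gi);
    int idx;
    if (it == seen.end()) {
      preps.push_back(prepare(List(gi), p));
      idx = (int)preps.size() - 1;
      seen[gi] = idx;
    } else {
      idx = it->second;
    }
    run_dev(preps[idx], p, mode, Pe[i], st, 0, NULL);
    out[i] = st.P;
  }
  return out;
}

// Per-gene transcription rates for a given state; used to cross-check the
// compiled regulatory algebra against the R reference implementation.
// [[Rcpp::export]]
NumericVector cpp_transcription_rates(List gt, NumericVector protein,
                                      double basic_tf, double signal,
                                      List par) {
  const Params p = read_params(par);
  const Prep g = prepare(gt, p);
  const int n = g.n;
  std::vector<double> X(n + 1);
  for (int i = 0; i < n; ++i)
    X[i] = (g.kind[i] == 2) ? hill(signal, g.hill_n[i], p.K_hill) * protein[i]
                            : protein[i];
  X[n] = basic_tf;
  NumericVector rate(n);
  for (int j = 0; j < n; ++j) {
    double A = 0.0, R = 0.0;
    for (int b = 0; b < g.n_sites; ++b) {
      const std::vector<int>& regs = g.by_motif[g.site_motif[j * g.n_sites + b]];
      const double ce = g.site_effect[j * g.n_sites + b];
      const double kd = g.Kd[j * g.n_sites + b];
      for (size_t k = 0; k < regs.size(); ++k) {
        const int r = regs[k];
        if (X[r] <= 0.0) continue;
        const double theta = X[r] / (X[r] + kd);
        const double s = ce * ((r == n) ? 1.0 : g.inherent[r]) * theta;
        if (s > 0.0) A += s; else R -= s;
      }
    }
    rate[j] = (A > 0.0) ? p.r_max * A / (1.0 + A + R) : 0.0;
  }
  return rate;
}
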