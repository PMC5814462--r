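#include <Rcpp.h>
using namespace Rcpp;

// Asynchronous Monte Carlo loop for monotone weighted threshold dynamics.
//
// One sweep = N single-node updates; each update picks a node uniformly at
// random (with replacement) and time advances by 1/N. A susceptible node
// becomes infected spontaneously with probability p, or else adopts iff its
// partial strength q_m reaches phi * q_k (relative tie tolerance 1e-12).
// Nodes with zero strength (k = 0, or all incident weights 0 in the diluted
// limit) can only be infected spontaneously. Partial strengths are kept
// incrementally: infecting a node pushes its edge weights to neighbours.
//
// Uses R's RNG (seed via set.seed() before the call).
// [[Rcpp::export]]
List mc_core(IntegerVector from, IntegerVector to, NumericVector weight,
             IntegerVector etype, int n_types, int N,
             double phi, double p, double t_max, double sample_dt,
             double rho_stop, IntegerVector init_infected) {
  const int E = from.size();
  const double tol_rel = 1e-12;

  // CSR adjacency
  std::vector<int> deg(N, 0);
  for (int e = 0; e < E; ++e) { deg[from[e]]++; deg[to[e]]++; }
  std::vector<int> start(N + 1, 0);
  for (int v = 0; v < N; ++v) start[v + 1] = start[v] + deg[v];
  std::vector<int> nbr(2 * E), eid(2 * E), fill(N, 0);
  for (int e = 0; e < E; ++e) {
    int u = from[e], v = to[e];
    nbr[start[u] + fill[u]] = v; eid[start[u] + fill[u]] = e; fill[u]++;
    nbr[start[v] + fill[v]] = u; eid[start[v] + fill[v]] = e; fill[v]++;
  }

  std::vector<double> qk(N, 0.0), qm(N, 0.0);
  for (int e = 0; e < E; ++e) {
    qk[from[e]] += weight[e];
    qk[to[e]] += weight[e];
  }

  std::vector<char> infected(N, 0);
  std::vector<double> ii_cnt(n_types > 0 ? n_types : 1, 0.0);
  std::vector<double> si_cnt(n_types > 0 ? n_types : 1, 0.0);
  int n_inf = 0;

  // infect node v: update states, partial strengths, edge category counts
  auto infect = [&](int v) {
    infected[v] = 1; ++n_inf;
    for (int ptr = start[v]; ptr < start[v + 1]; ++ptr) {
      int u = nbr[ptr], e = eid[ptr];
      int tj = n_types > 0 ? etype[e] - 1 : 0;
      if (infected[u]) {
        if (n_types > 0) { ii_cnt[tj] += 1.0; si_cnt[tj] -= 1.0; }
      } else {
        qm[u] += weight[e];
        if (n_types > 0) si_cnt[tj] += 1.0;
      }
    }
  };

  auto satisfied = [&](int v) {
    return qk[v] > 0.0 && qm[v] >= phi * qk[v] - tol_rel * qk[v];
  };

  for (int i = 0; i < init_infected.size(); ++i) {
    int v = init_infected[i];
    if (!infected[v]) infect(v);
  }

  int max_samples = (int)(t_max / sample_dt) + 3;
  std::vector<double> s_t, s_rho;
  std::vector<std::vector<double>> s_ii(n_types), s_si(n_types);
  s_t.reserve(max_samples); s_rho.reserve(max_samples);

  auto record = [&](double t) {
    s_t.push_back(t);
    s_rho.push_back((double)n_inf / N);
    double ii_tot = 0.0, si_tot = 0.0;
    for (int j = 0; j < n_types; ++j) { ii_tot += ii_cnt[j]; si_tot += si_cnt[j]; }
    for (int j = 0; j < n_types; ++j) {
      s_ii[j].push_back(ii_tot > 0 ? ii_cnt[j] / ii_tot : NA_REAL);
      s_si[j].push_back(si_tot > 0 ? si_cnt[j] / si_tot : NA_REAL);
    }
  };

  double t = 0.0, next_sample = 0.0;
  record(0.0);
  next_sample += sample_dt;
  const double dt = 1.0 / N;
  bool stopped = false;
  long long sweep_checks = 0;

  while (!stopped) {
    for (int step = 0; step < N; ++step) {
      int v = (int)(unif_rand() * N);
      if (v == N) v = N - 1;
      if (!infected[v]) {
        bool doit = false;
        if (p > 0.0 && unif_rand() < p) doit = true;
        else if (satisfied(v)) doit = true;
        if (doit) infect(v);
      }
      t += dt;
      while (next_sample <= t + 1e-12 && next_sample <= t_max + 1e-12) {
        record(next_sample);
        next_sample += sample_dt;
      }
      if (n_inf == N || (double)n_inf / N >= rho_stop) { stopped = true; break; }
      if (t >= t_max - 1e-12) { stopped = true; break; }
    }
    ++sweep_checks;
    if (!stopped && p <= 0.0) {
      // frozen-state detection: no susceptible node can still adopt
      bool active = false;
      for (int v = 0; v < N && !active; ++v)
        if (!infected[v] && satisfied(v)) active = true;
      if (!active) stopped = true;
    }
    if (sweep_checks % 64 == 0) checkUserInterrupt();
  }
  if (s_t.back() < t - 1e-12) record(t);

  List out = List::create(
    _["times"] = wrap(s_t),
    _["rho"] = wrap(s_rho),
    _["final_state"] = IntegerVector(infected.begin(), infected.end()),
    _["t_end"] = t);
  if (n_types > 0) {
    NumericMatrix eii(s_t.size(), n_types), esi(s_t.size(), n_types);
    for (int j = 0; j < n_types; ++j)
      for (size_t i = 0; i < s_t.size(); ++i) {
        eii(i, j) = s_ii[j][i];
        esi(i, j) = s_si[j][i];
      }
    out["E_II"] = eii;
    out["E_SI"] = esi;
  }
  return out;
}
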