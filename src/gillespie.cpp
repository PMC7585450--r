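// Exact continuous-time (Gillespie) simulation of hypergraph SIS.
//
// Reaction channels:
//   * healing: every infected node at rate gamma;
//   * per size-m hyperedge, depending on the rule:
//       collective contagion: the single susceptible member is infected at
//         rate beta_m when the other m-1 members are all infected;
//       individual contagion: each susceptible member is infected at rate
//         beta_m when at least one other member is infected;
//       higher-order healing (size-3 only): the contagion action is replaced
//         by recovery of qualifying infected members at rate beta_3.
// Each class keeps an integer edge weight w(cnt) (number of eligible
// infection/recovery targets), an active-edge list, and an exact integer
// total weight, so channel rates are beta_m * W_m with no floating drift.
// Edge selection uses rejection on w/w_max within the active list.
//
// Uses R's RNG throughout: runs are reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct EdgeClass {
  int m;            // hyperedge size
  double beta;
  int mode;         // 0 coll-contagion, 1 ind-contagion, 2 coll-heal, 3 ind-heal
  int wmax;
  int E;
  std::vector<int> members;  // flat, m * E, 0-based node ids
  std::vector<int> cnt;      // infected members per edge
  std::vector<int> active;   // edges with w > 0
  std::vector<int> pos;      // index into active, -1 if inactive
  long long W = 0;           // sum of weights over edges

  int weight(int c) const {
    switch (mode) {
      case 0: return c == m - 1 ? 1 : 0;
      case 1: return c >= 1 ? m - c : 0;
      case 2: return c == m ? m : 0;
      case 3: return c >= 2 ? c : 0;
    }
    return 0;
  }
  void set_active(int e, int w_old, int w_new) {
    if (w_old == 0 && w_new > 0) {
      pos[e] = (int)active.size();
      active.push_back(e);
    } else if (w_old > 0 && w_new == 0) {
      int q = pos[e], last = active.back();
      active[q] = last; pos[last] = q;
      active.pop_back(); pos[e] = -1;
    }
    W += w_new - w_old;
  }
};

struct Engine {
  int n;
  double gamma;
  std::vector<EdgeClass> classes;
  std::vector<char> infected;
  std::vector<int> inf_list, inf_pos;     // infected set with O(1) removal
  // node -> incident (class, edge) pairs, CSR
  std::vector<int> inc_start, inc_class, inc_edge;

  int I() const { return (int)inf_list.size(); }

  void build(int n_, double gamma_, const List& edge_mats,
             const NumericVector& betas, int rule, bool healing) {
    n = n_; gamma = gamma_;
    int ncl = edge_mats.size();
    classes.resize(ncl);
    std::vector<int> deg(n, 0);
    for (int c = 0; c < ncl; ++c) {
      IntegerMatrix em = edge_mats[c];
      EdgeClass& ec = classes[c];
      ec.m = em.nrow(); ec.E = em.ncol(); ec.beta = betas[c];
      bool heal_here = healing && ec.m == 3;
      ec.mode = heal_here ? (rule == 0 ? 2 : 3) : (rule == 0 ? 0 : 1);
      ec.wmax = ec.mode == 0 ? 1 : (ec.mode == 1 ? ec.m - 1 : ec.m);
      ec.members.assign(em.begin(), em.end());
      for (auto& v : ec.members) --v;       // to 0-based
      ec.cnt.assign(ec.E, 0);
      ec.pos.assign(ec.E, -1);
      for (int e = 0; e < ec.E; ++e)
        for (int j = 0; j < ec.m; ++j) ++deg[ec.members[e * ec.m + j]];
    }
    inc_start.assign(n + 1, 0);
    for (int i = 0; i < n; ++i) inc_start[i + 1] = inc_start[i] + deg[i];
    inc_class.resize(inc_start[n]); inc_edge.resize(inc_start[n]);
    std::vector<int> fill(n, 0);
    for (int c = 0; c < (int)classes.size(); ++c) {
      EdgeClass& ec = classes[c];
      for (int e = 0; e < ec.E; ++e)
        for (int j = 0; j < ec.m; ++j) {
          int v = ec.members[e * ec.m + j];
          int slot = inc_start[v] + fill[v]++;
          inc_class[slot] = c; inc_edge[slot] = e;
        }
    }
    infected.assign(n, 0);
    inf_pos.assign(n, -1);
  }

  void set_state(const IntegerVector& inf0) {
    for (auto& ec : classes) {
      for (int e : ec.active) ec.pos[e] = -1;
      ec.active.clear();
      std::fill(ec.cnt.begin(), ec.cnt.end(), 0);
      ec.W = 0;
    }
    std::fill(infected.begin(), infected.end(), 0);
    std::fill(inf_pos.begin(), inf_pos.end(), -1);
    inf_list.clear();
    for (int idx = 0; idx < inf0.size(); ++idx) flip(inf0[idx] - 1);
  }

  void flip(int v) {
    int d;
    if (!infected[v]) {
      infected[v] = 1; d = 1;
      inf_pos[v] = (int)inf_list.size();
      inf_list.push_back(v);
    } else {
      infected[v] = 0; d = -1;
      int q = inf_pos[v], last = inf_list.back();
      inf_list[q] = last; inf_pos[last] = q;
      inf_list.pop_back(); inf_pos[v] = -1;
    }
    for (int s = inc_start[v]; s < inc_start[v + 1]; ++s) {
      EdgeClass& ec = classes[inc_class[s]];
      int e = inc_edge[s];
      int w_old = ec.weight(ec.cnt[e]);
      ec.cnt[e] += d;
      ec.set_active(e, w_old, ec.weight(ec.cnt[e]));
    }
  }

  double total_rate() const {
    double r = gamma * I();
    for (const auto& ec : classes) r += ec.beta * (double)ec.W;
    return r;
  }

  void fire_class(EdgeClass& ec) {
    int e = -1;
    for (;;) {
      int cand = ec.active[(int)(unif_rand() * ec.active.size())];
      int w = ec.weight(ec.cnt[cand]);
      if (unif_rand() * ec.wmax < w) { e = cand; break; }
    }
    bool want_susceptible = (ec.mode == 0 || ec.mode == 1);
    int n_targets = ec.weight(ec.cnt[e]);
    int pick = (int)(unif_rand() * n_targets);
    for (int j = 0; j < ec.m; ++j) {
      int v = ec.members[e * ec.m + j];
      bool match = want_susceptible ? !infected[v] : (bool)infected[v];
      if (match && pick-- == 0) { flip(v); break; }
    }
  }

  // execute one event (assumes total_rate() > 0)
  void execute_event(double R) {
    double u = unif_rand() * R;
    double hr = gamma * I();
    if (u < hr && I() > 0) {
      flip(inf_list[(int)(unif_rand() * I())]);
      return;
    }
    u -= hr;
    for (auto& ec : classes) {
      double rc = ec.beta * (double)ec.W;
      if (u < rc && !ec.active.empty()) { fire_class(ec); return; }
      u -= rc;
    }
    // floating-point residue: fire any live channel
    if (gamma > 0 && I() > 0) {
      flip(inf_list[(int)(unif_rand() * I())]);
      return;
    }
    for (auto& ec : classes)
      if (ec.beta > 0 && !ec.active.empty()) { fire_class(ec); return; }
  }
};

Engine make_engine(int n, const List& edge_mats, const NumericVector& betas,
                   double gamma, int rule, bool healing) {
  Engine eng;
  eng.build(n, gamma, edge_mats, betas, rule, healing);
  return eng;
}

} // namespace

// [[Rcpp::export]]
List cpp_gillespie(int n, List edge_mats, NumericVector betas, double gamma,
                   int rule, bool healing, IntegerVector infected0,
                   double t_end, double record_dt, double burnin,
                   bool event_log) {
  Engine eng = make_engine(n, edge_mats, betas, gamma, rule, healing);
  eng.set_state(infected0);

  std::vector<double> rec_t, rec_u, ev_t;
  std::vector<int> ev_i;
  double t = 0.0, rec_next = 0.0;
  double area = 0.0;                  // integral of I dt over [burnin, t_end]
  long long n_events = 0;

  RNGScope scope;
  for (;;) {
    int I_now = eng.I();
    double R = eng.total_rate();
    double t_event = (R > 0.0) ? t + exp_rand() / R : R_PosInf;
    double t_stop = std::min(t_event, t_end);
    while (rec_next <= t_stop + 1e-12 && rec_next <= t_end + 1e-12) {
      rec_t.push_back(rec_next);
      rec_u.push_back((double)I_now / n);
      rec_next += record_dt;
    }
    double a = std::max(t, burnin), b = std::max(t_stop, burnin);
    if (b > a) area += (double)I_now * (b - a);
    t = t_stop;
    if (t_event >= t_end) break;
    eng.execute_event(R);
    ++n_events;
    if (event_log) { ev_t.push_back(t); ev_i.push_back(eng.I()); }
    if (n_events % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  IntegerVector final_inf(eng.inf_list.size());
  for (size_t i = 0; i < eng.inf_list.size(); ++i)
    final_inf[i] = eng.inf_list[i] + 1;
  std::sort(final_inf.begin(), final_inf.end());
  double window = t_end - burnin;
  double u_mean = (window > 0.0) ? area / window / n : NA_REAL;
  return List::create(_["t"] = rec_t, _["U"] = rec_u,
                      _["u_mean"] = u_mean,
                      _["final_infected"] = final_inf,
                      _["n_events"] = (double)n_events,
                      _["event_t"] = ev_t, _["event_i"] = ev_i);
}

// Replicated first-event sampling on a fixed initial condition: returns the
// waiting time to the first event (t_max if none can occur) and the node
// whose state changed (0 if none).  Used by the exactness tests.
// [[Rcpp::export]]
List cpp_first_event(int n, List edge_mats, NumericVector betas, double gamma,
                     int rule, bool healing, IntegerVector infected0,
                     int n_rep, double t_max) {
  Engine eng = make_engine(n, edge_mats, betas, gamma, rule, healing);
  NumericVector times(n_rep);
  IntegerVector node(n_rep);
  RNGScope scope;
  for (int r = 0; r < n_rep; ++r) {
    eng.set_state(infected0);
    double R = eng.total_rate();
    if (R <= 0.0) { times[r] = t_max; node[r] = 0; continue; }
    double dt = exp_rand() / R;
    if (dt >= t_max) { times[r] = t_max; node[r] = 0; continue; }
    std::vector<char> before = eng.infected;
    eng.execute_event(R);
    times[r] = dt;
    node[r] = 0;
    for (int v = 0; v < n; ++v)
      if (eng.infected[v] != before[v]) { node[r] = v + 1; break; }
  }
  return List::create(_["t"] = times, _["node"] = node);
}
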