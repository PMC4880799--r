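#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Continuous-time (Gillespie) engine for two-headed loop-extruding factors
// (LEFs) on a 1D lattice of L sites, 1-based inclusive coordinates.
//
// Event kinds (integer codes shared with R):
//   1 step_left, 2 step_right, 3 dissociate, 4 rebind, 5 activate
//
// All randomness is drawn from R's RNG (unif_rand), so runs are reproducible
// under set.seed() on the R side.

namespace {

struct Engine {
  int L;
  int N;
  double v;
  double tau;
  bool coupled;
  bool explicit_exchange;
  double k_on;
  double activation_rate;

  std::vector<int> left, right;  // head positions, 0 when unbound
  std::vector<int> bound;        // 1 = bound to lattice
  std::vector<int> active;       // 0 = awaiting activation (gradual loading)
  std::vector<int> occ;          // occ[site] = lef index + 1, 0 = free; 1..L

  double t;

  // scratch rate table: for each LEF, rates of (move_left, move_right,
  // dissociate, bind, activate)
  std::vector<double> rate;

  Engine(int L_, int N_, double v_, double tau_, bool coupled_,
         bool explicit_exchange_, double k_on_, double activation_rate_)
      : L(L_), N(N_), v(v_), tau(tau_), coupled(coupled_),
        explicit_exchange(explicit_exchange_), k_on(k_on_),
        activation_rate(activation_rate_),
        left(N_, 0), right(N_, 0), bound(N_, 0), active(N_, 1),
        occ(L_ + 2, 0), t(0.0), rate(5 * N_, 0.0) {}

  double diss_rate() const {
    return std::isfinite(tau) ? 1.0 / tau : 0.0;
  }

  bool free_site(int s) const { return s >= 1 && s <= L && occ[s] == 0; }

  // Sample a free adjacent pair (i, i+1), i in 1..L-1: rejection sampling
  // capped at 1000 tries, then exhaustive enumeration. Returns -1 if none.
  int sample_free_pair() {
    for (int tries = 0; tries < 1000; ++tries) {
      int i = 1 + (int)std::floor(unif_rand() * (L - 1));
      if (i > L - 1) i = L - 1;
      if (occ[i] == 0 && occ[i + 1] == 0) return i;
    }
    std::vector<int> valid;
    for (int i = 1; i <= L - 1; ++i)
      if (occ[i] == 0 && occ[i + 1] == 0) valid.push_back(i);
    if (valid.empty()) return -1;
    int k = (int)std::floor(unif_rand() * valid.size());
    if (k >= (int)valid.size()) k = (int)valid.size() - 1;
    return valid[k];
  }

  void bind_at(int lef, int i) {
    left[lef] = i;
    right[lef] = i + 1;
    bound[lef] = 1;
    occ[i] = lef + 1;
    occ[i + 1] = lef + 1;
  }

  void unbind(int lef) {
    occ[left[lef]] = 0;
    occ[right[lef]] = 0;
    left[lef] = 0;
    right[lef] = 0;
    bound[lef] = 0;
  }

  // Fill the per-LEF rate table; returns the total propensity.
  double compute_rates() {
    double total = 0.0;
    const double dr = diss_rate();
    for (int i = 0; i < N; ++i) {
      double *r = &rate[5 * i];
      r[0] = r[1] = r[2] = r[3] = r[4] = 0.0;
      if (!active[i]) {
        r[4] = activation_rate;
      } else if (bound[i]) {
        bool lfree = free_site(left[i] - 1);
        bool rfree = free_site(right[i] + 1);
        if (coupled) {
          // both heads halt whenever either head is blocked
          r[0] = (lfree && rfree) ? v : 0.0;
          r[1] = r[0];
        } else {
          r[0] = lfree ? v : 0.0;
          r[1] = rfree ? v : 0.0;
        }
        r[2] = dr;
      } else {
        // unbound, explicit exchange pool
        r[3] = explicit_exchange ? k_on : 0.0;
      }
      total += r[0] + r[1] + r[2] + r[3] + r[4];
    }
    return total;
  }

  // Apply one event chosen with probability proportional to its rate.
  // Appends to the event log if recording. Returns the event kind applied.
  int apply_event(double total, bool record, std::vector<double> &ev) {
    double u = unif_rand() * total;
    double acc = 0.0;
    int lef = -1, slot = -1;
    for (int i = 0; i < N && lef < 0; ++i) {
      for (int s = 0; s < 5; ++s) {
        acc += rate[5 * i + s];
        if (u < acc) { lef = i; slot = s; break; }
      }
    }
    if (lef < 0) { lef = N - 1; slot = 2; }  // numerical guard

    int kind = 0;
    int ol = left[lef], orr = right[lef];
    switch (slot) {
      case 0: {  // left head steps left
        occ[left[lef]] = 0;
        left[lef] -= 1;
        occ[left[lef]] = lef + 1;
        kind = 1;
        break;
      }
      case 1: {  // right head steps right
        occ[right[lef]] = 0;
        right[lef] += 1;
        occ[right[lef]] = lef + 1;
        kind = 2;
        break;
      }
      case 2: {  // dissociation
        unbind(lef);
        kind = 3;
        if (!explicit_exchange) {
          // constant-N: immediate rebinding at a random free adjacent pair
          if (record) {
            ev.insert(ev.end(), {t, 3.0, (double)(lef + 1), (double)ol,
                                 (double)orr, 0.0, 0.0});
          }
          int i = sample_free_pair();
          if (i < 0)
            stop("rebinding failed: no free adjacent site pair on lattice "
                 "(L = %d, 2N = %d occupied head sites)", L, 2 * N);
          bind_at(lef, i);
          kind = 4;
          ol = 0; orr = 0;
        }
        break;
      }
      case 3: {  // binding from the free pool (explicit exchange)
        int i = sample_free_pair();
        if (i >= 0) bind_at(lef, i);  // else: no free pair, attempt is void
        kind = 4;
        break;
      }
      case 4: {  // activation
        active[lef] = 1;
        kind = 5;
        if (record) {
          ev.insert(ev.end(), {t, 5.0, (double)(lef + 1), 0.0, 0.0, 0.0, 0.0});
        }
        if (!explicit_exchange) {
          int i = sample_free_pair();
          if (i < 0)
            stop("activation binding failed: no free adjacent site pair "
                 "(L = %d)", L);
          bind_at(lef, i);
          kind = 4;
          ol = 0; orr = 0;
        } else {
          return 5;  // will bind later at rate k_on
        }
        break;
      }
    }
    if (record) {
      ev.insert(ev.end(), {t, (double)kind, (double)(lef + 1), (double)ol,
                           (double)orr, (double)left[lef], (double)right[lef]});
    }
    return kind;
  }

  void snapshot(std::vector<double> &snap) const {
    for (int i = 0; i < N; ++i) {
      snap.insert(snap.end(),
                  {t, (double)(i + 1), (double)left[i], (double)right[i],
                   (double)bound[i], (double)active[i]});
    }
  }
};

Engine make_engine(List params, IntegerVector left, IntegerVector right,
                   IntegerVector bound, IntegerVector active, double t0) {
  int L = as<int>(params["L"]);
  int N = as<int>(params["N"]);
  Engine e(L, N, as<double>(params["v"]), as<double>(params["tau"]),
           as<bool>(params["coupled_heads"]),
           as<std::string>(params["mode"]) == "explicit_exchange",
           as<double>(params["k_on"]), as<double>(params["activation_rate"]));
  e.t = t0;
  for (int i = 0; i < N; ++i) {
    e.bound[i] = bound[i];
    e.active[i] = active[i];
    if (bound[i]) {
      if (left[i] < 1 || right[i] > L || left[i] >= right[i])
        stop("invalid LEF %d: heads at (%d, %d) on lattice of %d sites",
             i + 1, left[i], right[i], L);
      if (e.occ[left[i]] || e.occ[right[i]])
        stop("invalid state: two LEF heads share a site");
      e.left[i] = left[i];
      e.right[i] = right[i];
      e.occ[left[i]] = i + 1;
      e.occ[right[i]] = i + 1;
    }
  }
  return e;
}

NumericMatrix to_matrix(const std::vector<double> &x, int ncol,
                        const CharacterVector &names) {
  int nrow = ncol > 0 ? (int)x.size() / ncol : 0;
  NumericMatrix m(nrow, ncol);
  for (int r = 0; r < nrow; ++r)
    for (int c = 0; c < ncol; ++c) m(r, c) = x[r * ncol + c];
  colnames(m) = names;
  return m;
}

}  // namespace

// [[Rcpp::export]]
List cpp_initialize(List params) {
  int L = as<int>(params["L"]);
  int N = as<int>(params["N"]);
  bool gradual = as<double>(params["activation_rate"]) > 0;
  Engine e(L, N, as<double>(params["v"]), as<double>(params["tau"]),
           as<bool>(params["coupled_heads"]),
           as<std::string>(params["mode"]) == "explicit_exchange",
           as<double>(params["k_on"]), as<double>(params["activation_rate"]));
  for (int i = 0; i < N; ++i) {
    if (gradual) {
      e.active[i] = 0;
      continue;
    }
    int s = e.sample_free_pair();
    if (s < 0)
      stop("cannot place %d LEFs on %d sites: no free adjacent pair left "
           "(density 2N/L = %.3f)", N, L, 2.0 * N / L);
    e.bind_at(i, s);
  }
  return List::create(_["left"] = wrap(e.left), _["right"] = wrap(e.right),
                      _["bound"] = wrap(e.bound), _["active"] = wrap(e.active));
}

// [[Rcpp::export]]
NumericMatrix cpp_propensities(List params, IntegerVector left,
                               IntegerVector right, IntegerVector bound,
                               IntegerVector active) {
  Engine e = make_engine(params, left, right, bound, active, 0.0);
  e.compute_rates();
  int N = e.N;
  NumericMatrix m(N, 5);
  for (int i = 0; i < N; ++i)
    for (int s = 0; s < 5; ++s) m(i, s) = e.rate[5 * i + s];
  colnames(m) = CharacterVector::create("step_left", "step_right",
                                        "dissociate", "rebind", "activate");
  return m;
}

// Run the Gillespie dynamics from the given state until t_max (or until
// max_events events have fired, if max_events > 0). Snapshots are taken at
// t0, t0 + dt, t0 + 2 dt, ... (dt = sample_interval); the state reported at a
// sample time is the state holding at that instant.
// [[Rcpp::export]]
List cpp_run(List params, IntegerVector left, IntegerVector right,
             IntegerVector bound, IntegerVector active, double t0,
             double t_max, double sample_interval, int max_events,
             bool record_events) {
  Engine e = make_engine(params, left, right, bound, active, t0);
  std::vector<double> snaps, evlog;
  snaps.reserve(6 * e.N * 64);

  double next_sample = t0;
  bool sampling = sample_interval > 0;
  if (sampling) {
    e.snapshot(snaps);
    next_sample = t0 + sample_interval;
  }

  long long n_events = 0;
  int last_kind = 0;
  while (e.t < t_max) {
    double total = e.compute_rates();
    if (total <= 0.0) {
      if (sampling) {
        while (next_sample <= t_max + 1e-12) {
          e.t = next_sample;
          e.snapshot(snaps);
          next_sample += sample_interval;
        }
      }
      e.t = t_max;
      break;
    }
    double dt = -std::log(unif_rand()) / total;
    double t_next = e.t + dt;
    if (sampling) {
      while (next_sample <= std::min(t_next, t_max) + 1e-12) {
        double t_save = e.t;
        e.t = next_sample;
        e.snapshot(snaps);
        e.t = t_save;
        next_sample += sample_interval;
      }
    }
    if (t_next >= t_max) {
      e.t = t_max;
      break;
    }
    e.t = t_next;
    last_kind = e.apply_event(total, record_events, evlog);
    if (++n_events % 65536 == 0) checkUserInterrupt();
    if (max_events > 0 && n_events >= max_events) break;
  }

  CharacterVector snap_cols = CharacterVector::create(
      "time", "lef_id", "left", "right", "bound", "active");
  CharacterVector ev_cols = CharacterVector::create(
      "time", "kind", "lef_id", "old_left", "old_right", "new_left",
      "new_right");
  return List::create(
      _["snapshots"] = to_matrix(snaps, 6, snap_cols),
      _["events"] = to_matrix(evlog, 7, ev_cols),
      _["left"] = wrap(e.left), _["right"] = wrap(e.right),
      _["bound"] = wrap(e.bound), _["active"] = wrap(e.active),
      _["time"] = e.t, _["n_events"] = (double)n_events,
      _["last_kind"] = last_kind);
}

// Parent of each interval in a properly nested/disjoint interval set.
// Inputs must be sorted by left ascending; returns 0 for roots, else the
// 1-based index (in sorted order) of the smallest enclosing interval.
// Crossing (partially overlapping) intervals are an error: the extrusion
// dynamics cannot produce them, so they indicate a corrupt state.
// [[Rcpp::export]]
IntegerVector cpp_nesting_parents(IntegerVector left, IntegerVector right) {
  int n = left.size();
  IntegerVector parent(n, 0);
  std::vector<int> stk;
  for (int i = 0; i < n; ++i) {
    if (i > 0 && left[i] <= left[i - 1])
      stop("intervals must be sorted by left head with distinct sites");
    while (!stk.empty() && right[stk.back()] < left[i]) stk.pop_back();
    if (!stk.empty()) {
      int p = stk.back();
      if (right[i] > right[p])
        stop("crossing intervals (%d,%d) and (%d,%d): not a valid loop "
             "configuration", left[p], right[p], left[i], right[i]);
      parent[i] = p + 1;
    }
    stk.push_back(i);
  }
  return parent;
}
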