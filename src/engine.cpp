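// Event-driven core: per-link renewal scheduler and the bounded-confidence
// opinion update loop. Per-link RNG sub-streams (splitmix64 seeded by a
// stable hash of master seed and link id) make event streams reproducible
// independently of queue iteration order.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>
#include <string>

using namespace Rcpp;

// ---- RNG: splitmix64 streams -------------------------------------------

static inline uint64_t sm64_next(uint64_t &s) {
  uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// uniform on the open interval (0,1), 53-bit resolution
static inline double u01(uint64_t &s) {
  return ((sm64_next(s) >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

// splitmix64 output scrambler as a stateless hash
static inline uint64_t mix64(uint64_t z) {
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// stable hash of (seed, stream id) -> initial stream state; the double
// scramble scatters states pseudo-randomly over the 2^64 orbit so distinct
// per-link streams never overlap in practice
static inline uint64_t stream_state(uint64_t seed, uint64_t id) {
  uint64_t s = (seed ^ 0xD1B54A32D192ED03ULL) + 0x9E3779B97F4A7C15ULL * (id + 1);
  return mix64(mix64(s));
}

// ---- scheduler ----------------------------------------------------------

struct Ev {
  double t;
  int link;
};
struct EvCmp {
  bool operator()(const Ev &a, const Ev &b) const {
    if (a.t != b.t) return a.t > b.t;
    return a.link > b.link; // ties broken by link id (earlier link first)
  }
};

class Scheduler {
public:
  int n_nodes;
  int family;   // 0 = exponential, 1 = log-normal
  int cap_mode; // 0 = dormant beyond horizon, 1 = truncated law
  double p1, p2; // rate b | (meanlog, sdlog)
  double tmax, cur_time, u_cap;
  long long delivered;
  std::vector<int> eu, evv; // 1-based endpoints per link
  std::vector<uint64_t> st; // per-link stream state
  std::priority_queue<Ev, std::vector<Ev>, EvCmp> pq;

  // inverse-CDF draw; in truncate mode the uniform is scaled by
  // P(dt <= tmax) so draws follow the conditional law exactly
  double draw_dt(int l) {
    double u = u01(st[l]);
    if (cap_mode == 1) u *= u_cap;
    if (family == 0) return -std::log1p(-u) / p1;
    return std::exp(p1 + p2 * R::qnorm(u, 0.0, 1.0, 1, 0));
  }

  Scheduler(const IntegerMatrix &edges, int n_nodes_, int family_,
            int cap_mode_, double p1_, double p2_, double init_mean,
            double init_sd, double tmax_, double seed)
      : n_nodes(n_nodes_), family(family_), cap_mode(cap_mode_), p1(p1_),
        p2(p2_), tmax(tmax_), cur_time(0.0), delivered(0) {
    if (family == 0)
      u_cap = -std::expm1(-p1 * tmax);
    else
      u_cap = R::pnorm((std::log(tmax) - p1) / p2, 0.0, 1.0, 1, 0);
    int E = edges.nrow();
    eu.resize(E);
    evv.resize(E);
    st.resize(E);
    uint64_t sd = (uint64_t)(int64_t)seed;
    for (int l = 0; l < E; ++l) {
      eu[l] = edges(l, 0);
      evv[l] = edges(l, 1);
      st[l] = stream_state(sd, (uint64_t)l);
      double t0;
      if (init_sd <= 0.0) {
        t0 = init_mean;
      } else {
        int guard = 0;
        do {
          t0 = init_mean + init_sd * R::qnorm(u01(st[l]), 0.0, 1.0, 1, 0);
        } while (t0 <= 0.0 && ++guard < 10000);
        if (t0 <= 0.0) t0 = init_mean;
      }
      if (cap_mode == 1 || t0 <= tmax) pq.push(Ev{t0, l});
    }
  }

  bool next(Ev &e) {
    if (pq.empty()) return false;
    e = pq.top();
    pq.pop();
    cur_time = e.t;
    ++delivered;
    double nt = e.t + draw_dt(e.link);
    // dormant mode: a link re-armed beyond the horizon never fires again
    if (cap_mode == 1 || nt <= tmax) pq.push(Ev{nt, e.link});
    return true;
  }
};

// [[Rcpp::export]]
SEXP sched_create(IntegerMatrix edges, int n_nodes, int family, int cap_mode,
                  double p1, double p2, double init_mean, double init_sd,
                  double tmax, double seed) {
  XPtr<Scheduler> p(new Scheduler(edges, n_nodes, family, cap_mode, p1, p2,
                                  init_mean, init_sd, tmax, seed),
                    true);
  return p;
}

// pop up to n events; returns fewer if the queue exhausts first
// [[Rcpp::export]]
List sched_pop(SEXP ptr, int n) {
  XPtr<Scheduler> s(ptr);
  std::vector<double> t;
  std::vector<int> u, v;
  t.reserve(n);
  u.reserve(n);
  v.reserve(n);
  Ev e;
  for (int i = 0; i < n; ++i) {
    if (!s->next(e)) break;
    t.push_back(e.t);
    u.push_back(s->eu[e.link]);
    v.push_back(s->evv[e.link]);
    if ((i & 0xFFFF) == 0xFFFF) Rcpp::checkUserInterrupt();
  }
  return List::create(_["time"] = wrap(t), _["u"] = wrap(u), _["v"] = wrap(v));
}

// advance, discarding events; returns the number actually discarded
// [[Rcpp::export]]
double sched_discard(SEXP ptr, double n) {
  XPtr<Scheduler> s(ptr);
  Ev e;
  double done = 0;
  while (done < n) {
    if (!s->next(e)) break;
    ++done;
    if (((long long)done & 0xFFFFF) == 0xFFFFF) Rcpp::checkUserInterrupt();
  }
  return done;
}

// [[Rcpp::export]]
List sched_state(SEXP ptr) {
  XPtr<Scheduler> s(ptr);
  return List::create(_["pending"] = (double)s->pq.size(),
                      _["current_time"] = s->cur_time,
                      _["delivered"] = (double)s->delivered);
}

// ---- opinion update -----------------------------------------------------

// success = gate open AND at least one opinion actually changes
static inline bool attempt(std::vector<double> &x, int i, int j, double d,
                           double mu) {
  double xi = x[i], xj = x[j];
  if (std::fabs(xi - xj) >= d) return false;
  double ni = xi + mu * (xj - xi);
  double nj = xj + mu * (xi - xj);
  if (ni == xi && nj == xj) return false;
  x[i] = ni;
  x[j] = nj;
  return true;
}

static List result_list(const std::vector<double> &x, double tf,
                        double events, double succ, double ev_stable,
                        const std::string &reason,
                        const std::vector<double> &rec_t,
                        const std::vector<double> &rec_x, int n_nodes) {
  List out = List::create(
      _["opinions"] = wrap(x), _["t_f"] = tf, _["events"] = events,
      _["successes"] = succ, _["events_to_stable"] = ev_stable,
      _["termination"] = reason);
  if (!rec_t.empty()) {
    NumericMatrix snap((int)rec_t.size(), n_nodes);
    for (size_t r = 0; r < rec_t.size(); ++r)
      for (int c = 0; c < n_nodes; ++c)
        snap((int)r, c) = rec_x[r * n_nodes + c];
    out["trajectory_times"] = wrap(rec_t);
    out["trajectory"] = snap;
  }
  return out;
}

// stop_unit: 0 = window counts consecutive failed activations,
//            1 = window is a duration in continuous time with no success
// [[Rcpp::export]]
List run_temporal_cpp(SEXP ptr, NumericVector x0, double d, double mu,
                      double stop_window, int stop_unit, double max_events,
                      double max_time, double record_every) {
  XPtr<Scheduler> s(ptr);
  std::vector<double> x(x0.begin(), x0.end());
  int n = (int)x.size();
  double events = 0, succ = 0, fails = 0, ev_stable = 0, tf = 0;
  double t_start = s->cur_time;
  double t_ref = s->cur_time; // last success (or dynamics start) time
  std::string reason = "exhausted";
  std::vector<double> rec_t, rec_x;
  double rec_count = 0;
  Ev e;
  for (;;) {
    if (events >= max_events) {
      reason = "max_events";
      break;
    }
    if (!s->pq.empty() && s->pq.top().t - t_start > max_time) {
      // simulation horizon: no activation beyond it is processed
      reason = "horizon";
      break;
    }
    if (stop_unit == 1 && !s->pq.empty() &&
        s->pq.top().t - t_ref >= stop_window) {
      // the quiet window elapses before the next activation arrives
      reason = "converged";
      break;
    }
    if (!s->next(e)) {
      reason = "exhausted";
      break;
    }
    events += 1;
    bool ok = attempt(x, s->eu[e.link] - 1, s->evv[e.link] - 1, d, mu);
    if (ok) {
      succ += 1;
      fails = 0;
      tf = e.t;
      ev_stable = events;
      t_ref = e.t;
    } else if (stop_unit == 0 && ++fails >= stop_window) {
      reason = "converged";
      break;
    }
    if (record_every > 0 && ++rec_count >= record_every) {
      rec_count = 0;
      rec_t.push_back(e.t);
      rec_x.insert(rec_x.end(), x.begin(), x.end());
    }
    if (((long long)events & 0xFFFF) == 0xFFFF) Rcpp::checkUserInterrupt();
  }
  return result_list(x, tf, events, succ, ev_stable, reason, rec_t, rec_x, n);
}

// static baseline: one uniformly chosen edge per discrete step
// [[Rcpp::export]]
List run_static_cpp(IntegerMatrix edges, NumericVector x0, double d, double mu,
                    double stop_window, double max_steps, double seed,
                    double record_every) {
  std::vector<double> x(x0.begin(), x0.end());
  int n = (int)x.size(), E = edges.nrow();
  uint64_t st = stream_state((uint64_t)(int64_t)seed, 0x5EEDULL);
  double steps = 0, succ = 0, fails = 0, ev_stable = 0, tf = 0;
  std::string reason = "max_steps";
  std::vector<double> rec_t, rec_x;
  double rec_count = 0;
  for (;;) {
    if (steps >= max_steps) {
      reason = "max_steps";
      break;
    }
    steps += 1;
    int l = (int)(u01(st) * E);
    if (l >= E) l = E - 1;
    bool ok = attempt(x, edges(l, 0) - 1, edges(l, 1) - 1, d, mu);
    if (ok) {
      succ += 1;
      fails = 0;
      tf = steps;
      ev_stable = steps;
    } else if (++fails >= stop_window) {
      reason = "converged";
      break;
    }
    if (record_every > 0 && ++rec_count >= record_every) {
      rec_count = 0;
      rec_t.push_back(steps);
      rec_x.insert(rec_x.end(), x.begin(), x.end());
    }
    if (((long long)steps & 0xFFFF) == 0xFFFF) Rcpp::checkUserInterrupt();
  }
  return result_list(x, tf, steps, succ, ev_stable, reason, rec_t, rec_x, n);
}

// replay a fixed, chronologically ordered activation stream
// [[Rcpp::export]]
List run_replay_cpp(NumericVector time, IntegerVector u, IntegerVector v,
                    NumericVector x0, double d, double mu, double stop_window) {
  std::vector<double> x(x0.begin(), x0.end());
  int n = (int)x.size();
  double events = 0, succ = 0, fails = 0, ev_stable = 0, tf = 0;
  std::string reason = "stream_end";
  std::vector<double> rec_t, rec_x;
  for (int k = 0; k < time.size(); ++k) {
    if (k > 0 && time[k] < time[k - 1])
      stop("replay stream is not chronologically ordered at row %d", k + 1);
    events += 1;
    bool ok = attempt(x, u[k] - 1, v[k] - 1, d, mu);
    if (ok) {
      succ += 1;
      fails = 0;
      tf = time[k];
      ev_stable = events;
    } else if (++fails >= stop_window) {
      reason = "converged";
      break;
    }
  }
  return result_list(x, tf, events, succ, ev_stable, reason, rec_t, rec_x, n);
}
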