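#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// l-TASEP lattice with extended particles.
//
// Conventions (shared by both simulators):
//  * A ribosome with A-site at codon i covers codons i .. i+L-1 (cover
//    truncated at S, so footprints may hang over the 3' end).
//  * Initiation (rate k0) is enabled iff codons 1..L are all uncovered,
//    i.e. the 5'-most A-site is > L (or the lattice is empty).
//  * Elongation i -> i+1 (rate k[i]) is enabled iff codon i+L is uncovered;
//    always enabled when i+L > S. Blocking requires the next A-site to be
//    exactly L away, so the check is pos[j+1] - pos[j] > L.
//  * The ribosome at codon S detaches (termination) with rate k[S].
//  * Residence time is credited to the A-site position only.
//
// Positions are kept sorted ascending (pos.front() = 5'-most ribosome).

struct LatticeSim {
  const std::vector<double>& k;   // site rates, k[0] is codon 1
  double k0;
  int S, L;
  std::vector<int> pos;           // A-site positions, 1-based, ascending
  double k_total;                 // k0 + sum of occupied-site rates
  bool check_exclusion;

  LatticeSim(const std::vector<double>& k_, double k0_, int S_, int L_,
             bool check_)
    : k(k_), k0(k0_), S(S_), L(L_), k_total(k0_), check_exclusion(check_) {}

  inline bool init_enabled() const {
    return pos.empty() || pos.front() > L;
  }
  // enabled state-changing rate; fills which events are enabled
  // ev index: 0 = initiation, j+1 = ribosome j (elongation or termination)
  double enabled_rate(std::vector<int>& ev, std::vector<double>& evr) const {
    ev.clear(); evr.clear();
    double kp = 0.0;
    if (k0 > 0 && init_enabled()) { ev.push_back(0); evr.push_back(k0); kp += k0; }
    const int m = (int) pos.size();
    for (int j = 0; j < m; ++j) {
      bool ok;
      if (j == m - 1) ok = true;                 // lead: move or terminate
      else ok = (pos[j + 1] - pos[j] > L);
      if (ok) {
        double r = k[pos[j] - 1];
        ev.push_back(j + 1); evr.push_back(r); kp += r;
      }
    }
    return kp;
  }
  // returns true if the event was a termination
  bool execute(int ev) {
    if (ev == 0) {
      pos.insert(pos.begin(), 1);
      k_total += k[0];
    } else {
      int j = ev - 1;
      if (pos[j] == S) {                         // termination
        k_total -= k[S - 1];
        pos.erase(pos.begin() + j);
        return true;
      }
      k_total += k[pos[j]] - k[pos[j] - 1];
      pos[j] += 1;
    }
    if (check_exclusion) {
      for (size_t j = 1; j < pos.size(); ++j)
        if (pos[j] - pos[j - 1] < L)
          stop("exclusion violated: A-sites closer than L");
    }
    return false;
  }
};

static inline double seg_mean(const std::vector<double>& Ti, double T,
                              int l, int r) {
  double s = 0.0;
  for (int i = l; i <= r; ++i) s += Ti[i - 1];
  return s / ((r - l + 1) * T);
}

// Shared convergence monitor: segment averages compared between checks.
struct Monitor {
  const std::vector<int>& seg_l, & seg_r;
  std::vector<double> prev;
  bool have_prev = false;
  Monitor(const std::vector<int>& l_, const std::vector<int>& r_)
    : seg_l(l_), seg_r(r_) {}
  // returns true when max |change| < eps
  bool check(const std::vector<double>& Ti, double T, double eps) {
    if (T <= 0) return false;
    std::vector<double> cur(seg_l.size());
    for (size_t s = 0; s < seg_l.size(); ++s)
      cur[s] = seg_mean(Ti, T, seg_l[s], seg_r[s]);
    bool conv = false;
    if (have_prev) {
      double mx = 0.0;
      for (size_t s = 0; s < cur.size(); ++s)
        mx = std::max(mx, std::fabs(cur[s] - prev[s]));
      conv = (mx < eps);
    }
    prev = cur; have_prev = true;
    return conv;
  }
};

// [[Rcpp::export]]
List tasep_simulate_cpp(NumericVector site_rates, double k0, int L,
                        int burn_in_terminations, double max_burn_events,
                        double max_steps, double first_check_step,
                        double check_interval, double epsilon,
                        IntegerVector seg_l, IntegerVector seg_r,
                        bool check_exclusion = false) {
  const int S = site_rates.size();
  std::vector<double> k(site_rates.begin(), site_rates.end());
  std::vector<int> sl(seg_l.begin(), seg_l.end());
  std::vector<int> sr(seg_r.begin(), seg_r.end());
  LatticeSim sim(k, k0, S, L, check_exclusion);
  Monitor mon(sl, sr);

  std::vector<double> Ti(S, 0.0);
  double T = 0.0, steps = 0.0, attempts = 0.0;
  long long F = 0;
  bool converged = false;

  std::vector<int> ev; std::vector<double> evr;
  ev.reserve(S / L + 2); evr.reserve(S / L + 2);

  long long burn_F = 0;
  double burn_events = 0.0;
  bool burning = burn_in_terminations > 0;
  double next_check = first_check_step;

  while (true) {
    double kp = sim.enabled_rate(ev, evr);
    if (kp <= 0.0 || sim.k_total <= 0.0) break;   // absorbing (k0 = 0, empty)
    double p_plus = kp / sim.k_total;
    if (p_plus > 1.0) p_plus = 1.0;
    // number of attempted events until the state-changing one (support 1,2,...)
    double e = 1.0;
    if (p_plus < 1.0) {
      double u = unif_rand();
      e = std::floor(std::log(u) / std::log1p(-p_plus)) + 1.0;
      if (e < 1.0) e = 1.0;
    }
    double dt = R::rgamma(e, 1.0 / sim.k_total);  // Erlang(shape e, rate k)
    // credit residence time of the pre-event state
    T += dt;
    for (size_t j = 0; j < sim.pos.size(); ++j) Ti[sim.pos[j] - 1] += dt;
    // draw the executed event among enabled ones, prob proportional to rate
    double u2 = unif_rand() * kp, acc = 0.0;
    int chosen = ev.back();
    for (size_t j = 0; j < ev.size(); ++j) {
      acc += evr[j];
      if (u2 <= acc) { chosen = ev[j]; break; }
    }
    bool term = sim.execute(chosen);
    if (term) ++F;
    steps += 1.0;
    attempts += e;

    if (burning) {
      if (term) ++burn_F;
      burn_events += 1.0;
      if (burn_F >= burn_in_terminations || burn_events >= max_burn_events) {
        // reset statistics, keep the lattice configuration
        std::fill(Ti.begin(), Ti.end(), 0.0);
        T = 0.0; F = 0; steps = 0.0; attempts = 0.0;
        burning = false;
      }
      continue;
    }
    if (steps >= next_check) {
      if (mon.check(Ti, T, epsilon)) { converged = true; break; }
      next_check += check_interval;
    }
    if (steps >= max_steps) break;
  }

  NumericVector n(S);
  for (int i = 0; i < S; ++i) n[i] = (T > 0) ? Ti[i] / T : 0.0;
  double J = (T > 0) ? (double) F / T : 0.0;
  return List::create(_["n"] = n, _["J"] = J, _["T"] = T,
                      _["F"] = (double) F, _["steps"] = steps,
                      _["attempts"] = attempts, _["converged"] = converged);
}

// Naive rejection scheme: every attempted event (enabled or blocked) is an
// explicit step with Exp(k_total) waiting time; blocked events advance time
// without changing state. Kept deliberately independent of the accelerated
// scheme above: it serves as its simulation oracle.
// [[Rcpp::export]]
List tasep_simulate_reject_cpp(NumericVector site_rates, double k0, int L,
                               int burn_in_terminations, double max_burn_events,
                               double max_attempts, double first_check_attempt,
                               double check_interval, double epsilon,
                               IntegerVector seg_l, IntegerVector seg_r) {
  const int S = site_rates.size();
  std::vector<double> k(site_rates.begin(), site_rates.end());
  std::vector<int> sl(seg_l.begin(), seg_l.end());
  std::vector<int> sr(seg_r.begin(), seg_r.end());
  std::vector<int> pos;                 // ascending A-site positions
  std::vector<double> Ti(S, 0.0);
  double T = 0.0, attempts = 0.0, steps = 0.0;
  long long F = 0;
  bool converged = false;
  Monitor mon(sl, sr);

  long long burn_F = 0;
  double burn_events = 0.0;
  bool burning = burn_in_terminations > 0;
  double next_check = first_check_attempt;

  while (true) {
    double k_total = k0;
    for (size_t j = 0; j < pos.size(); ++j) k_total += k[pos[j] - 1];
    if (k_total <= 0.0) break;
    double dt = R::exp_rand() / k_total;
    T += dt;
    for (size_t j = 0; j < pos.size(); ++j) Ti[pos[j] - 1] += dt;
    // categorical draw over ALL attemptable events (o_0 = 1 for initiation)
    double u = unif_rand() * k_total, acc = k0;
    int who = -1;                       // -1 = initiation attempt
    if (u > acc) {
      for (size_t j = 0; j < pos.size(); ++j) {
        acc += k[pos[j] - 1];
        if (u <= acc) { who = (int) j; break; }
      }
      if (who < 0) who = (int) pos.size() - 1;   // numeric guard
    }
    attempts += 1.0;
    bool term = false, changed = false;
    if (who < 0) {                       // initiation attempt
      if (pos.empty() || pos.front() > L) {
        pos.insert(pos.begin(), 1);
        changed = true;
      }
    } else if (pos[who] == S) {          // termination
      pos.erase(pos.begin() + who);
      term = true; changed = true;
    } else {
      bool lead = (who == (int) pos.size() - 1);
      if (lead || pos[who + 1] - pos[who] > L) {
        pos[who] += 1;
        changed = true;
      }
    }
    if (changed) steps += 1.0;
    if (term) ++F;

    if (burning) {
      if (term) ++burn_F;
      burn_events += 1.0;
      if (burn_F >= burn_in_terminations || burn_events >= max_burn_events) {
        std::fill(Ti.begin(), Ti.end(), 0.0);
        T = 0.0; F = 0; attempts = 0.0; steps = 0.0;
        burning = false;
      }
      continue;
    }
    if (attempts >= next_check) {
      if (mon.check(Ti, T, epsilon)) { converged = true; break; }
      next_check += check_interval;
    }
    if (attempts >= max_attempts) break;
  }

  NumericVector n(S);
  for (int i = 0; i < S; ++i) n[i] = (T > 0) ? Ti[i] / T : 0.0;
  double J = (T > 0) ? (double) F / T : 0.0;
  return List::create(_["n"] = n, _["J"] = J, _["T"] = T,
                      _["F"] = (double) F, _["steps"] = steps,
                      _["attempts"] = attempts, _["converged"] = converged);
}
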