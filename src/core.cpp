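#include <Rcpp.h>
using namespace Rcpp;

// Graphs arrive in CSR form: ptr (length n+1), nbr / sgn (length 2m),
// all 0-based. All randomness goes through R's RNG so that seeding with
// set.seed() on the R side makes every routine deterministic.

static inline int rand_node(int n) {
  int i = (int)(unif_rand() * n);
  return i >= n ? n - 1 : i;
}

// change in negative-edge count (gauge space) or in h/2 (spin space)
// caused by flipping node i
static inline int flip_delta(int i, const IntegerVector& ptr,
                             const IntegerVector& nbr,
                             const IntegerVector& sgn,
                             const std::vector<int>& s) {
  int d = 0;
  for (int k = ptr[i]; k < ptr[i + 1]; ++k)
    d += sgn[k] * s[i] * s[nbr[k]];
  return d;
}

static int count_negative(const IntegerVector& ptr, const IntegerVector& nbr,
                          const IntegerVector& sgn, const std::vector<int>& s) {
  int n = ptr.size() - 1, neg2 = 0;
  for (int i = 0; i < n; ++i)
    for (int k = ptr[i]; k < ptr[i + 1]; ++k)
      if (sgn[k] * s[i] * s[nbr[k]] < 0) ++neg2;
  return neg2 / 2;  // each edge visited twice
}

// random-order sweeps, strict-decrease flips, until a full sweep is quiet
static int greedy_descent(const IntegerVector& ptr, const IntegerVector& nbr,
                          const IntegerVector& sgn, std::vector<int>& s,
                          int cur) {
  int n = ptr.size() - 1;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  bool moved = true;
  while (moved) {
    moved = false;
    for (int i = n - 1; i > 0; --i) {  // Fisher-Yates reshuffle each sweep
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    for (int t = 0; t < n; ++t) {
      int i = order[t];
      int d = flip_delta(i, ptr, nbr, sgn, s);
      if (d < 0) { s[i] = -s[i]; cur += d; moved = true; }
    }
  }
  return cur;
}

// Multi-restart simulated annealing + greedy polish for the minimum
// negative-edge count over all gauges (equivalently MAX-CUT local search).
// [[Rcpp::export]]
List cpp_anneal_gauge(IntegerVector ptr, IntegerVector nbr, IntegerVector sgn,
                      int restarts, double t0, double cool,
                      int sweeps_per_restart) {
  int n = ptr.size() - 1;
  RNGScope scope;
  std::vector<int> s(n), best(n, 1);
  int best_neg = count_negative(ptr, nbr, sgn, best);
  for (int r = 0; r < restarts && best_neg > 0; ++r) {
    for (int i = 0; i < n; ++i) s[i] = unif_rand() < 0.5 ? -1 : 1;
    int cur = count_negative(ptr, nbr, sgn, s);
    double T = t0;
    for (int sweep = 0; sweep < sweeps_per_restart; ++sweep) {
      for (int t = 0; t < n; ++t) {
        int i = rand_node(n);
        int d = flip_delta(i, ptr, nbr, sgn, s);
        if (d <= 0 || unif_rand() < std::exp(-d / T)) {
          s[i] = -s[i]; cur += d;
        }
      }
      T *= cool;
    }
    cur = greedy_descent(ptr, nbr, sgn, s, cur);
    if (cur < best_neg) { best_neg = cur; best = s; }
  }
  return List::create(_["gauge"] = IntegerVector(best.begin(), best.end()),
                      _["negative"] = best_neg);
}

// Greedy energy descent from n_starts uniform random spin states; returns
// the fixed points and their energies h = 2*neg - m.
// [[Rcpp::export]]
List cpp_collect_minima(IntegerVector ptr, IntegerVector nbr,
                        IntegerVector sgn, int n_starts, int m) {
  int n = ptr.size() - 1;
  RNGScope scope;
  IntegerMatrix states(n_starts, n);
  NumericVector energies(n_starts);
  std::vector<int> s(n);
  for (int r = 0; r < n_starts; ++r) {
    for (int i = 0; i < n; ++i) s[i] = unif_rand() < 0.5 ? -1 : 1;
    int neg = count_negative(ptr, nbr, sgn, s);
    neg = greedy_descent(ptr, nbr, sgn, s, neg);
    for (int i = 0; i < n; ++i) states(r, i) = s[i];
    energies[r] = 2.0 * neg - m;
  }
  return List::create(_["states"] = states, _["energies"] = energies);
}

// Single-spin-flip Metropolis chain; one sweep = n proposals at uniformly
// random nodes; acceptance min(1, exp(-beta * dh)). Records per-sweep
// energy, magnetization in the gauge basis, and (for small n) the state
// code sum_i bit_i 2^i.
// [[Rcpp::export]]
List cpp_metropolis(IntegerVector ptr, IntegerVector nbr, IntegerVector sgn,
                    double beta, int sweeps, int burn_in,
                    IntegerVector s_init, IntegerVector gauge,
                    bool record_states) {
  int n = ptr.size() - 1;
  RNGScope scope;
  std::vector<int> s(s_init.begin(), s_init.end());
  double h = 0.0;
  for (int i = 0; i < n; ++i)
    for (int k = ptr[i]; k < ptr[i + 1]; ++k)
      h -= 0.5 * sgn[k] * s[i] * s[nbr[k]];
  int kept = sweeps - burn_in;
  NumericVector hs(kept), mags(kept), codes(record_states ? kept : 0);
  long long accepted = 0, proposed = 0;
  for (int sw = 0; sw < sweeps; ++sw) {
    for (int t = 0; t < n; ++t) {
      int i = rand_node(n);
      int d = flip_delta(i, ptr, nbr, sgn, s);  // dh = 2*d
      double dh = 2.0 * d;
      ++proposed;
      if (dh <= 0 || unif_rand() < std::exp(-beta * dh)) {
        s[i] = -s[i]; h += dh; ++accepted;
      }
    }
    if (sw >= burn_in) {
      int idx = sw - burn_in;
      hs[idx] = h;
      double mg = 0;
      for (int i = 0; i < n; ++i) mg += gauge[i] * s[i];
      mags[idx] = mg / n;
      if (record_states) {
        double code = 0, p = 1;
        for (int i = 0; i < n; ++i) { if (s[i] > 0) code += p; p *= 2; }
        codes[idx] = code;
      }
    }
  }
  List out = List::create(_["h"] = hs, _["magnetization"] = mags,
                          _["acceptance"] = (double)accepted / proposed,
                          _["final_state"] = IntegerVector(s.begin(), s.end()));
  if (record_states) out["state_code"] = codes;
  return out;
}
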