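// GENS chromosome operators and the generation step.  All randomness comes
// from R's RNG stream (Rcpp installs an RNGScope around exported calls), so
// fixed-seed runs are reproducible.
#include <Rcpp.h>
#include <set>
#include <vector>
#include <algorithm>
#include <climits>

using namespace Rcpp;

// uniform integer in 1..n
static inline int runi(int n) {
  int v = (int)(unif_rand() * n) + 1;
  return v > n ? n : v;
}

static bool admissible(const std::vector<int>& v, int m,
                       const IntegerVector& corr) {
  int last = 0;
  const bool seqdep = corr.size() > 0;
  for (size_t i = 0; i < v.size(); ++i) {
    if (v[i] < 0 || v[i] > m) return false;
    if (v[i] > 0) {
      if (v[i] <= last) return false;
      last = v[i];
      if (seqdep && (corr[i] == NA_INTEGER || v[i] != corr[i])) return false;
    }
  }
  return true;
}

static void legal_range(const std::vector<int>& v, int i, int m,
                        int& lo, int& hi);

// random admissible chromosome: visit positions in random order (all model
// residues equally likely a priori), at each choosing uniformly among 0 and
// the model indices still legal between the already-assigned neighbours.
// Visiting in chain order instead would systematically cram runs of the
// highest model indices into the lowest target positions.
static std::vector<int> random_chrom(int n, int m, const IntegerVector& corr) {
  std::vector<int> v(n, 0);
  const bool seqdep = corr.size() > 0;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  for (int i = n - 1; i > 0; --i) std::swap(order[i], order[runi(i + 1) - 1]);
  for (int q = 0; q < n; ++q) {
    const int i = order[q];
    int lo, hi;
    legal_range(v, i, m, lo, hi);
    if (seqdep) {
      const int c = corr[i];
      const bool ok = (c != NA_INTEGER) && c > lo && c < hi;
      if (ok && runi(2) == 1) v[i] = c;
    } else {
      const int nopt = hi - lo - 1;
      const int pick = runi(nopt + 1) - 1; // 0 = leave unassigned
      if (pick > 0) v[i] = lo + pick;
    }
  }
  return v;
}

// legal assignable values at position i: strictly between the nearest
// nonzero neighbours, restricted by the correspondence in seq-dep mode
static void legal_range(const std::vector<int>& v, int i, int m,
                        int& lo, int& hi) {
  lo = 0;
  hi = m + 1;
  for (int q = i - 1; q >= 0; --q) if (v[q] > 0) { lo = v[q]; break; }
  for (size_t q = i + 1; q < v.size(); ++q) if (v[q] > 0) { hi = v[q]; break; }
}

// one point mutation of a type drawn uniformly among the four variants;
// choices with no legal option are skipped
static void point_mutation(std::vector<int>& v, int m,
                           const IntegerVector& corr) {
  const int n = v.size();
  const bool seqdep = corr.size() > 0;
  const int type = runi(4);
  if (type == 1) { // unassign
    std::vector<int> at;
    for (int i = 0; i < n; ++i) if (v[i] > 0) at.push_back(i);
    if (at.empty()) return;
    v[at[runi(at.size()) - 1]] = 0;
  } else if (type == 2 || type == 3) { // assign free / re-assign
    std::vector<int> at;
    for (int i = 0; i < n; ++i)
      if ((type == 2) == (v[i] == 0)) at.push_back(i);
    if (at.empty()) return;
    const int i = at[runi(at.size()) - 1];
    int lo, hi;
    legal_range(v, i, m, lo, hi);
    if (seqdep) {
      const int c = corr[i];
      if (c == NA_INTEGER || c <= lo || c >= hi || c == v[i]) return;
      v[i] = c;
    } else {
      // uniform among legal values excluding the current one
      int count = hi - lo - 1;
      if (v[i] > lo && v[i] < hi) --count;
      if (count <= 0) return;
      int pick = runi(count);
      int val = lo;
      while (pick > 0) {
        ++val;
        if (val != v[i]) --pick;
      }
      v[i] = val;
    }
  } else { // swap the assignments of two target residues
    if (n < 2) return;
    const int i = runi(n) - 1;
    int j = runi(n - 1) - 1;
    if (j >= i) ++j;
    std::vector<int> w = v;
    std::swap(w[i], w[j]);
    if (admissible(w, m, corr)) v = w;
  }
}

static int draw_points(const NumericVector& probs) {
  const double u = unif_rand();
  double acc = 0.0;
  for (int k = 0; k < probs.size(); ++k) {
    acc += probs[k];
    if (u < acc) return k + 1;
  }
  return probs.size();
}

static std::vector<int> mutate_chrom(std::vector<int> v, int m,
                                     const IntegerVector& corr,
                                     const NumericVector& point_probs,
                                     int& points) {
  points = draw_points(point_probs);
  for (int q = 0; q < points; ++q) point_mutation(v, m, corr);
  return v;
}

// two-point crossover with duplicate repair (zero one duplicate at random)
// and left-to-right monotonicity repair
static std::vector<int> crossover_chrom(const std::vector<int>& vi,
                                        const std::vector<int>& vj) {
  const int n = vi.size();
  int x = runi(n), y = runi(n - 1);
  if (y >= x) ++y;
  if (x > y) std::swap(x, y);
  std::vector<int> child = vj;
  for (int q = x - 1; q <= y - 1; ++q) child[q] = vi[q];
  // duplicate repair
  for (int q = 0; q < n; ++q) {
    if (child[q] == 0) continue;
    for (int r = q + 1; r < n; ++r) {
      if (child[r] == child[q]) {
        child[(runi(2) == 1) ? q : r] = 0;
        break;
      }
    }
  }
  // monotonicity repair; the scan direction is drawn at random so neither
  // chain end is systematically favored
  if (runi(2) == 1) {
    int last = 0;
    for (int q = 0; q < n; ++q) {
      if (child[q] == 0) continue;
      if (child[q] <= last) child[q] = 0; else last = child[q];
    }
  } else {
    int last = INT_MAX;
    for (int q = n - 1; q >= 0; --q) {
      if (child[q] == 0) continue;
      if (child[q] >= last) child[q] = 0; else last = child[q];
    }
  }
  return child;
}

static std::vector<int> row_of(const IntegerMatrix& M, int q) {
  std::vector<int> v(M.ncol());
  for (int j = 0; j < M.ncol(); ++j) v[j] = M(q, j);
  return v;
}

// [[Rcpp::export]]
IntegerVector cpp_random_chromosome(int n, int m, IntegerVector corr) {
  return wrap(random_chrom(n, m, corr));
}

// [[Rcpp::export]]
List cpp_mutate(IntegerVector v, int m, IntegerVector corr,
                NumericVector point_probs) {
  int points = 0;
  std::vector<int> out = mutate_chrom(as<std::vector<int> >(v), m, corr,
                                      point_probs, points);
  return List::create(_["v"] = wrap(out), _["points"] = points);
}

// [[Rcpp::export]]
IntegerVector cpp_crossover(IntegerVector vi, IntegerVector vj) {
  if (vi.size() != vj.size()) stop("parents must have equal length");
  return wrap(crossover_chrom(as<std::vector<int> >(vi),
                              as<std::vector<int> >(vj)));
}

// [[Rcpp::export]]
IntegerVector cpp_is_admissible(IntegerMatrix V, int m, IntegerVector corr) {
  IntegerVector out(V.nrow());
  for (int q = 0; q < V.nrow(); ++q)
    out[q] = admissible(row_of(V, q), m, corr) ? 1 : 0;
  return out;
}

// Build the next generation: the fittest distinct individuals form the
// elite seed pool; the incumbent best is copied through; the rest of the
// population is filled by elite mutation / whole-population crossover /
// fresh random chromosomes.
// [[Rcpp::export]]
IntegerMatrix cpp_generation(IntegerMatrix pop, NumericVector score,
                             int n_elite, int m, IntegerVector corr,
                             double p_mut, double p_cross,
                             NumericVector point_probs) {
  const int c = pop.nrow(), n = pop.ncol();
  std::vector<int> ord(c);
  for (int i = 0; i < c; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return score[a] > score[b]; });
  // distinct fittest individuals
  std::set<std::vector<int> > seen;
  std::vector<int> elite;
  for (int i = 0; i < c && (int)elite.size() < n_elite; ++i) {
    std::vector<int> v = row_of(pop, ord[i]);
    if (seen.insert(v).second) elite.push_back(ord[i]);
  }
  IntegerMatrix out(c, n);
  for (int j = 0; j < n; ++j) out(0, j) = pop(ord[0], j);
  for (int q = 1; q < c; ++q) {
    const double u = unif_rand();
    std::vector<int> child;
    if (u < p_mut) {
      int points = 0;
      child = mutate_chrom(row_of(pop, elite[runi(elite.size()) - 1]), m,
                           corr, point_probs, points);
    } else if (u < p_mut + p_cross) {
      const int a = runi(c) - 1;
      int b = runi(c - 1) - 1;
      if (b >= a) ++b;
      child = crossover_chrom(row_of(pop, a), row_of(pop, b));
    } else {
      child = random_chrom(n, m, corr);
    }
    for (int j = 0; j < n; ++j) out(q, j) = child[j];
  }
  return out;
}
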