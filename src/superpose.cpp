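// Rigid-body superposition core shared by every RMSD computation in the
// package: Kabsch (covariance SVD with determinant correction), batched
// kernel screening and chromosome fitness evaluation.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Kabsch fit of `moving` onto `fixed` (both k x 3, row i <-> row i).
// Returns rotation R (3x3, det +1), translation t, and the minimum RMSD.
// Transformed coordinates: Y %*% t(R) + t (rows).
static void kabsch(const arma::mat& X, const arma::mat& Y,
                   arma::mat& R, arma::rowvec& t, double& rmsd) {
  const arma::rowvec xc = arma::mean(X, 0);
  const arma::rowvec yc = arma::mean(Y, 0);
  arma::mat X0 = X.each_row() - xc;
  arma::mat Y0 = Y.each_row() - yc;
  arma::mat H = Y0.t() * X0;
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H)) Rcpp::stop("SVD failed in superposition");
  arma::mat D = arma::eye(3, 3);
  if (arma::det(V * U.t()) < 0.0) D(2, 2) = -1.0;
  R = V * D * U.t();
  t = xc - yc * R.t();
  arma::mat Yt = Y * R.t();
  Yt.each_row() += t;
  rmsd = std::sqrt(arma::accu(arma::square(Yt - X)) / X.n_rows);
}

// [[Rcpp::export]]
List cpp_kabsch(const arma::mat& fixed, const arma::mat& moving) {
  if (fixed.n_rows == 0) stop("empty input to superposition");
  if (fixed.n_rows != moving.n_rows || fixed.n_cols != 3 || moving.n_cols != 3)
    stop("coordinate matrices must have matching rows and 3 columns");
  arma::mat R;
  arma::rowvec t;
  double rmsd;
  kabsch(fixed, moving, R, t, rmsd);
  return List::create(_["rotation"] = R,
                      _["translation"] = NumericVector(t.begin(), t.end()),
                      _["rmsd"] = rmsd);
}

// [[Rcpp::export]]
double cpp_rmsd_rows(const arma::mat& a, const arma::mat& b) {
  if (a.n_rows != b.n_rows || a.n_cols != b.n_cols) stop("shape mismatch");
  if (a.n_rows == 0) stop("empty input");
  return std::sqrt(arma::accu(arma::square(a - b)) / a.n_rows);
}

// Stack the shared beads of the residue pairs (ti, mi) into fixed/moving
// matrices.  Bead order per pair: p (only if present in BOTH residues), r, b.
static void stack_pairs(const arma::mat& tp, const arma::mat& tr,
                        const arma::mat& tb, const LogicalVector& tpres,
                        const arma::mat& mp, const arma::mat& mr,
                        const arma::mat& mb, const LogicalVector& mpres,
                        const IntegerVector& ti, const IntegerVector& mi,
                        arma::mat& X, arma::mat& Y, arma::uvec& pair_of) {
  const int np = ti.size();
  int k = 0;
  for (int i = 0; i < np; ++i)
    k += 2 + ((tpres[ti[i] - 1] && mpres[mi[i] - 1]) ? 1 : 0);
  X.set_size(k, 3);
  Y.set_size(k, 3);
  pair_of.set_size(k);
  int r = 0;
  for (int i = 0; i < np; ++i) {
    const int a = ti[i] - 1, b = mi[i] - 1;
    if (tpres[a] && mpres[b]) {
      X.row(r) = tp.row(a); Y.row(r) = mp.row(b); pair_of(r++) = i;
    }
    X.row(r) = tr.row(a); Y.row(r) = mr.row(b); pair_of(r++) = i;
    X.row(r) = tb.row(a); Y.row(r) = mb.row(b); pair_of(r++) = i;
  }
}

// Optimal superposition over the shared beads of a pair list.
// Returns transform, rmsd, and the mean per-pair bead distance after the fit.
// [[Rcpp::export]]
List cpp_alignment_fit(const arma::mat& tp, const arma::mat& tr,
                       const arma::mat& tb, const LogicalVector& tpres,
                       const arma::mat& mp, const arma::mat& mr,
                       const arma::mat& mb, const LogicalVector& mpres,
                       const IntegerVector& ti, const IntegerVector& mi) {
  if (ti.size() == 0) stop("empty pair list");
  arma::mat X, Y;
  arma::uvec pair_of;
  stack_pairs(tp, tr, tb, tpres, mp, mr, mb, mpres, ti, mi, X, Y, pair_of);
  arma::mat R;
  arma::rowvec t;
  double rmsd;
  kabsch(X, Y, R, t, rmsd);
  arma::mat Yt = Y * R.t();
  Yt.each_row() += t;
  const arma::vec d = arma::sqrt(arma::sum(arma::square(Yt - X), 1));
  NumericVector pair_dist(ti.size());
  IntegerVector nb(ti.size());
  for (arma::uword r = 0; r < d.n_elem; ++r) {
    pair_dist[pair_of(r)] += d(r);
    nb[pair_of(r)] += 1;
  }
  for (int i = 0; i < ti.size(); ++i) pair_dist[i] /= nb[i];
  return List::create(_["rotation"] = R,
                      _["translation"] = NumericVector(t.begin(), t.end()),
                      _["rmsd"] = rmsd,
                      _["pair_dist"] = pair_dist);
}

// Superposed RMSD for each candidate pair set in `cand` (N x 2k matrix of
// columns t1, m1, ..., tk, mk; 1-based).  Used to screen kernel candidates.
// [[Rcpp::export]]
NumericVector cpp_pairs_rmsd_batch(const arma::mat& tp, const arma::mat& tr,
                                   const arma::mat& tb, const LogicalVector& tpres,
                                   const arma::mat& mp, const arma::mat& mr,
                                   const arma::mat& mb, const LogicalVector& mpres,
                                   const IntegerMatrix& cand) {
  const int n = cand.nrow();
  const int k = cand.ncol() / 2;
  NumericVector out(n);
  IntegerVector ti(k), mi(k);
  arma::mat X, Y, R;
  arma::uvec pair_of;
  arma::rowvec t;
  double rmsd;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < k; ++j) {
      ti[j] = cand(i, 2 * j);
      mi[j] = cand(i, 2 * j + 1);
    }
    stack_pairs(tp, tr, tb, tpres, mp, mr, mb, mpres, ti, mi, X, Y, pair_of);
    kabsch(X, Y, R, t, rmsd);
    out[i] = rmsd;
  }
  return out;
}

// Superposed RMSD for an arbitrary list of pair matrices (each N_i x 2,
// columns t, m).  Used by the exhaustive toy oracle.
// [[Rcpp::export]]
NumericVector cpp_pairlist_rmsd(const arma::mat& tp, const arma::mat& tr,
                                const arma::mat& tb, const LogicalVector& tpres,
                                const arma::mat& mp, const arma::mat& mr,
                                const arma::mat& mb, const LogicalVector& mpres,
                                const List& pairsets) {
  const int n = pairsets.size();
  NumericVector out(n);
  arma::mat X, Y, R;
  arma::uvec pair_of;
  arma::rowvec t;
  double rmsd;
  for (int i = 0; i < n; ++i) {
    IntegerMatrix pm = pairsets[i];
    IntegerVector ti = pm(_, 0), mi = pm(_, 1);
    stack_pairs(tp, tr, tb, tpres, mp, mr, mb, mpres, ti, mi, X, Y, pair_of);
    kabsch(X, Y, R, t, rmsd);
    out[i] = rmsd;
  }
  return out;
}

// Batched GENS fitness: one row of V per chromosome, V(i, j) in {0, 1..m}.
// score = N_aligned - wr * rmsd - wb * N_bad - wp * max(0, rmsd - U) * N_aligned
// where N_bad counts aligned pairs whose mean bead distance after the
// chromosome's own optimal superposition exceeds bad_cut (the "incorrectly
// aligned" nucleotides).  Empty chromosome: 0.
// [[Rcpp::export]]
List cpp_chrom_fitness(const arma::mat& tp, const arma::mat& tr,
                       const arma::mat& tb, const LogicalVector& tpres,
                       const arma::mat& mp, const arma::mat& mr,
                       const arma::mat& mb, const LogicalVector& mpres,
                       const IntegerMatrix& V, double U, double bad_cut,
                       double wr, double wb, double wp) {
  const int c = V.nrow(), n = V.ncol();
  NumericVector score(c), rmsd_out(c);
  IntegerVector len(c), nbad(c);
  arma::mat X, Y, R;
  arma::uvec pair_of;
  arma::rowvec t;
  double rmsd;
  for (int q = 0; q < c; ++q) {
    std::vector<int> ti, mi;
    for (int i = 0; i < n; ++i)
      if (V(q, i) > 0) { ti.push_back(i + 1); mi.push_back(V(q, i)); }
    const int na = ti.size();
    len[q] = na;
    if (na == 0) { score[q] = 0.0; rmsd_out[q] = NA_REAL; nbad[q] = 0; continue; }
    IntegerVector tiv = wrap(ti), miv = wrap(mi);
    stack_pairs(tp, tr, tb, tpres, mp, mr, mb, mpres, tiv, miv, X, Y, pair_of);
    kabsch(X, Y, R, t, rmsd);
    arma::mat Yt = Y * R.t();
    Yt.each_row() += t;
    const arma::vec d = arma::sqrt(arma::sum(arma::square(Yt - X), 1));
    std::vector<double> pd(na, 0.0);
    std::vector<int> nb(na, 0);
    for (arma::uword r = 0; r < d.n_elem; ++r) {
      pd[pair_of(r)] += d(r);
      nb[pair_of(r)] += 1;
    }
    int bad = 0;
    for (int i = 0; i < na; ++i) if (pd[i] / nb[i] > bad_cut) ++bad;
    nbad[q] = bad;
    rmsd_out[q] = rmsd;
    score[q] = na - wr * rmsd - wb * bad - wp * std::max(0.0, rmsd - U) * na;
  }
  return List::create(_["score"] = score, _["rmsd"] = rmsd_out,
                      _["n_aligned"] = len, _["n_bad"] = nbad);
}
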