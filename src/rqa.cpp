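#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Time-delay embedding distances and recurrence structures for RQA.
// Conventions (shared with the R-level brute-force oracle in the tests):
//  * embedded points v_i = (x_i, x_{i+tau}, ..., x_{i+(m-1)tau}), i = 1..N'
//  * Euclidean distance; a pair (i, j) is admissible iff |i - j| > theiler
//  * vertical/white-vertical scans run over each column's two admissible
//    segments (above and below the Theiler band) separately
//  * white-vertical (gap) lengths are zero-runs strictly between two
//    recurrent points of the same segment

static inline double emb_dist(const double* x, int i, int j, int tau, int m) {
  double s = 0.0;
  for (int k = 0; k < m; ++k) {
    double d = x[i + k * tau] - x[j + k * tau];
    s += d * d;
  }
  return std::sqrt(s);
}

// [[Rcpp::export]]
int cpp_embed_count(int n, int tau, int m) { return n - (m - 1) * tau; }

// Fraction of admissible pairs with distance <= eps.
// [[Rcpp::export]]
double cpp_recurrence_rate(NumericVector x, int tau, int m, double eps,
                           int theiler) {
  int np = x.size() - (m - 1) * tau;
  const double* xp = REAL(x);
  long long tot = 0, rec = 0;
  for (int i = 0; i < np; ++i) {
    for (int j = i + theiler + 1; j < np; ++j) {
      ++tot;
      if (emb_dist(xp, i, j, tau, m) <= eps) ++rec;
    }
  }
  if (tot == 0) return 0.0;
  return (double)rec / (double)tot;
}

// Range of admissible pair distances (for bisection brackets).
// [[Rcpp::export]]
NumericVector cpp_dist_range(NumericVector x, int tau, int m, int theiler) {
  int np = x.size() - (m - 1) * tau;
  const double* xp = REAL(x);
  double lo = R_PosInf, hi = 0.0;
  for (int i = 0; i < np; ++i) {
    for (int j = i + theiler + 1; j < np; ++j) {
      double d = emb_dist(xp, i, j, tau, m);
      if (d < lo) lo = d;
      if (d > hi) hi = d;
    }
  }
  return NumericVector::create(lo, hi);
}

// One-pass recurrence-plot construction: materialize squared admissible
// pair distances once, bisect the threshold on them (fixed recurrence rate
// mode) or use the supplied eps (fixed threshold mode), then fill the
// binary matrix from the stored distances.
// [[Rcpp::export]]
List cpp_recurrence_plot(NumericVector x, int tau, int m, int theiler,
                         double target, double tol, int maxit,
                         double eps_fixed, bool use_fixed) {
  int np = x.size() - (m - 1) * tau;
  const double* xp = REAL(x);
  std::vector<double> d2;
  d2.reserve((size_t)np * (np > theiler ? np - theiler : 0) / 2);
  double hi2 = 0.0;
  for (int i = 0; i < np; ++i)
    for (int j = i + theiler + 1; j < np; ++j) {
      double s = 0.0;
      for (int k = 0; k < m; ++k) {
        double dd = xp[i + k * tau] - xp[j + k * tau];
        s += dd * dd;
      }
      d2.push_back(s);
      if (s > hi2) hi2 = s;
    }
  double eps2, rr = 0.0;
  int converged = 1;
  size_t ntot = d2.size();
  if (use_fixed) {
    eps2 = eps_fixed * eps_fixed;
    size_t cnt = 0;
    for (size_t k = 0; k < ntot; ++k) if (d2[k] <= eps2) ++cnt;
    rr = ntot ? (double)cnt / (double)ntot : 0.0;
  } else {
    double lo = 0.0, hi = hi2;
    eps2 = hi2 / 2;
    converged = 0;
    // coarse stage: bisect on a strided subsample to shrink the bracket
    // cheaply; the final tolerance check below always uses the full count
    size_t stride = ntot > 200000 ? ntot / 100000 : 1;
    if (stride > 1) {
      size_t nsub = 0;
      for (size_t k = 0; k < ntot; k += stride) ++nsub;
      for (int it = 0; it < maxit && nsub > 0; ++it) {
        double mid = (lo + hi) / 2;
        size_t cnt = 0;
        for (size_t k = 0; k < ntot; k += stride) if (d2[k] <= mid) ++cnt;
        double rsub = (double)cnt / (double)nsub;
        if (std::abs(rsub - target) <= tol / 2) break;
        if (rsub > target) hi = mid; else lo = mid;
      }
    }
    for (int it = 0; it < maxit && ntot > 0; ++it) {
      eps2 = (lo + hi) / 2;
      size_t cnt = 0;
      for (size_t k = 0; k < ntot; ++k) if (d2[k] <= eps2) ++cnt;
      rr = (double)cnt / (double)ntot;
      if (std::abs(rr - target) <= tol) { converged = 1; break; }
      if (rr > target) hi = eps2; else lo = eps2;
    }
  }
  IntegerMatrix R(np, np);
  int* rp = INTEGER(R);
  size_t idx = 0;
  for (int i = 0; i < np; ++i)
    for (int j = i + theiler + 1; j < np; ++j, ++idx) {
      if (d2[idx] <= eps2) {
        rp[(R_xlen_t)j * np + i] = 1;
        rp[(R_xlen_t)i * np + j] = 1;
      }
    }
  return List::create(_["R"] = R, _["eps"] = std::sqrt(eps2), _["rr"] = rr,
                      _["converged"] = converged);
}

// Binary recurrence matrix, Theiler band (|i-j| <= theiler) forced to 0.
// [[Rcpp::export]]
IntegerMatrix cpp_recurrence_matrix(NumericVector x, int tau, int m,
                                    double eps, int theiler) {
  int np = x.size() - (m - 1) * tau;
  const double* xp = REAL(x);
  IntegerMatrix R(np, np);
  int* rp = INTEGER(R);
  for (int i = 0; i < np; ++i) {
    for (int j = i + theiler + 1; j < np; ++j) {
      if (emb_dist(xp, i, j, tau, m) <= eps) {
        rp[(R_xlen_t)j * np + i] = 1;
        rp[(R_xlen_t)i * np + j] = 1;
      }
    }
  }
  return R;
}

// Diagonal line lengths on upper-triangle diagonals with offset > theiler.
// [[Rcpp::export]]
IntegerVector cpp_diag_lengths(IntegerMatrix R, int theiler) {
  int n = R.nrow();
  const int* rp = INTEGER(R);
  std::vector<int> lens;
  for (int k = theiler + 1; k < n; ++k) {
    int run = 0;
    for (int i = 0; i + k < n; ++i) {
      if (rp[(R_xlen_t)(i + k) * n + i]) {
        ++run;
      } else if (run > 0) {
        lens.push_back(run);
        run = 0;
      }
    }
    if (run > 0) lens.push_back(run);
  }
  return wrap(lens);
}

// Vertical runs, white-vertical gaps and type-2 recurrence times, scanned
// per column over the two admissible segments.
// [[Rcpp::export]]
List cpp_vertical_structures(IntegerMatrix R, int theiler) {
  int n = R.nrow();
  const int* rp = INTEGER(R);
  std::vector<int> vert, white, t2;
  for (int j = 0; j < n; ++j) {
    const int* col = rp + (R_xlen_t)j * n;
    int segs[2][2] = {{0, j - theiler - 1}, {j + theiler + 1, n - 1}};
    for (int s = 0; s < 2; ++s) {
      int lo = segs[s][0], hi = segs[s][1];
      if (lo > hi) continue;
      int run = 0;
      int last_rec = -1;
      int prev_entry = -1;
      bool in_block = false;
      for (int i = lo; i <= hi; ++i) {
        if (col[i]) {
          ++run;
          if (last_rec >= 0 && i - last_rec - 1 > 0)
            white.push_back(i - last_rec - 1);
          last_rec = i;
          if (!in_block) {
            if (prev_entry >= 0) t2.push_back(i - prev_entry);
            prev_entry = i;
            in_block = true;
          }
        } else {
          if (run > 0) vert.push_back(run);
          run = 0;
          in_block = false;
        }
      }
      if (run > 0) vert.push_back(run);
    }
  }
  return List::create(_["vertical"] = wrap(vert), _["white"] = wrap(white),
                      _["t2"] = wrap(t2));
}

// Recurrence-network clustering: mean local clustering coefficient and
// transitivity of the (Theiler-masked) recurrence matrix as an adjacency.
// Rows are packed into bitsets; t_i = 1/2 sum_{u in N(i)} |N(u) & N(i)|.
// [[Rcpp::export]]
NumericVector cpp_clust_trans(IntegerMatrix R) {
  int n = R.nrow();
  const int* rp = INTEGER(R);
  int words = (n + 63) / 64;
  std::vector<uint64_t> bits((size_t)n * words, 0ULL);
  std::vector< std::vector<int> > nbr(n);
  for (int j = 0; j < n; ++j) {
    const int* col = rp + (R_xlen_t)j * n;
    for (int i = 0; i < n; ++i) {
      if (col[i]) {
        bits[(size_t)j * words + (i >> 6)] |= (1ULL << (i & 63));
        nbr[j].push_back(i);
      }
    }
  }
  double clust_sum = 0.0;
  long long tri2 = 0, triples = 0;   // tri2 = sum_i t_i (3x triangles)
  for (int i = 0; i < n; ++i) {
    int k = (int)nbr[i].size();
    if (k < 2) continue;
    const uint64_t* bi = &bits[(size_t)i * words];
    long long common = 0;
    for (int a = 0; a < k; ++a) {
      const uint64_t* bu = &bits[(size_t)nbr[i][a] * words];
      for (int w = 0; w < words; ++w)
        common += __builtin_popcountll(bi[w] & bu[w]);
    }
    long long ti = common / 2;
    tri2 += ti;
    triples += (long long)k * (k - 1) / 2;
    clust_sum += (double)ti / ((double)k * (k - 1) / 2.0);
  }
  double clust = n > 0 ? clust_sum / n : 0.0;
  double trans = triples > 0 ? (double)tri2 / (double)triples : 0.0;
  return NumericVector::create(clust, trans);
}

// Kennel false-nearest-neighbour fractions for m = 1..m_max.
// Nearest neighbours searched with a Theiler exclusion |i-j| > theiler;
// candidate points restricted so the (m+1)-th coordinate exists.
// [[Rcpp::export]]
NumericVector cpp_fnn_fractions(NumericVector x, int tau, int m_max,
                                double rtol, double atol, int theiler) {
  int n = x.size();
  const double* xp = REAL(x);
  double mean = 0.0;
  for (int i = 0; i < n; ++i) mean += xp[i];
  mean /= n;
  double sdx = 0.0;
  for (int i = 0; i < n; ++i) sdx += (xp[i] - mean) * (xp[i] - mean);
  sdx = std::sqrt(sdx / (n - 1));
  NumericVector out(m_max, NA_REAL);
  for (int m = 1; m <= m_max; ++m) {
    int np = n - m * tau;          // need coordinate at i + m*tau
    if (np < 2 * (theiler + 1)) break;
    long long false_n = 0, valid = 0;
    for (int i = 0; i < np; ++i) {
      double best = R_PosInf;
      int bj = -1;
      for (int j = 0; j < np; ++j) {
        if (std::abs(i - j) <= theiler) continue;
        double d = emb_dist(xp, i, j, tau, m);
        if (d < best) { best = d; bj = j; }
      }
      if (bj < 0 || best <= 0.0) continue;
      ++valid;
      double extra = std::abs(xp[i + m * tau] - xp[bj + m * tau]);
      double dmp1 = std::sqrt(best * best + extra * extra);
      if (extra / best > rtol || dmp1 / sdx > atol) ++false_n;
    }
    out[m - 1] = valid > 0 ? (double)false_n / (double)valid : NA_REAL;
  }
  return out;
}
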