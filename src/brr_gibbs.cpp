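// Single-site Gibbs sampler for the additive + dominance Bayesian ridge model
//
//   y_i = mu + sum_j X_ij a_j + sum_j Z_ij d_j + e_i
//
// with a_j ~ N(0, s2a), d_j ~ N(0, s2d), e_i ~ N(0, s2e) and scaled-inverse-
// chi-square hyperpriors on the three variances. X is a dosage matrix coded
// 0/1/2 and Z a 0/1 heterozygosity indicator; both are stored as per-column
// row-index lists (rows where x = 1 and rows where x = 2), which makes each
// single-site update a pair of add-only passes over the nonzero rows.
//
// Internally the columns are centered (the update uses x - xbar), which
// decorrelates the intercept from the marker effects and greatly improves
// mixing; the residual vector is kept on the uncentered scale together with
// a scalar offset, so no full-length vector is touched during effect
// updates. Posterior means are reported on the original (uncentered) scale.
//
// Each iteration updates the intercept, then sweeps all additive effects,
// then all dominance effects. Dominance columns with no heterozygotes are
// pinned at 0 and excluded from the s2d update. With fix_var = true the
// variance components stay at their starting values, making the posterior
// mean converge to the closed-form joint ridge solution.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

// Column-compressed storage of a 0/1/2 matrix: rows with value 1 and value 2.
struct DosageCols {
  std::vector<int> idx1, idx2;
  std::vector<int> ptr1, ptr2;     // p + 1 offsets each
  std::vector<double> xbar;        // column means
  std::vector<double> ssq_c;       // centered sum of squares
  int n, p;

  void build(const NumericMatrix& X) {
    n = X.nrow(); p = X.ncol();
    ptr1.assign(p + 1, 0); ptr2.assign(p + 1, 0);
    xbar.assign(p, 0.0); ssq_c.assign(p, 0.0);
    size_t n1 = 0, n2 = 0;
    for (int j = 0; j < p; ++j) {
      const double* xj = &X(0, j);
      for (int i = 0; i < n; ++i) {
        if (xj[i] == 1.0) ++n1;
        else if (xj[i] == 2.0) ++n2;
        else if (xj[i] != 0.0) stop("design entries must be coded 0, 1 or 2");
      }
      ptr1[j + 1] = (int) n1; ptr2[j + 1] = (int) n2;
    }
    idx1.resize(n1); idx2.resize(n2);
    size_t k1 = 0, k2 = 0;
    for (int j = 0; j < p; ++j) {
      const double* xj = &X(0, j);
      double sx = 0, sxx = 0;
      for (int i = 0; i < n; ++i) {
        if (xj[i] == 1.0) { idx1[k1++] = i; sx += 1; sxx += 1; }
        else if (xj[i] == 2.0) { idx2[k2++] = i; sx += 2; sxx += 4; }
      }
      xbar[j] = sx / n;
      ssq_c[j] = sxx - n * xbar[j] * xbar[j];
    }
  }

  // dot(x_j, e)
  inline double dot(int j, const double* e) const {
    double s1 = 0, s2 = 0;
    for (int k = ptr1[j]; k < ptr1[j + 1]; ++k) s1 += e[idx1[k]];
    for (int k = ptr2[j]; k < ptr2[j + 1]; ++k) s2 += e[idx2[k]];
    return s1 + 2.0 * s2;
  }

  // e -= delta * x_j
  inline void update(int j, double* e, double delta) const {
    const double d2 = 2.0 * delta;
    for (int k = ptr1[j]; k < ptr1[j + 1]; ++k) e[idx1[k]] -= delta;
    for (int k = ptr2[j]; k < ptr2[j + 1]; ++k) e[idx2[k]] -= d2;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_brr_gibbs(NumericVector y, NumericMatrix X, NumericMatrix Z,
                   int niter, int burnin, int thin,
                   double df_prior, double Sa, double Sd, double Se,
                   bool fix_var, double s2a0, double s2d0, double s2e0) {
  const int n = y.size();
  const int p = X.ncol();
  if (X.nrow() != n || Z.nrow() != n || Z.ncol() != p)
    stop("dimension mismatch between y, X and Z");
  if (niter <= burnin) stop("chain length must exceed burn-in");

  DosageCols xc, zc;
  xc.build(X);
  zc.build(Z);

  int p_dom = 0;                              // dominance columns with signal
  for (int j = 0; j < p; ++j) if (zc.ptr1[j + 1] > zc.ptr1[j]) ++p_dom;

  std::vector<double> a(p, 0.0), d(p, 0.0);
  double mu = 0.0;                             // intercept on centered scale
  for (int i = 0; i < n; ++i) mu += y[i];
  mu /= n;
  // e_store = y - mu - X a - Z d; true (centered-model) residual is
  // e_store + C with C = sum_j (a_j xbar_j + d_j zbar_j).
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  double s2a = s2a0, s2d = s2d0, s2e = s2e0;

  std::vector<double> a_mean(p, 0.0), d_mean(p, 0.0);
  double mu_mean = 0.0, s2a_mean = 0.0, s2d_mean = 0.0, s2e_mean = 0.0;
  int n_keep = 0;

  const int n_rec = (niter + thin - 1) / thin;
  NumericVector mu_chain(n_rec), s2a_chain(n_rec), s2d_chain(n_rec), s2e_chain(n_rec);
  int rec = 0;

  for (int it = 0; it < niter; ++it) {
    // exact recomputation of the residual sum and centering offset guards
    // against drift from millions of incremental updates
    double S = 0.0;
    for (int i = 0; i < n; ++i) S += e[i];
    double C = 0.0;
    for (int j = 0; j < p; ++j) C += a[j] * xc.xbar[j] + d[j] * zc.xbar[j];

    // intercept of the centered model (flat prior)
    {
      const double ebar = S / n + C;
      const double mu_new = mu + ebar + norm_rand() * std::sqrt(s2e / n);
      const double delta = mu_new - mu;
      for (int i = 0; i < n; ++i) e[i] -= delta;
      S -= n * delta;
      mu = mu_new;
    }
    // additive effects (centered columns; rhs = x_j'e_store - xbar_j * S)
    {
      const double lambda = s2e / s2a;
      for (int j = 0; j < p; ++j) {
        const double rhs = xc.dot(j, e.data()) - xc.xbar[j] * S + xc.ssq_c[j] * a[j];
        const double Cj = xc.ssq_c[j] + lambda;
        const double a_new = rhs / Cj + norm_rand() * std::sqrt(s2e / Cj);
        const double delta = a_new - a[j];
        if (delta != 0.0) {
          xc.update(j, e.data(), delta);
          S -= delta * n * xc.xbar[j];
        }
        a[j] = a_new;
      }
    }
    // dominance effects
    {
      const double lambda = s2e / s2d;
      for (int j = 0; j < p; ++j) {
        if (zc.ptr1[j + 1] == zc.ptr1[j] && zc.ptr2[j + 1] == zc.ptr2[j]) {
          d[j] = 0.0;
          continue;
        }
        const double rhs = zc.dot(j, e.data()) - zc.xbar[j] * S + zc.ssq_c[j] * d[j];
        const double Cj = zc.ssq_c[j] + lambda;
        const double d_new = rhs / Cj + norm_rand() * std::sqrt(s2e / Cj);
        const double delta = d_new - d[j];
        if (delta != 0.0) {
          zc.update(j, e.data(), delta);
          S -= delta * n * zc.xbar[j];
        }
        d[j] = d_new;
      }
    }
    // variance components
    if (!fix_var) {
      double ssa = 0, ssd = 0, sse = 0;
      for (int j = 0; j < p; ++j) ssa += a[j] * a[j];
      for (int j = 0; j < p; ++j) ssd += d[j] * d[j];
      // true residual = e_store + C (recompute C after the sweeps)
      double C2 = 0.0;
      for (int j = 0; j < p; ++j) C2 += a[j] * xc.xbar[j] + d[j] * zc.xbar[j];
      for (int i = 0; i < n; ++i) { const double r = e[i] + C2; sse += r * r; }
      s2a = (ssa + df_prior * Sa) / R::rchisq(df_prior + p);
      s2d = (ssd + df_prior * Sd) / R::rchisq(df_prior + (p_dom > 0 ? p_dom : 1));
      s2e = (sse + df_prior * Se) / R::rchisq(df_prior + n);
    }

    // intercept on the original (uncentered) scale
    double C3 = 0.0;
    for (int j = 0; j < p; ++j) C3 += a[j] * xc.xbar[j] + d[j] * zc.xbar[j];
    const double mu_orig = mu - C3;

    if (it % thin == 0) {
      mu_chain[rec] = mu_orig; s2a_chain[rec] = s2a;
      s2d_chain[rec] = s2d; s2e_chain[rec] = s2e;
      ++rec;
    }
    if (it >= burnin) {
      ++n_keep;
      mu_mean += mu_orig;
      s2a_mean += s2a; s2d_mean += s2d; s2e_mean += s2e;
      for (int j = 0; j < p; ++j) { a_mean[j] += a[j]; d_mean[j] += d[j]; }
    }
  }

  NumericVector a_out(p), d_out(p);
  for (int j = 0; j < p; ++j) {
    a_out[j] = a_mean[j] / n_keep;
    d_out[j] = d_mean[j] / n_keep;
  }

  return List::create(
    _["mu"] = mu_mean / n_keep,
    _["a"] = a_out,
    _["d"] = d_out,
    _["s2a"] = s2a_mean / n_keep,
    _["s2d"] = s2d_mean / n_keep,
    _["s2e"] = s2e_mean / n_keep,
    _["mu_chain"] = mu_chain[Range(0, rec - 1)],
    _["s2a_chain"] = s2a_chain[Range(0, rec - 1)],
    _["s2d_chain"] = s2d_chain[Range(0, rec - 1)],
    _["s2e_chain"] = s2e_chain[Range(0, rec - 1)],
    _["n_kept"] = n_keep);
}
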