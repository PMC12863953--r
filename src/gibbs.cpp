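#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// One-sided truncated standard-normal draw, x > a.  Inverse-CDF in the
// body of the distribution, Robert's exponential rejection in the far
// tail where the CDF saturates.
static double rtnorm_above(double a) {
  if (a < 5.0) {
    double p = R::pnorm(a, 0.0, 1.0, 1, 0);
    double u = p + unif_rand() * (1.0 - p);
    if (u >= 1.0) u = 1.0 - 1e-16;
    double x = R::qnorm(u, 0.0, 1.0, 1, 0);
    if (R_finite(x) && x >= a) return x;
  }
  const double alpha = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (;;) {
    double z = a + exp_rand() / alpha;
    double rho = std::exp(-0.5 * (z - alpha) * (z - alpha));
    if (unif_rand() <= rho) return z;
  }
}

// a' H^{-1} a for a symmetric sparse matrix in CSC arrays (i, p, x).
static double quad_form(const int* Hi, const int* Hp, const double* Hx,
                        const double* a, int n) {
  double q = 0.0;
  for (int col = 0; col < n; ++col) {
    double dot = 0.0;
    for (int k = Hp[col]; k < Hp[col + 1]; ++k) dot += Hx[k] * a[Hi[k]];
    q += a[col] * dot;
  }
  return q;
}

// Single-site Gibbs sampler for the animal model
//   y (or latent l) = X beta + Z a + e,  a ~ N(0, H sigma2a),
// with flat-ish normal prior on contemporary-group effects
// (variance sigma2b) and scaled-inverse-chi-square priors on the
// variance components.  For the threshold model the residual variance
// is fixed at 1, the threshold at 0, and the latent liability of every
// record is refreshed from its truncated-normal full conditional.
//
// record_animal / record_cg are 1-based; Hi/Hp/Hx are the dgCMatrix
// slots of H^{-1} over all animals.
// [[Rcpp::export(name = ".gibbs_animal_model")]]
List gibbs_animal_model(NumericVector y,
                        IntegerVector record_animal,
                        IntegerVector record_cg,
                        int n_animals, int n_cg,
                        IntegerVector Hi, IntegerVector Hp, NumericVector Hx,
                        bool threshold,
                        int n_iter, int burn_in, int thin,
                        double sigma2a_start, double sigma2e_start,
                        double sigma2b,
                        double nu_a, double scale_a,
                        double nu_e, double scale_e,
                        bool fix_variances) {
  const int n_rec = y.size();
  RNGScope scope;
  const int* hi = INTEGER(Hi);
  const int* hp = INTEGER(Hp);
  const double* hx = REAL(Hx);

  // record lists per CG and per animal, built once
  std::vector<std::vector<int> > cg_rec(n_cg), an_rec(n_animals);
  for (int r = 0; r < n_rec; ++r) {
    cg_rec[record_cg[r] - 1].push_back(r);
    an_rec[record_animal[r] - 1].push_back(r);
  }

  std::vector<double> beta(n_cg, 0.0), a(n_animals, 0.0), e(n_rec);
  std::vector<double> ystar(n_rec);      // observed y, or latent liability
  for (int r = 0; r < n_rec; ++r) {
    ystar[r] = threshold ? 0.0 : y[r];   // liabilities start at 0
    e[r] = ystar[r];
  }

  double s2a = sigma2a_start, s2e = threshold ? 1.0 : sigma2e_start;

  const int n_keep = (n_iter - burn_in) / thin;
  NumericVector keep_s2a(n_keep), keep_s2e(n_keep);
  NumericMatrix keep_a(n_keep, n_animals);
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // latent liabilities (threshold model): l_r ~ N(fitted, 1) truncated
    if (threshold) {
      for (int r = 0; r < n_rec; ++r) {
        double fitted = ystar[r] - e[r];
        double l;
        if (y[r] > 0.5) l = fitted + rtnorm_above(-fitted);        // l > 0
        else            l = fitted - rtnorm_above(fitted);         // l <= 0
        e[r] += l - ystar[r];
        ystar[r] = l;
      }
    }

    // contemporary-group effects
    for (int j = 0; j < n_cg; ++j) {
      const std::vector<int>& recs = cg_rec[j];
      double rsum = 0.0;
      for (size_t k = 0; k < recs.size(); ++k) rsum += e[recs[k]] + beta[j];
      double prec = recs.size() / s2e + 1.0 / sigma2b;
      double mean = (rsum / s2e) / prec;
      double bnew = mean + norm_rand() / std::sqrt(prec);
      double diff = beta[j] - bnew;
      for (size_t k = 0; k < recs.size(); ++k) e[recs[k]] += diff;
      beta[j] = bnew;
    }

    // additive genetic effects
    for (int i = 0; i < n_animals; ++i) {
      double hdot = 0.0, hii = 0.0;
      for (int k = hp[i]; k < hp[i + 1]; ++k) {
        hdot += hx[k] * a[hi[k]];
        if (hi[k] == i) hii = hx[k];
      }
      if (hii <= 0.0) stop("non-positive diagonal in H-inverse at animal %d", i + 1);
      const std::vector<int>& recs = an_rec[i];
      double rhs = -(hdot - hii * a[i]) / s2a;
      for (size_t k = 0; k < recs.size(); ++k) rhs += (e[recs[k]] + a[i]) / s2e;
      double prec = recs.size() / s2e + hii / s2a;
      if (!R_finite(prec) || prec <= 0.0)
        stop("non-finite full-conditional precision at iteration %d", it);
      double anew = rhs / prec + norm_rand() / std::sqrt(prec);
      double diff = a[i] - anew;
      for (size_t k = 0; k < recs.size(); ++k) e[recs[k]] += diff;
      a[i] = anew;
    }

    // variance components: scaled-inverse-chi-square full conditionals
    if (!fix_variances) {
      double qf = quad_form(hi, hp, hx, a.data(), n_animals);
      double df_a = n_animals + nu_a;
      if (df_a > 0.0) s2a = (qf + nu_a * scale_a) / R::rchisq(df_a);
      if (s2a < 1e-12) s2a = 1e-12;
      if (!threshold) {
        double sse = 0.0;
        for (int r = 0; r < n_rec; ++r) sse += e[r] * e[r];
        double df_e = n_rec + nu_e;
        if (df_e > 0.0) s2e = (sse + nu_e * scale_e) / R::rchisq(df_e);
        if (s2e < 1e-12) s2e = 1e-12;
      }
    }

    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      keep_s2a[kept] = s2a;
      keep_s2e[kept] = s2e;
      for (int i = 0; i < n_animals; ++i) keep_a(kept, i) = a[i];
      ++kept;
    }
  }

  return List::create(_["sigma2a"] = keep_s2a,
                      _["sigma2e"] = keep_s2e,
                      _["a_draws"] = keep_a,
                      _["n_kept"] = kept);
}
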