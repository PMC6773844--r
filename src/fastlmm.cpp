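// Profiled maximum-likelihood fitter for the Gaussian linear mixed model with
// a single random intercept (grouping = participant). Used where many fits of
// the same model structure are needed (per-channel maps, permutation nulls).
//
// Model: y = X beta + Z b + e,  b_g ~ N(0, sigma_b^2), e ~ N(0, sigma_e^2 I).
// For a fixed variance ratio rho = sigma_b^2 / sigma_e^2 the GLS solution and
// the error variance profile out in closed form via the per-group Woodbury
// identity  V_g^{-1} = (I - c_g J) / sigma_e^2 with c_g = rho / (1 + n_g rho),
// leaving a smooth 1-D deviance in rho that is minimised by golden-section
// search on the log scale (with an explicit check of the rho = 0 boundary).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct ProfileFit {
  arma::vec beta;
  arma::mat XtWXinv;
  double sigma2;   // ML estimate of sigma_e^2
  double deviance; // -2 log likelihood
  bool ok;
};

// Evaluate the profile deviance at a given rho. Rows of X / y must be sorted
// by group; sizes holds the per-group row counts.
ProfileFit profile_at(const arma::mat& X, const arma::vec& y,
                      const arma::uvec& sizes, double rho,
                      bool need_cov) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  arma::mat XtWX(p, p, arma::fill::zeros);
  arma::vec XtWy(p, arma::fill::zeros);
  double ytWy = 0.0, ldet = 0.0;
  arma::uword off = 0;
  for (arma::uword g = 0; g < sizes.n_elem; ++g) {
    const arma::uword ng = sizes[g];
    const arma::mat Xg = X.rows(off, off + ng - 1);
    const arma::vec yg = y.subvec(off, off + ng - 1);
    const double c = rho / (1.0 + ng * rho);
    const arma::vec sx = arma::sum(Xg, 0).t();
    const double sy = arma::accu(yg);
    XtWX += Xg.t() * Xg - c * (sx * sx.t());
    XtWy += Xg.t() * yg - c * sx * sy;
    ytWy += arma::dot(yg, yg) - c * sy * sy;
    ldet += std::log1p(ng * rho);
    off += ng;
  }
  ProfileFit out;
  out.ok = arma::solve(out.beta, XtWX, XtWy, arma::solve_opts::likely_sympd);
  if (!out.ok) { out.deviance = R_PosInf; return out; }
  double rss = ytWy - arma::dot(out.beta, XtWy);
  if (rss <= 0) rss = 1e-300; // numerically zero residual
  out.sigma2 = rss / n;
  out.deviance = n * std::log(2.0 * M_PI * out.sigma2) + ldet + n;
  if (need_cov) out.ok = arma::inv_sympd(out.XtWXinv, XtWX);
  return out;
}

double dev_only(const arma::mat& X, const arma::vec& y,
                const arma::uvec& sizes, double rho) {
  return profile_at(X, y, sizes, rho, false).deviance;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".fit_ri_ml")]]
List fit_ri_ml(const arma::mat& X, const arma::mat& Y,
               const arma::uvec& sizes) {
  const arma::uword p = X.n_cols, K = Y.n_cols;
  if (arma::accu(sizes) != X.n_rows)
    stop("group sizes do not sum to the number of rows");
  arma::mat beta(p, K), se(p, K), tval(p, K);
  arma::vec logLik(K), sigma_e(K), sigma_b(K);
  LogicalVector conv(K);

  const double lo = -14.0, hi = 14.0; // log(rho) search bracket
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;

  for (arma::uword k = 0; k < K; ++k) {
    const arma::vec y = Y.col(k);
    // golden-section search on log(rho)
    double a = lo, b = hi;
    double c1 = b - gr * (b - a), c2 = a + gr * (b - a);
    double f1 = dev_only(X, y, sizes, std::exp(c1));
    double f2 = dev_only(X, y, sizes, std::exp(c2));
    for (int it = 0; it < 80 && (b - a) > 1e-7; ++it) {
      if (f1 < f2) { b = c2; c2 = c1; f2 = f1; c1 = b - gr * (b - a);
                     f1 = dev_only(X, y, sizes, std::exp(c1)); }
      else         { a = c1; c1 = c2; f1 = f2; c2 = a + gr * (b - a);
                     f2 = dev_only(X, y, sizes, std::exp(c2)); }
    }
    double rho = std::exp((a + b) / 2.0);
    double dev_int = dev_only(X, y, sizes, rho);
    double dev_bnd = dev_only(X, y, sizes, 0.0);
    if (dev_bnd <= dev_int) rho = 0.0; // boundary (no between-group variance)
    ProfileFit fit = profile_at(X, y, sizes, rho, true);
    conv[k] = fit.ok && std::isfinite(fit.deviance);
    beta.col(k) = fit.beta;
    for (arma::uword j = 0; j < p; ++j)
      se(j, k) = std::sqrt(fit.sigma2 * fit.XtWXinv(j, j));
    tval.col(k) = beta.col(k) / se.col(k);
    logLik[k] = -0.5 * fit.deviance;
    sigma_e[k] = std::sqrt(fit.sigma2);
    sigma_b[k] = std::sqrt(fit.sigma2 * rho);
  }
  return List::create(_["beta"] = beta, _["se"] = se, _["t"] = tval,
                      _["logLik"] = logLik, _["sigma_e"] = sigma_e,
                      _["sigma_b"] = sigma_b, _["converged"] = conv);
}
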