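// Negative-binomial GLM fitting by IRLS with log link and fixed per-gene
// dispersion, plus the Cox-Reid adjusted profile log-likelihood used for
// dispersion estimation. Genes are rows; all genes share the design matrix
// and per-sample offsets (log effective library sizes).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double PHI_POISSON = 1e-10; // below this, treat as Poisson
static const double ETA_MAX = 50.0;      // clamp linear predictor
static const double MU_MIN = 1e-10;

struct GeneFit {
  vec beta;
  vec mu;
  double deviance;
  double loglik;
  double cr_adj; // 0.5 * log det(X' W X)
  bool converged;
  bool singular;
  int iter;
};

static double nb_loglik(const vec &y, const vec &mu, double phi) {
  double ll = 0.0;
  if (phi < PHI_POISSON) {
    for (uword i = 0; i < y.n_elem; ++i)
      ll += R::dpois(y[i], std::max(mu[i], MU_MIN), 1);
  } else {
    double r = 1.0 / phi;
    for (uword i = 0; i < y.n_elem; ++i)
      ll += R::dnbinom_mu(y[i], r, std::max(mu[i], MU_MIN), 1);
  }
  return ll;
}

static double nb_deviance(const vec &y, const vec &mu, double phi) {
  double dev = 0.0;
  for (uword i = 0; i < y.n_elem; ++i) {
    double yi = y[i];
    double mui = std::max(mu[i], MU_MIN);
    if (phi < PHI_POISSON) {
      double t = (yi > 0) ? yi * std::log(yi / mui) - (yi - mui) : mui;
      dev += 2.0 * t;
    } else {
      double t1 = (yi > 0) ? yi * std::log(yi / mui) : 0.0;
      double t2 = (yi + 1.0 / phi) *
                  std::log((1.0 + phi * yi) / (1.0 + phi * mui));
      dev += 2.0 * (t1 - t2);
    }
  }
  return dev;
}

// IRLS for one gene. beta0 may be empty (cold start from a log-linear OLS).
static GeneFit irls_one(const vec &y, const mat &X, const vec &offset,
                        double phi, double eps, int maxit) {
  const uword p = X.n_cols;
  GeneFit out;
  out.singular = false;
  out.converged = false;

  // cold start: OLS of log counts (damped at zero) minus offset
  vec z0 = log(y + 0.5) - offset;
  mat XtX = X.t() * X;
  vec beta;
  if (!solve(beta, XtX, X.t() * z0, solve_opts::no_approx)) {
    beta = pinv(XtX) * (X.t() * z0);
    out.singular = true;
  }

  vec eta = clamp(X * beta + offset, -ETA_MAX, ETA_MAX);
  vec mu = exp(eta);
  int it = 0;
  for (; it < maxit; ++it) {
    vec w = (phi < PHI_POISSON) ? mu : mu / (1.0 + phi * mu);
    w = clamp(w, 1e-12, datum::inf);
    vec z = (eta - offset) + (y - mu) / clamp(mu, MU_MIN, datum::inf);
    mat Xw = X.each_col() % w;
    mat A = X.t() * Xw;
    vec b = Xw.t() * z;
    vec beta_new;
    if (!solve(beta_new, A, b, solve_opts::no_approx)) {
      A.diag() += 1e-8; // ridge rescue for degenerate cells
      out.singular = true;
      if (!solve(beta_new, A, b, solve_opts::no_approx)) {
        beta_new = beta;
        break;
      }
    }
    if (!beta_new.is_finite()) {
      beta_new = 0.5 * (beta + beta_new.replace(datum::nan, 0.0));
    }
    vec eta_new = clamp(X * beta_new + offset, -ETA_MAX, ETA_MAX);
    double delta = max(abs(eta_new - eta) / (abs(eta) + 1.0));
    beta = beta_new;
    eta = eta_new;
    mu = exp(eta);
    if (delta < eps) {
      out.converged = true;
      ++it;
      break;
    }
  }

  out.beta = beta;
  out.mu = mu;
  out.iter = it;
  out.deviance = nb_deviance(y, mu, phi);
  out.loglik = nb_loglik(y, mu, phi);

  vec w = (phi < PHI_POISSON) ? mu : mu / (1.0 + phi * mu);
  mat A = X.t() * (X.each_col() % clamp(w, 1e-12, datum::inf));
  double ldet, sign;
  log_det(ldet, sign, A);
  out.cr_adj = (sign > 0) ? 0.5 * ldet : datum::nan;
  (void)p;
  return out;
}

// [[Rcpp::export(name = ".nb_glm_fit_cpp")]]
Rcpp::List nb_glm_fit_cpp(const arma::mat &Y, const arma::mat &X,
                          const arma::vec &offset, const arma::vec &phi,
                          double eps = 1e-8, int maxit = 100,
                          bool covariance = false) {
  const uword G = Y.n_rows, S = Y.n_cols, p = X.n_cols;
  mat beta(G, p), mu(G, S);
  vec dev(G), ll(G);
  Rcpp::LogicalVector conv(G), sing(G);
  Rcpp::IntegerVector iters(G);
  cube covb;
  if (covariance) covb.set_size(p, p, G);

  for (uword g = 0; g < G; ++g) {
    GeneFit f = irls_one(Y.row(g).t(), X, offset, phi[g], eps, maxit);
    beta.row(g) = f.beta.t();
    mu.row(g) = f.mu.t();
    dev[g] = f.deviance;
    ll[g] = f.loglik;
    conv[g] = f.converged;
    sing[g] = f.singular;
    iters[g] = f.iter;
    if (covariance) {
      vec w = (phi[g] < PHI_POISSON) ? f.mu : f.mu / (1.0 + phi[g] * f.mu);
      mat A = X.t() * (X.each_col() % clamp(w, 1e-12, datum::inf));
      mat V;
      if (!inv_sympd(V, A)) V = pinv(A);
      covb.slice(g) = V;
    }
  }
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("beta") = beta, Rcpp::Named("fitted") = mu,
      Rcpp::Named("deviance") = dev, Rcpp::Named("loglik") = ll,
      Rcpp::Named("converged") = conv, Rcpp::Named("singular") = sing,
      Rcpp::Named("iter") = iters);
  if (covariance) out["cov"] = covb;
  return out;
}

// Adjusted profile log-likelihood at one dispersion per gene:
// APL_g(phi) = loglik at IRLS-fitted means - 0.5 log det(X' W X).
// [[Rcpp::export(name = ".nb_apl_cpp")]]
arma::vec nb_apl_cpp(const arma::mat &Y, const arma::mat &X,
                     const arma::vec &offset, const arma::vec &phi,
                     double eps = 1e-8, int maxit = 100) {
  const uword G = Y.n_rows;
  vec apl(G);
  for (uword g = 0; g < G; ++g) {
    GeneFit f = irls_one(Y.row(g).t(), X, offset, phi[g], eps, maxit);
    apl[g] = (f.converged || f.iter > 0) ? f.loglik - f.cr_adj : datum::nan;
    if (!std::isfinite(f.cr_adj)) apl[g] = datum::nan;
  }
  return apl;
}

// APL evaluated on a shared grid of dispersions; returns genes x grid.
// [[Rcpp::export(name = ".nb_apl_grid_cpp")]]
arma::mat nb_apl_grid_cpp(const arma::mat &Y, const arma::mat &X,
                          const arma::vec &offset, const arma::vec &phi_grid,
                          double eps = 1e-8, int maxit = 100) {
  const uword G = Y.n_rows, K = phi_grid.n_elem;
  mat apl(G, K);
  for (uword k = 0; k < K; ++k) {
    vec phis(G);
    phis.fill(phi_grid[k]);
    apl.col(k) = nb_apl_cpp(Y, X, offset, phis, eps, maxit);
  }
  return apl;
}
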