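// EM for Gaussian mixture models with full or diagonal covariances.
//
// Performance notes: the E-step is dominated by one triangular solve per
// component (n x d against the Cholesky factor of Sigma_k) and the M-step by
// one crossprod per component; both map onto BLAS level-3 calls, which keeps
// scans over K = 2..50 tractable at n of a few thousand and d = 54.
//
// Randomness comes from R's RNG (RNGScope), so set.seed() on the R side
// makes every fit reproducible.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// kmeans++ style seeding: first center uniform, then each subsequent center
// drawn with probability proportional to squared distance to nearest chosen.
static arma::uvec seed_centers(const arma::mat& X, int K) {
  int n = X.n_rows;
  arma::uvec idx(K);
  idx(0) = (arma::uword)(unif_rand() * n);
  if (idx(0) >= (arma::uword)n) idx(0) = n - 1;
  arma::vec d2 = arma::sum(arma::square(X.each_row() - X.row(idx(0))), 1);
  for (int k = 1; k < K; ++k) {
    double tot = arma::accu(d2);
    arma::uword pick;
    if (tot <= 0.0) {
      pick = (arma::uword)(unif_rand() * n);
      if (pick >= (arma::uword)n) pick = n - 1;
    } else {
      double u = unif_rand() * tot, cum = 0.0;
      pick = n - 1;
      for (int i = 0; i < n; ++i) {
        cum += d2(i);
        if (cum >= u) { pick = i; break; }
      }
    }
    idx(k) = pick;
    arma::vec d2new = arma::sum(arma::square(X.each_row() - X.row(pick)), 1);
    d2 = arma::min(d2, d2new);
  }
  return idx;
}

// Lloyd refinement of the seeded centers, run to (near) convergence: EM
// with full covariances in high dimension is sensitive to its starting
// partition, and Lloyd iterations are cheap by comparison.
static arma::mat lloyd_refine(const arma::mat& X, arma::mat centers, int iters) {
  int n = X.n_rows, K = centers.n_rows;
  arma::vec xsq = arma::sum(arma::square(X), 1);
  arma::uvec prev(n, arma::fill::zeros);
  for (int it = 0; it < iters; ++it) {
    arma::vec csq = arma::sum(arma::square(centers), 1);
    arma::mat D = arma::repmat(xsq, 1, K) - 2.0 * X * centers.t() +
                  arma::repmat(csq.t(), n, 1);
    arma::uvec lab = arma::index_min(D, 1);
    for (int k = 0; k < K; ++k) {
      arma::uvec members = arma::find(lab == (arma::uword)k);
      if (members.n_elem > 0)
        centers.row(k) = arma::mean(X.rows(members), 0);
    }
    if (it > 0 && arma::all(lab == prev)) break;
    prev = lab;
  }
  return centers;
}

struct GmmState {
  arma::vec phi;       // K mixing weights
  arma::mat mu;        // K x d means
  arma::cube sigma;    // d x d x K (full) or d x 1 x K (diag variances)
  bool diag;
};

// log component densities -> n x K matrix
static arma::mat log_dens(const arma::mat& X, const GmmState& st) {
  int n = X.n_rows, d = X.n_cols, K = st.mu.n_rows;
  arma::mat LD(n, K);
  for (int k = 0; k < K; ++k) {
    arma::mat Xc = X.each_row() - st.mu.row(k);
    if (st.diag) {
      arma::vec v = st.sigma.slice(k).col(0);
      double logdet = arma::accu(arma::log(v));
      arma::mat Z = Xc.each_row() / arma::sqrt(v.t());
      LD.col(k) = -0.5 * (arma::sum(arma::square(Z), 1) + logdet + d * LOG2PI);
    } else {
      arma::mat R;
      bool ok = arma::chol(R, st.sigma.slice(k));
      if (!ok) {
        arma::mat S = st.sigma.slice(k);
        S.diag() += 1e-6 * arma::trace(S) / d + 1e-12;
        ok = arma::chol(R, S);
        if (!ok) stop("covariance not positive definite after regularization");
      }
      double logdet = 2.0 * arma::accu(arma::log(R.diag()));
      arma::mat Z = arma::solve(arma::trimatl(R.t()), Xc.t());
      LD.col(k) = (-0.5 * (arma::sum(arma::square(Z), 0).t() + logdet + d * LOG2PI));
    }
  }
  return LD;
}

// responsibilities + log-likelihood via row-wise log-sum-exp
static double e_step(const arma::mat& LD, const arma::vec& phi, arma::mat& resp) {
  arma::mat A = LD.each_row() + arma::log(phi.t());
  arma::vec m = arma::max(A, 1);
  arma::mat E = arma::exp(A.each_col() - m);
  arma::vec s = arma::sum(E, 1);
  resp = E.each_col() / s;
  return arma::accu(m + arma::log(s));
}

static void m_step(const arma::mat& X, const arma::mat& resp, double ridge,
                   GmmState& st) {
  int n = X.n_rows, d = X.n_cols, K = resp.n_cols;
  arma::rowvec w = arma::sum(resp, 0);
  for (int k = 0; k < K; ++k) {
    double wk = w(k);
    if (wk < 1e-10) {
      // collapsed component: re-seed on a random data point, broad covariance
      int i = (int)(unif_rand() * n);
      if (i >= n) i = n - 1;
      st.mu.row(k) = X.row(i);
      arma::rowvec gv = arma::var(X, 0, 0);
      if (st.diag) st.sigma.slice(k).col(0) = gv.t() + ridge;
      else { st.sigma.slice(k) = arma::diagmat(gv); st.sigma.slice(k).diag() += ridge; }
      st.phi(k) = 1.0 / n;
      continue;
    }
    st.phi(k) = wk / n;
    arma::rowvec mu = (resp.col(k).t() * X) / wk;
    st.mu.row(k) = mu;
    arma::mat Xc = X.each_row() - mu;
    if (st.diag) {
      arma::vec v = (arma::sum(arma::square(Xc) % arma::repmat(resp.col(k), 1, d), 0).t()) / wk;
      st.sigma.slice(k).col(0) = v + ridge;
    } else {
      arma::mat Xw = Xc.each_col() % arma::sqrt(resp.col(k));
      arma::mat S = (Xw.t() * Xw) / wk;
      S.diag() += ridge;
      st.sigma.slice(k) = S;
    }
  }
  st.phi /= arma::accu(st.phi);
}

static GmmState init_state(const arma::mat& X, int K, bool diag, double ridge) {
  int d = X.n_cols;
  GmmState st;
  st.diag = diag;
  arma::uvec idx = seed_centers(X, K);
  st.mu = lloyd_refine(X, X.rows(idx), 30);
  st.phi = arma::vec(K, arma::fill::value(1.0 / K));
  arma::rowvec gv = arma::var(X, 0, 0);
  gv.replace(0.0, 1e-12);
  st.sigma = arma::cube(diag ? d : d, diag ? 1 : d, K);
  for (int k = 0; k < K; ++k) {
    if (diag) st.sigma.slice(k).col(0) = gv.t() + ridge;
    else { st.sigma.slice(k) = arma::diagmat(gv); st.sigma.slice(k).diag() += ridge; }
  }
  return st;
}

// run EM from a given state; fills ll_trace, returns final log-likelihood
static double run_em(const arma::mat& X, GmmState& st, double ridge, double tol,
                     int max_iter, arma::mat& resp, std::vector<double>& ll_trace,
                     bool& converged) {
  double ll = -arma::datum::inf;
  converged = false;
  for (int it = 0; it < max_iter; ++it) {
    arma::mat LD = log_dens(X, st);
    double ll_new = e_step(LD, st.phi, resp);
    ll_trace.push_back(ll_new);
    if (std::isfinite(ll) &&
        std::abs(ll_new - ll) < tol * (std::abs(ll_new) + 1e-10)) {
      ll = ll_new;
      converged = true;
      break;
    }
    ll = ll_new;
    m_step(X, resp, ridge, st);
  }
  return ll;
}

//' @noRd
// [[Rcpp::export(name = ".gmm_em_cpp")]]
List gmm_em_cpp(const arma::mat& X, int K, bool diag_cov, double ridge,
                double tol, int max_iter, int n_restarts, int restart_iters) {
  int n = X.n_rows;
  if (K < 1) stop("K must be >= 1");
  if (K > n) stop("K exceeds the number of observations");
  RNGScope rngScope;

  // Stage 1: short EM runs from each random start, keep the best by
  // log-likelihood (equivalently BIC, since K is fixed across restarts).
  GmmState best;
  double best_ll = -arma::datum::inf;
  arma::mat resp;
  for (int r = 0; r < n_restarts; ++r) {
    GmmState st = init_state(X, K, diag_cov, ridge);
    std::vector<double> trace;
    bool conv = false;
    double ll = run_em(X, st, ridge, tol, std::min(restart_iters, max_iter),
                       resp, trace, conv);
    if (ll > best_ll) { best_ll = ll; best = st; }
  }
  // Stage 2: run the winning start to convergence.
  std::vector<double> trace;
  bool converged = false;
  best_ll = run_em(X, best, ridge, tol, max_iter, resp, trace, converged);

  arma::uvec lab = arma::index_max(resp, 1) + 1;  // ties -> lowest index
  int d = X.n_cols;
  int n_params = (K - 1) + K * d + (diag_cov ? K * d : K * d * (d + 1) / 2);

  List covs(K);
  for (int k = 0; k < K; ++k) {
    if (diag_cov) covs[k] = NumericVector(wrap(best.sigma.slice(k).col(0)));
    else covs[k] = wrap(best.sigma.slice(k));
  }
  return List::create(
    _["weights"] = best.phi, _["means"] = best.mu, _["covariances"] = covs,
    _["log_likelihood"] = best_ll, _["responsibilities"] = resp,
    _["labels"] = IntegerVector(wrap(arma::conv_to<arma::ivec>::from(lab))),
    _["n_params"] = n_params, _["ll_trace"] = trace,
    _["converged"] = converged);
}
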