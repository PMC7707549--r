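// Collapsed Gibbs sampler for the T-augmented Gaussian mixture with
// overfitted novelty components. Component means/covariances are
// marginalised under a conjugate Normal-Inverse-Wishart prior and the
// mixture weights under a symmetric Dirichlet, so the per-protein
// conditionals only involve sufficient statistics and posterior-predictive
// multivariate-t densities. All randomness flows through R's RNG so that
// set.seed() in R gives bit-reproducible chains.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct NIWCache {
  bool valid = false;
  double df = 0.0, lognorm = 0.0;
  arma::vec mu_n;
  arma::mat chol_upper;  // upper-triangular U with U'U = predictive scale
};

// Cholesky with a trace-scaled diagonal jitter fallback.
arma::mat safe_chol(arma::mat S, int L) {
  arma::mat U;
  if (arma::chol(U, S)) return U;
  double jit = 1e-8 * arma::trace(S) / L;
  if (jit <= 0.0) jit = 1e-12;
  S.diag() += jit;
  if (arma::chol(U, S)) return U;
  stop("scale matrix is not positive definite even after jitter; consider a diagonal outlier scale or stronger prior");
  return U;  // unreachable
}

// log multivariate-t density given a precomputed upper Cholesky of the scale.
double mvt_logdens(const arma::vec& x, const arma::vec& mu, double df,
                   const arma::mat& chol_upper, double lognorm) {
  arma::vec d = arma::solve(arma::trimatl(chol_upper.t()), x - mu);
  double delta = arma::dot(d, d);
  int L = x.n_elem;
  return lognorm - 0.5 * (df + L) * std::log1p(delta / df);
}

double mvt_lognorm(double df, int L, const arma::mat& chol_upper) {
  double logdet = 2.0 * arma::sum(arma::log(chol_upper.diag()));
  return std::lgamma(0.5 * (df + L)) - std::lgamma(0.5 * df) -
         0.5 * L * std::log(df * M_PI) - 0.5 * logdet;
}

}  // namespace

// One fitted-state container manipulated in place during the run.
class NTagmSampler {
 public:
  const arma::mat& X;
  int N, L, K, Kmax;
  arma::vec mu0;
  double lambda0, nu0, alpha, u, v;
  arma::mat S0;
  arma::ivec z, phi, n_z, n1;
  arma::vec eps_state;  // length 1, current epsilon
  arma::mat sumx;       // L x Kmax
  arma::cube scat;      // L x L x Kmax
  std::vector<NIWCache> cache;
  arma::vec out_logdens;  // per-protein outlier t log-density (fixed params)
  LogicalVector fixed_z;
  bool fix_marker_phi;

  NTagmSampler(const arma::mat& X_, arma::ivec z0, arma::ivec phi0,
               LogicalVector fixed_z_, int K_, int Kmax_, const arma::vec& mu0_,
               double lambda0_, double nu0_, const arma::mat& S0_, double alpha_,
               double kappa, const arma::vec& M, const arma::mat& V, double u_,
               double v_, double eps0, bool fix_marker_phi_)
      : X(X_), N(X_.n_rows), L(X_.n_cols), K(K_), Kmax(Kmax_), mu0(mu0_),
        lambda0(lambda0_), nu0(nu0_), alpha(alpha_), u(u_), v(v_), S0(S0_),
        z(z0), phi(phi0), fixed_z(fixed_z_), fix_marker_phi(fix_marker_phi_) {
    eps_state.set_size(1);
    eps_state[0] = eps0;
    n_z.zeros(Kmax);
    n1.zeros(Kmax);
    sumx.zeros(L, Kmax);
    scat.zeros(L, L, Kmax);
    cache.resize(Kmax);
    for (int i = 0; i < N; ++i) {
      n_z[z[i]] += 1;
      if (phi[i] == 1) add_stats(z[i], i);
    }
    // outlier density is parameter-free during the run: precompute
    arma::mat Uv = safe_chol(V, L);
    double ln = mvt_lognorm(kappa, L, Uv);
    out_logdens.set_size(N);
    for (int i = 0; i < N; ++i)
      out_logdens[i] = mvt_logdens(X.row(i).t(), M, kappa, Uv, ln);
  }

  void add_stats(int k, int i) {
    arma::vec x = X.row(i).t();
    n1[k] += 1;
    sumx.col(k) += x;
    scat.slice(k) += x * x.t();
    cache[k].valid = false;
  }
  void remove_stats(int k, int i) {
    arma::vec x = X.row(i).t();
    n1[k] -= 1;
    sumx.col(k) -= x;
    scat.slice(k) -= x * x.t();
    cache[k].valid = false;
  }

  const NIWCache& predictive(int k) {
    NIWCache& c = cache[k];
    if (!c.valid) {
      double n = n1[k];
      double lambda_n = lambda0 + n, nu_n = nu0 + n;
      arma::vec mu_n = (lambda0 * mu0 + sumx.col(k)) / lambda_n;
      arma::mat S_n = S0 + scat.slice(k) + lambda0 * (mu0 * mu0.t()) -
                      lambda_n * (mu_n * mu_n.t());
      S_n = 0.5 * (S_n + S_n.t());
      double df = nu_n - L + 1;
      if (df <= 0) stop("invalid prior: nu0 must exceed L - 1");
      arma::mat Sigma = S_n * (lambda_n + 1.0) / (lambda_n * df);
      c.chol_upper = safe_chol(Sigma, L);
      c.mu_n = mu_n;
      c.df = df;
      c.lognorm = mvt_lognorm(df, L, c.chol_upper);
      c.valid = true;
    }
    return c;
  }

  double pred_logdens(int k, int i) {
    const NIWCache& c = predictive(k);
    return mvt_logdens(X.row(i).t(), c.mu_n, c.df, c.chol_upper, c.lognorm);
  }

  // joint (z_i, phi_i) update for an unlabelled protein; returns the
  // normalised per-component (z=k, phi=1) probabilities in alloc.
  void update_unlabelled(int i, arma::vec& alloc) {
    double eps = eps_state[0];
    n_z[z[i]] -= 1;
    if (phi[i] == 1) remove_stats(z[i], i);

    arma::vec lp(Kmax + 1);
    double log1m = std::log1p(-eps);
    for (int k = 0; k < Kmax; ++k)
      lp[k] = std::log(n_z[k] + alpha) + log1m + pred_logdens(k, i);
    lp[Kmax] = (eps > 0.0)
                   ? std::log(eps) + out_logdens[i] +
                         std::log((double)(N - 1) + Kmax * alpha)
                   : R_NegInf;
    if (!lp.head(Kmax).is_finite())
      stop("non-finite conditional log-density for protein index %d", i + 1);

    double m = lp.max();
    arma::vec p = arma::exp(lp - m);
    p /= arma::accu(p);
    alloc = p.head(Kmax);

    double r = R::runif(0.0, 1.0), acc = 0.0;
    int pick = Kmax;
    for (int k = 0; k <= Kmax; ++k) {
      acc += p[k];
      if (r <= acc) { pick = k; break; }
    }
    if (pick == Kmax) {
      phi[i] = 0;
      // latent component label under the outlier indicator, drawn from the
      // conditional prior so component-indexed outlier terms stay defined
      double tot = (double)(N - 1) + Kmax * alpha;
      double r2 = R::runif(0.0, 1.0) * tot, a2 = 0.0;
      int zk = Kmax - 1;
      for (int k = 0; k < Kmax; ++k) {
        a2 += n_z[k] + alpha;
        if (r2 <= a2) { zk = k; break; }
      }
      z[i] = zk;
    } else {
      phi[i] = 1;
      z[i] = pick;
    }
    n_z[z[i]] += 1;
    if (phi[i] == 1) add_stats(z[i], i);
  }

  // labelled proteins keep z fixed; phi is resampled against their own class
  void update_labelled_phi(int i) {
    double eps = eps_state[0];
    int k = z[i];
    if (phi[i] == 1) remove_stats(k, i);
    double lp1 = std::log1p(-eps) + pred_logdens(k, i);
    double lp0 = (eps > 0.0) ? std::log(eps) + out_logdens[i] : R_NegInf;
    double m = std::max(lp1, lp0);
    double p1 = std::exp(lp1 - m);
    p1 = p1 / (p1 + std::exp(lp0 - m));
    phi[i] = (R::runif(0.0, 1.0) <= p1) ? 1 : 0;
    if (phi[i] == 1) add_stats(k, i);
  }

  void sweep(arma::mat& alloc_buf, const arma::ivec& unlab_pos) {
    arma::vec alloc(Kmax);
    for (int i = 0; i < N; ++i) {
      if (!fixed_z[i]) {
        update_unlabelled(i, alloc);
        alloc_buf.row(unlab_pos[i]) = alloc.t();
      } else if (!fix_marker_phi) {
        update_labelled_phi(i);
      }
    }
    int n0 = N - arma::accu(phi);
    eps_state[0] = R::rbeta(u + n0, v + (N - n0));
  }

  int occupied() const { return arma::accu(n1 > 0); }
};

// [[Rcpp::export(name = ".ntagm_run_cpp")]]
List ntagm_run_cpp(const arma::mat& X, arma::ivec z0, arma::ivec phi0,
                   LogicalVector fixed_z, int K, int Kmax, const arma::vec& mu0,
                   double lambda0, double nu0, const arma::mat& S0, double alpha,
                   double kappa, const arma::vec& M, const arma::mat& V,
                   double u, double v, double eps0, int n_iter, int burn,
                   int thin, bool fix_marker_phi) {
  NTagmSampler s(X, z0 - 1, phi0, fixed_z, K, Kmax, mu0, lambda0, nu0, S0,
                 alpha, kappa, M, V, u, v, eps0, fix_marker_phi);
  int N = s.N;
  int n_unlab = 0;
  arma::ivec unlab_pos(N);
  unlab_pos.fill(-1);
  for (int i = 0; i < N; ++i)
    if (!fixed_z[i]) unlab_pos[i] = n_unlab++;

  int T = (n_iter - burn) / thin;
  arma::imat z_draws(T, N), phi_draws(T, N);
  arma::vec eps_draws(T);
  arma::ivec occ_trace(T);
  arma::cube alloc_draws(n_unlab, Kmax, T);
  arma::mat alloc_buf(std::max(n_unlab, 1), Kmax, arma::fill::zeros);

  int t_out = 0;
  for (int it = 1; it <= n_iter; ++it) {
    s.sweep(alloc_buf, unlab_pos);
    if (it > burn && ((it - burn) % thin == 0) && t_out < T) {
      z_draws.row(t_out) = (s.z + 1).t();
      phi_draws.row(t_out) = s.phi.t();
      eps_draws[t_out] = s.eps_state[0];
      occ_trace[t_out] = s.occupied();
      if (n_unlab > 0) alloc_draws.slice(t_out) = alloc_buf;
      ++t_out;
    }
    if (it % 256 == 0) checkUserInterrupt();
  }

  return List::create(
      _["z_draws"] = z_draws, _["phi_draws"] = phi_draws,
      _["eps_draws"] = eps_draws, _["occupied_trace"] = occ_trace,
      _["alloc_probs"] = alloc_draws,
      _["final"] = List::create(_["z"] = arma::ivec(s.z + 1),
                                _["phi"] = s.phi,
                                _["eps"] = s.eps_state[0]));
}
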