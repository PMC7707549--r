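# Independent oracles used by the tests. Everything here is deliberately
# written along different code paths from the package: textbook two-pass
# covariance, grid quadrature, a closed-form Normal-Inverse-Wishart marginal
# likelihood, full enumeration of the joint (z, phi) posterior, and
# exhaustive set-partition search for the PEAR optimum.

# textbook two-pass covariance (unbiased)
oracle_cov <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  S <- matrix(0, ncol(X), ncol(X))
  for (i in seq_len(n)) {
    d <- X[i, ] - mu
    S <- S + outer(d, d)
  }
  S / (n - 1)
}

# trapezoid mass of exp(logf) over a tensor grid (1-3 dims)
grid_mass <- function(logf, grids) {
  steps <- vapply(grids, function(g) g[2] - g[1], numeric(1))
  pts <- as.matrix(expand.grid(grids))
  sum(exp(apply(pts, 1, logf))) * prod(steps)
}

# log multivariate gamma
lmvgamma <- function(a, p) {
  p * (p - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

# closed-form NIW marginal likelihood of a data matrix (rows = obs)
oracle_niw_logml <- function(X, prior) {
  X <- rbind(X)
  n <- nrow(X)
  if (n == 0) return(0)
  L <- ncol(X)
  lambda_n <- prior$lambda0 + n
  nu_n <- prior$nu0 + n
  xbar <- colMeans(X)
  mu_n <- (prior$lambda0 * prior$mu0 + n * xbar) / lambda_n
  S_n <- prior$S0 + crossprod(X) + prior$lambda0 * outer(prior$mu0, prior$mu0) -
    lambda_n * outer(mu_n, mu_n)
  -0.5 * n * L * log(pi) +
    lmvgamma(nu_n / 2, L) - lmvgamma(prior$nu0 / 2, L) +
    0.5 * prior$nu0 * as.numeric(determinant(as.matrix(prior$S0))$modulus) -
    0.5 * nu_n * as.numeric(determinant(as.matrix(S_n))$modulus) +
    0.5 * L * (log(prior$lambda0) - log(lambda_n))
}

# univariate NIW marginal likelihood by brute 2-D quadrature over (mu, s2);
# prior here is mu ~ N(mu0, s2/lambda0), s2 ~ Inv-Gamma-type scaled inverse
# chi-square implied by the Inverse-Wishart with nu0, S0 (L = 1)
oracle_niw_logml_quadrature <- function(x, prior) {
  stopifnot(length(prior$mu0) == 1)
  nu0 <- prior$nu0; S0 <- as.numeric(prior$S0); l0 <- prior$lambda0; m0 <- prior$mu0
  log_iw <- function(s2) {
    # Inverse-Wishart_1(nu0, S0): density prop to s2^-(nu0/2+1) exp(-S0/(2 s2))
    0.5 * nu0 * log(S0 / 2) - lgamma(nu0 / 2) - (nu0 / 2 + 1) * log(s2) - S0 / (2 * s2)
  }
  integrand <- function(mu, s2) {
    exp(log_iw(s2) + dnorm(mu, m0, sqrt(s2 / l0), log = TRUE) +
          sum(dnorm(x, mu, sqrt(s2), log = TRUE)))
  }
  inner <- function(s2) {
    stats::integrate(function(mu) vapply(mu, integrand, numeric(1), s2 = s2),
                     -60, 60, rel.tol = 1e-9)$value
  }
  log(stats::integrate(function(s2) vapply(s2, inner, numeric(1)),
                       1e-4, 400, rel.tol = 1e-8)$value)
}

# Exact joint posterior over (z, phi) for every protein, by enumeration.
# Labelled proteins have fixed z; phi is enumerated for them too unless
# fix_marker_phi. Returns configs (matrix of z then phi, unfixed slots
# varying) and normalised probabilities.
oracle_enumerate_posterior <- function(X, z_fixed, K_max, prior, alpha, u, v,
                                       kappa, M, V, fix_marker_phi = TRUE) {
  N <- nrow(X)
  labelled <- !is.na(z_fixed)
  g_log <- vapply(seq_len(N), function(i) {
    noveltytagm::student_logdensity(X[i, ], kappa, M, V)
  }, numeric(1))

  z_opts <- lapply(seq_len(N), function(i) if (labelled[i]) z_fixed[i] else seq_len(K_max))
  phi_opts <- lapply(seq_len(N), function(i) {
    if (labelled[i] && fix_marker_phi) 1L else c(0L, 1L)
  })
  grid <- expand.grid(c(z_opts, phi_opts), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- c(paste0("z", seq_len(N)), paste0("phi", seq_len(N)))

  logp <- apply(as.matrix(grid), 1, function(cfg) {
    z <- cfg[seq_len(N)]
    phi <- cfg[N + seq_len(N)]
    n_k <- tabulate(z, nbins = K_max)
    n0 <- sum(phi == 0)
    lp <- sum(lgamma(n_k + alpha)) - K_max * lgamma(alpha) +
      lbeta(u + n0, v + (N - n0)) - lbeta(u, v)
    for (k in seq_len(K_max)) {
      members <- which(z == k & phi == 1)
      if (length(members) > 0) {
        lp <- lp + oracle_niw_logml(X[members, , drop = FALSE], prior)
      }
    }
    lp + sum(g_log[phi == 0])
  })
  prob <- exp(logp - max(logp))
  grid$prob <- prob / sum(prob)
  grid
}

# all set partitions of 1..n as label vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, next_max) {
    i <- length(labels) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- labels
      return(invisible(NULL))
    }
    for (lab in seq_len(next_max + 1)) {
      rec(c(labels, lab), max(next_max, lab))
    }
  }
  rec(integer(0), 0L)
  out
}

# adjusted Rand index between two binary membership vectors, via mclust
binary_ari <- function(a, b) mclust::adjustedRandIndex(as.integer(a), as.integer(b))
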