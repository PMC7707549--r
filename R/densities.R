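# Log-space density kernels of the augmented mixture. These are the
# reference R implementations of the quantities the compiled sampler uses
# internally; they are exported so conditionals can be inspected, unit-tested
# and reused (e.g. by the chain initialiser).

chol_or_jitter <- function(sigma, what = "scale matrix") {
  U <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(U)) {
    jit <- 1e-8 * sum(diag(sigma)) / ncol(sigma)
    if (jit <= 0) jit <- 1e-12
    U <- tryCatch(chol(sigma + diag(jit, ncol(sigma))), error = function(e) NULL)
    if (is.null(U)) {
      abort(paste0(
        what, " is singular even after diagonal jitter; ",
        "consider a diagonal outlier scale or a stronger NIW prior (larger nu0/S0)"
      ))
    }
  }
  U
}

#' Multivariate Gaussian log-density
#'
#' Density `f(x | mu, Sigma)` of the component distributions of the mixture,
#' evaluated in log space via a Cholesky factorisation.
#'
#' @param x Numeric length-L vector (a protein profile).
#' @param mu Length-L mean vector.
#' @param sigma L x L positive-definite covariance.
#' @return The log-density, a scalar.
#' @export
gaussian_logdensity <- function(x, mu, sigma) {
  x <- as.numeric(x); mu <- as.numeric(mu)
  sigma <- as.matrix(sigma)
  L <- length(x)
  stopifnot(length(mu) == L, all(dim(sigma) == L))
  U <- tryCatch(chol(sigma), error = function(e) {
    abort(paste0(
      "covariance matrix is singular or not positive definite: ",
      conditionMessage(e),
      "; regularise it (e.g. add a small diagonal) before evaluating"
    ))
  })
  d <- backsolve(U, x - mu, transpose = TRUE)
  -0.5 * L * log(2 * pi) - sum(log(diag(U))) - 0.5 * sum(d^2)
}

#' Multivariate Student-t log-density
#'
#' Density `g(x | kappa, M, V)` of the heavy-tailed outlier component, with
#' `kappa` degrees of freedom, location `M` and scale matrix `V`.
#'
#' @param x Numeric length-L vector.
#' @param kappa Degrees of freedom (> 0), or an `outlier_params` object in
#'   which case `M` and `V` are taken from it.
#' @param M Length-L location vector.
#' @param V L x L positive-definite scale matrix.
#' @return The log-density, a scalar.
#' @export
student_logdensity <- function(x, kappa, M = NULL, V = NULL) {
  if (inherits(kappa, "outlier_params")) {
    params <- kappa
    kappa <- params$kappa; M <- params$M; V <- params$V
  }
  x <- as.numeric(x); M <- as.numeric(M)
  V <- as.matrix(V)
  L <- length(x)
  stopifnot(kappa > 0, length(M) == L, all(dim(V) == L))
  U <- chol_or_jitter(V, "outlier scale matrix")
  d <- backsolve(U, x - M, transpose = TRUE)
  delta <- sum(d^2)
  lgamma((kappa + L) / 2) - lgamma(kappa / 2) - 0.5 * L * log(kappa * pi) -
    sum(log(diag(U))) - 0.5 * (kappa + L) * log1p(delta / kappa)
}

#' Sufficient statistics of a mixture component
#'
#' Holds the count, profile sum and raw scatter (sum of outer products) of
#' the proteins currently assigned to one Gaussian component with `phi = 1`.
#' These are all the collapsed sampler needs: component means and
#' covariances are integrated out analytically under the NIW prior.
#'
#' @param x Optional numeric matrix (rows = member profiles) or vector used
#'   to initialise the statistic; default empty.
#' @param L Profile length; required when `x` is missing.
#' @return An object of class `component_stats`.
#' @export
component_stats <- function(x = NULL, L = NULL) {
  if (is.null(x)) {
    stopifnot(!is.null(L))
    return(structure(list(count = 0L, sum = numeric(L),
                          scatter = matrix(0, L, L)), class = "component_stats"))
  }
  x <- rbind(x)
  structure(
    list(count = nrow(x), sum = colSums(x), scatter = crossprod(x)),
    class = "component_stats"
  )
}

#' @rdname component_stats
#' @param stats A `component_stats` object.
#' @export
stats_add <- function(stats, x) {
  x <- as.numeric(x)
  stats$count <- stats$count + 1L
  stats$sum <- stats$sum + x
  stats$scatter <- stats$scatter + tcrossprod(x)
  stats
}

#' @rdname component_stats
#' @export
stats_remove <- function(stats, x) {
  x <- as.numeric(x)
  if (stats$count < 1) abort("cannot remove from an empty component")
  stats$count <- stats$count - 1L
  stats$sum <- stats$sum - x
  stats$scatter <- stats$scatter - tcrossprod(x)
  stats
}

niw_posterior <- function(stats, prior) {
  n <- stats$count
  lambda_n <- prior$lambda0 + n
  nu_n <- prior$nu0 + n
  mu_n <- (prior$lambda0 * prior$mu0 + stats$sum) / lambda_n
  S_n <- prior$S0 + stats$scatter + prior$lambda0 * tcrossprod(prior$mu0) -
    lambda_n * tcrossprod(mu_n)
  S_n <- (S_n + t(S_n)) / 2
  list(mu_n = mu_n, lambda_n = lambda_n, nu_n = nu_n, S_n = S_n)
}

#' Collapsed (NIW posterior-predictive) log-density
#'
#' The density of a new profile under a Gaussian component whose mean and
#' covariance have been integrated out against the NIW prior updated by the
#' component's current members. This is a multivariate t with
#' `nu_n - L + 1` degrees of freedom, location `mu_n`, and scale
#' `S_n (lambda_n + 1) / (lambda_n (nu_n - L + 1))`, where
#' `(mu_n, lambda_n, nu_n, S_n)` are the standard conjugate updates. An empty
#' component gives the prior predictive.
#'
#' @param x Numeric length-L vector.
#' @param stats A `component_stats` object (the component's current members).
#' @param prior List with `mu0`, `lambda0`, `nu0`, `S0` (e.g. `spec$niw`).
#' @return The log predictive density, a scalar.
#' @export
collapsed_predictive_logdensity <- function(x, stats, prior) {
  x <- as.numeric(x)
  L <- length(x)
  post <- niw_posterior(stats, prior)
  df <- post$nu_n - L + 1
  if (df <= 0) abort("invalid prior: nu0 must exceed L - 1")
  scale <- post$S_n * (post$lambda_n + 1) / (post$lambda_n * df)
  student_logdensity(x, df, post$mu_n, scale)
}

#' Full conditional allocation probabilities for one profile
#'
#' The collapsed joint conditional of `(z_i, phi_i)` for an unlabelled
#' protein, given every other assignment. Component `k` (with `phi = 1`)
#' receives mass proportional to `(n_k + alpha) (1 - eps) p_k(x)` where
#' `p_k` is the collapsed predictive of component `k` and `n_k` counts the
#' other proteins with `z = k`; the outlier slot receives the aggregated
#' mass `eps g(x) sum_k (n_k + alpha)` (the outlier density does not depend
#' on the component, and the latent component label of an outlier follows
#' the conditional prior weights). Empty novelty components contribute their
#' bare prior predictive with prior weight `alpha`.
#'
#' @param x Numeric length-L profile of an unlabelled protein whose own
#'   current assignment has been removed from `state`.
#' @param state List describing the rest of the chain state: `n_z`
#'   (length-`K_max` integer counts of `z` over the other proteins, outliers
#'   included via their latent label), `stats` (list of `K_max`
#'   `component_stats` over the `phi = 1` members), and `eps` (current
#'   outlier rate).
#' @param spec An `ntagm_spec`.
#' @return List with `component` (length-`K_max` vector of
#'   `P(z_i = k, phi_i = 1)`) and `outlier` (scalar `P(phi_i = 0)`); the
#'   entries sum to one.
#' @export
conditional_probs <- function(x, state, spec) {
  K_max <- spec$K_max
  stopifnot(length(state$n_z) == K_max, length(state$stats) == K_max)
  eps <- state$eps
  lp <- vapply(seq_len(K_max), function(k) {
    log(state$n_z[k] + spec$dirichlet_concentration) +
      collapsed_predictive_logdensity(x, state$stats[[k]], spec$niw)
  }, numeric(1))
  if (any(!is.finite(lp))) {
    abort("non-finite conditional log-density; check the profile and priors")
  }
  lp <- lp + log1p(-eps)
  lp0 <- if (eps > 0) {
    log(eps) + student_logdensity(x, spec$outlier) +
      log(sum(state$n_z) + K_max * spec$dirichlet_concentration)
  } else {
    -Inf
  }
  all_lp <- c(lp, lp0)
  m <- max(all_lp)
  p <- exp(all_lp - m)
  p <- p / sum(p)
  list(component = p[seq_len(K_max)], outlier = p[K_max + 1])
}
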