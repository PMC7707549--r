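# Chain orchestration around the compiled collapsed Gibbs kernel. Labelled
# (marker) proteins keep their component assignment fixed at every
# iteration; only their outlier indicator is resampled (unless
# spec$fix_marker_phi). Unlabelled proteins have (z_i, phi_i) drawn jointly
# from the collapsed conditional, and epsilon is refreshed by Beta
# conjugacy at the end of each sweep.

chain_inputs <- function(profiles, markers, spec) {
  profiles <- validate_profiles(profiles)
  markers <- validate_markers(markers, profiles)
  X <- profile_matrix(profiles)
  lab_idx <- match(markers$accession, profiles$accession)
  z_lab <- match(markers$markers, spec$components)
  fixed <- rep(FALSE, nrow(X))
  fixed[lab_idx] <- TRUE
  z <- rep(NA_integer_, nrow(X))
  z[lab_idx] <- z_lab
  list(X = X, fixed = fixed, z = z, accessions = profiles$accession)
}

#' Initialise a chain state
#'
#' Marker proteins are fixed to their annotated component; unlabelled
#' proteins are assigned sequentially from the collapsed prior-predictive
#' conditionals (with all outlier indicators started at `phi = 1`), and the
#' outlier rate is drawn from its Beta prior. The result is deterministic
#' given `seed`.
#'
#' @param profiles Profile tibble.
#' @param markers Marker tibble.
#' @param spec An `ntagm_spec`.
#' @param seed Integer RNG seed.
#' @return An object of class `ntagm_state`: list with `accession`, `z`
#'   (component index in `1..K_max`), `phi` (0/1), `eps`, `fixed` (logical,
#'   marker proteins).
#' @export
init_chain <- function(profiles, markers, spec, seed = 1) {
  set.seed(seed)
  inp <- chain_inputs(profiles, markers, spec)
  K_max <- spec$K_max
  L <- ncol(inp$X)
  if (all(inp$fixed) && spec$k_novelty == 0) {
    warn("all proteins are labelled and k_novelty = 0: nothing to infer")
  }
  n_z <- integer(K_max)
  stats <- replicate(K_max, component_stats(L = L), simplify = FALSE)
  for (i in which(inp$fixed)) {
    k <- inp$z[i]
    n_z[k] <- n_z[k] + 1L
    stats[[k]] <- stats_add(stats[[k]], inp$X[i, ])
  }
  eps <- stats::rbeta(1, spec$eps_prior[1], spec$eps_prior[2])
  for (i in which(!inp$fixed)) {
    cp <- conditional_probs(inp$X[i, ],
                            list(n_z = n_z, stats = stats, eps = 0),
                            spec)
    k <- sample.int(K_max, 1, prob = cp$component)
    inp$z[i] <- k
    n_z[k] <- n_z[k] + 1L
    stats[[k]] <- stats_add(stats[[k]], inp$X[i, ])
  }
  structure(
    list(accession = inp$accessions, z = inp$z, phi = rep(1L, nrow(inp$X)),
         eps = eps, fixed = inp$fixed),
    class = "ntagm_state"
  )
}

#' Advance a chain state by Gibbs sweeps
#'
#' Each sweep visits every protein in ascending index order: unlabelled
#' proteins are removed from the sufficient statistics, their `(z_i, phi_i)`
#' redrawn jointly from [conditional_probs()], and reinserted; marker
#' proteins keep `z` fixed and have `phi` resampled between their own
#' component's collapsed predictive and the outlier density; finally the
#' outlier rate is redrawn from `Beta(u + #(phi = 0), v + #(phi = 1))`.
#' Randomness comes from R's RNG stream (seed with `set.seed()`).
#'
#' @param state An `ntagm_state`.
#' @param profiles,markers,spec The data and model specification.
#' @param sweeps Number of sweeps to advance (default 1).
#' @return The updated `ntagm_state`.
#' @export
gibbs_sweep <- function(state, profiles, markers, spec, sweeps = 1) {
  inp <- chain_inputs(profiles, markers, spec)
  res <- .ntagm_run_cpp(
    inp$X, as.integer(state$z), as.integer(state$phi), inp$fixed,
    spec$K, spec$K_max, spec$niw$mu0, spec$niw$lambda0, spec$niw$nu0,
    spec$niw$S0, spec$dirichlet_concentration,
    spec$outlier$kappa, spec$outlier$M, spec$outlier$V,
    spec$eps_prior[1], spec$eps_prior[2], state$eps,
    as.integer(sweeps), 0L, as.integer(sweeps), spec$fix_marker_phi
  )
  state$z <- as.integer(res$final$z)
  state$phi <- as.integer(res$final$phi)
  state$eps <- res$final$eps
  state
}

#' Run one MCMC chain
#'
#' @param profiles Profile tibble.
#' @param markers Marker tibble.
#' @param spec An `ntagm_spec`; default [model_spec()] of the data.
#' @param n_iter Total sweeps; must exceed `burn`.
#' @param burn Burn-in sweeps discarded (>= 0).
#' @param thin Keep every `thin`-th post-burn-in sweep (>= 1).
#' @param seed Integer seed; identical seeds give identical chains.
#' @param chain_id Identifier stored with the output.
#' @return An object of class `ntagm_chain` with `T` retained draws:
#'   `z_draws`, `phi_draws` (T x N), `eps_draws`, `occupied_trace` (length
#'   T, number of non-empty components), and `alloc_probs` — the
#'   Rao-Blackwellised conditional allocation probabilities
#'   `P(z_i = k, phi_i = 1 | ...)` for the unlabelled proteins, an
#'   `N_U x K_max x T` array whose slices sum to at most one per row (the
#'   remainder is outlier mass).
#' @export
run_chain <- function(profiles, markers, spec = NULL,
                      n_iter = 10000, burn = 2000, thin = 4,
                      seed = 1, chain_id = 1L) {
  if (is.null(spec)) spec <- model_spec(profiles, markers)
  if (burn < 0 || n_iter <= burn) abort("need n_iter > burn >= 0")
  if (thin < 1) abort("thin must be >= 1")
  T_keep <- (n_iter - burn) %/% thin
  if (T_keep < 1) abort("configuration error: no retained draws (increase n_iter or reduce thin)")

  state <- init_chain(profiles, markers, spec, seed = seed)
  inp <- chain_inputs(profiles, markers, spec)
  res <- .ntagm_run_cpp(
    inp$X, as.integer(state$z), as.integer(state$phi), inp$fixed,
    spec$K, spec$K_max, spec$niw$mu0, spec$niw$lambda0, spec$niw$nu0,
    spec$niw$S0, spec$dirichlet_concentration,
    spec$outlier$kappa, spec$outlier$M, spec$outlier$V,
    spec$eps_prior[1], spec$eps_prior[2], state$eps,
    as.integer(n_iter), as.integer(burn), as.integer(thin),
    spec$fix_marker_phi
  )
  unlab <- inp$accessions[!inp$fixed]
  z_draws <- res$z_draws
  colnames(z_draws) <- inp$accessions
  phi_draws <- res$phi_draws
  colnames(phi_draws) <- inp$accessions
  alloc <- res$alloc_probs
  dimnames(alloc) <- list(unlab, NULL, NULL)
  structure(
    list(
      T = nrow(z_draws), accessions = inp$accessions, unlabelled = unlab,
      z_draws = z_draws, phi_draws = phi_draws,
      eps_draws = as.numeric(res$eps_draws),
      occupied_trace = as.integer(res$occupied_trace),
      alloc_probs = alloc,
      chain_id = chain_id, seed = seed, n_iter = n_iter, burn = burn,
      thin = thin, K = spec$K, K_max = spec$K_max,
      components = spec$components
    ),
    class = "ntagm_chain"
  )
}

#' Run several independent chains
#'
#' Chain `c` uses seed `base_seed + c`; outputs are returned in chain order.
#'
#' @inheritParams run_chain
#' @param n_chains Number of chains (>= 1).
#' @param base_seed Base integer seed.
#' @return List of `ntagm_chain` objects.
#' @export
run_chains <- function(profiles, markers, spec = NULL,
                       n_chains = 4, n_iter = 10000, burn = 2000, thin = 4,
                       base_seed = 1) {
  if (n_chains < 1) abort("n_chains must be >= 1")
  if (is.null(spec)) spec <- model_spec(profiles, markers)
  purrr::map(seq_len(n_chains), function(cc) {
    run_chain(profiles, markers, spec, n_iter = n_iter, burn = burn,
              thin = thin, seed = base_seed + cc, chain_id = cc)
  })
}

#' Fit the Novelty TAGM model
#'
#' The main entry point: builds the model specification (empirical outlier
#' component, NIW prior, `k_novelty` overfitted novelty components), runs
#' `chains` collapsed Gibbs chains, and returns a fitted object on which all
#' posterior summaries operate ([compute_psm()], [discovery_probability()],
#' [outlier_probability()], [summarise_phenotypes()], [tidy()],
#' [glance()], [autoplot()]).
#'
#' @inheritParams run_chain
#' @param k_novelty Number of novelty components (ignored when `spec` is
#'   given); default 10.
#' @param chains Number of independent chains.
#' @return An object of class `novelty_tagm`.
#'
#' @examples
#' sim <- simulate_spatial_proteome(simulation_design(
#'   K_visible = 3, n_per_component = 25, L = 4, separation = 5, seed = 1))
#' fit <- fit_novelty_tagm(sim$profiles, sim$markers, k_novelty = 4,
#'                         chains = 1, n_iter = 400, burn = 100, thin = 2,
#'                         seed = 1)
#' glance(fit)
#' @export
fit_novelty_tagm <- function(profiles, markers, k_novelty = 10, spec = NULL,
                             chains = 4, n_iter = 10000, burn = 2000,
                             thin = 4, seed = 1) {
  profiles <- validate_profiles(profiles)
  markers <- validate_markers(markers, profiles)
  if (is.null(spec)) spec <- model_spec(profiles, markers, k_novelty = k_novelty)
  out <- run_chains(profiles, markers, spec, n_chains = chains,
                    n_iter = n_iter, burn = burn, thin = thin,
                    base_seed = seed)
  structure(
    list(chains = out, spec = spec, profiles = profiles, markers = markers,
         seed = seed),
    class = "novelty_tagm"
  )
}

#' @export
print.novelty_tagm <- function(x, ...) {
  ch <- x$chains[[1]]
  cat("Novelty TAGM fit:", length(x$chains), "chain(s) x", ch$T, "retained draws\n")
  cat("  proteins:", length(ch$accessions),
      "(", length(ch$unlabelled), "unlabelled ) | fractions:", x$spec$L, "\n")
  cat("  K =", x$spec$K, "known components + K_novelty =", x$spec$k_novelty, "\n")
  occ <- unlist(purrr::map(x$chains, "occupied_trace"))
  cat("  posterior median occupied components:", stats::median(occ), "\n")
  invisible(x)
}

# Potential scale reduction on a per-chain list of numeric traces; constant
# traces across chains are 1 by convention, disagreeing constant chains Inf.
psrf <- function(traces) {
  m <- length(traces)
  if (m < 2) return(NA_real_)
  n <- min(lengths(traces))
  mat <- vapply(traces, function(tr) as.numeric(tr[seq_len(n)]), numeric(n))
  W <- mean(apply(mat, 2, stats::var))
  B_over_n <- stats::var(colMeans(mat))
  if (W == 0) return(if (B_over_n == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Convergence report on the occupied-component trace
#'
#' The number of occupied (non-empty) mixture components at each retained
#' iteration is itself random under the overfitted mixture; its trace is the
#' convergence diagnostic monitored here. With two or more chains the
#' potential-scale-reduction statistic (Gelman-Rubin) of the trace is
#' computed; chains are flagged when it exceeds `threshold`. A constant
#' trace has scale reduction 1 by convention.
#'
#' @param fit A `novelty_tagm` fit, or a list of `ntagm_chain` objects.
#' @param threshold Flagging threshold for the scale-reduction statistic
#'   (default 1.1).
#' @return List with `chains` (tibble of per-chain occupied-trace
#'   summaries), `rhat`, `threshold`, and `flagged` (logical).
#' @export
diagnose <- function(fit, threshold = 1.1) {
  chains <- if (inherits(fit, "novelty_tagm")) fit$chains else fit
  stopifnot(length(chains) >= 1)
  tab <- purrr::map_dfr(chains, function(ch) {
    tibble::tibble(
      chain = ch$chain_id, draws = ch$T,
      occ_median = stats::median(ch$occupied_trace),
      occ_mean = mean(ch$occupied_trace),
      occ_sd = stats::sd(ch$occupied_trace),
      eps_mean = mean(ch$eps_draws)
    )
  })
  rhat <- psrf(purrr::map(chains, "occupied_trace"))
  list(chains = tab, rhat = rhat, threshold = threshold,
       flagged = is.finite(threshold) && !is.na(rhat) && rhat > threshold)
}

#' Persist / restore a fit
#'
#' Fits (including full MCMC traces) are serialised with base R's RDS
#' format; summary tables are exported separately as CSV by
#' [export_summaries()].
#'
#' @param fit A `novelty_tagm` object.
#' @param path File path (conventionally `.rds`).
#' @return `path` invisibly; the restored fit for `read_fit()`.
#' @export
write_fit <- function(fit, path) {
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  fit <- readRDS(path)
  if (!inherits(fit, "novelty_tagm")) abort("file does not contain a novelty_tagm fit")
  fit
}
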