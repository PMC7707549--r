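# Shared fixture builders. All fixtures are generated in code at test time.

toy_profiles <- function(n = 10, L = 4, seed = 11) {
  set.seed(seed)
  dplyr::bind_cols(
    tibble::tibble(accession = sprintf("Q%03d", seq_len(n))),
    tibble::as_tibble(matrix(rnorm(n * L), n, L,
                             dimnames = list(NULL, paste0("f", seq_len(L)))))
  )
}

# minimal stand-in for an ntagm_chain, for summary-layer unit tests
fake_chain <- function(z_draws, phi_draws = NULL, alloc = NULL, K = 1,
                       K_max = NULL, eps_draws = NULL, chain_id = 1) {
  T_n <- nrow(z_draws)
  acc <- colnames(z_draws)
  if (is.null(phi_draws)) {
    phi_draws <- matrix(1L, T_n, ncol(z_draws), dimnames = dimnames(z_draws))
  }
  if (is.null(K_max)) K_max <- max(z_draws)
  if (is.null(alloc)) alloc <- array(0, dim = c(ncol(z_draws), K_max, T_n))
  structure(
    list(T = T_n, accessions = acc, unlabelled = acc,
         z_draws = z_draws, phi_draws = phi_draws,
         eps_draws = if (is.null(eps_draws)) rep(0.05, T_n) else eps_draws,
         occupied_trace = apply(z_draws, 1, function(z) length(unique(z))),
         alloc_probs = alloc, chain_id = chain_id, K = K, K_max = K_max,
         components = paste0("c", seq_len(K))),
    class = "ntagm_chain"
  )
}

fake_fit <- function(chains) structure(list(chains = chains, spec = NULL),
                                       class = "novelty_tagm")

# a clean, well-separated dataset plus a quick low-cost fit; used by several
# summary tests so the MCMC only runs once per design
quick_sim_fit <- function(K_visible = 3, K_hidden = 0, n_per_component = 25,
                          L = 5, marker_fraction = 0.6, outlier_fraction = 0,
                          separation = 6, k_novelty = 5, seed = 3,
                          n_iter = 800, burn = 300, thin = 2, chains = 1) {
  sim <- simulate_spatial_proteome(simulation_design(
    K_visible = K_visible, K_hidden = K_hidden,
    n_per_component = n_per_component, L = L,
    marker_fraction = marker_fraction, outlier_fraction = outlier_fraction,
    separation = separation, seed = seed))
  fit <- fit_novelty_tagm(sim$profiles, sim$markers, k_novelty = k_novelty,
                          chains = chains, n_iter = n_iter, burn = burn,
                          thin = thin, seed = seed + 100)
  list(sim = sim, fit = fit)
}
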