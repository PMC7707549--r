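# Sampler-level tests. The deepest check is distributional: on problems
# small enough to enumerate the full (z, phi) posterior, the chain's
# assignment frequencies must match the exact posterior.

small_problem <- function() {
  acc <- paste0("P", 1:6)
  x <- c(-2.0, 2.2, -1.7, 1.9, 0.2, -0.5)
  profiles <- tibble::tibble(accession = acc, f1 = x)
  markers <- tibble::tibble(accession = c("P1", "P2"), markers = c("a", "b"))
  niw <- list(mu0 = 0, lambda0 = 1, nu0 = 3, S0 = matrix(1.5))
  out <- structure(list(kappa = 4, M = 0, V = matrix(3)),
                   class = "outlier_params")
  spec <- model_spec(profiles, markers, k_novelty = 0, niw_prior = niw,
                     outlier = out, fix_marker_phi = TRUE)
  list(profiles = profiles, markers = markers, spec = spec, x = x)
}

test_that("chain initialisation is seeded, constrained and boundary-safe", {
  pr <- small_problem()
  s1 <- init_chain(pr$profiles, pr$markers, pr$spec, seed = 7)
  s2 <- init_chain(pr$profiles, pr$markers, pr$spec, seed = 7)
  expect_identical(s1, s2)
  s3 <- init_chain(pr$profiles, pr$markers, pr$spec, seed = 8)
  expect_false(identical(s1$z, s3$z) && identical(s1$eps, s3$eps))

  # labelled proteins start at their marker component
  expect_equal(s1$z[1:2], 1:2)
  expect_true(all(s1$phi == 1L))
  # k_novelty = 0 restricts support to the known components
  expect_true(all(s1$z %in% 1:2))

  all_lab <- tibble::tibble(accession = pr$profiles$accession,
                            markers = rep(c("a", "b"), 3))
  spec_all <- model_spec(pr$profiles, all_lab, k_novelty = 0,
                         niw_prior = pr$spec$niw, outlier = pr$spec$outlier)
  expect_warning(init_chain(pr$profiles, all_lab, spec_all, seed = 1),
                 "nothing to infer")
})

test_that("run_chain bookkeeping: retention arithmetic, determinism, label constraint", {
  pr <- small_problem()
  ch <- run_chain(pr$profiles, pr$markers, pr$spec, n_iter = 100, burn = 50,
                  thin = 5, seed = 2)
  expect_equal(ch$T, 10)
  expect_equal(dim(ch$z_draws), c(10, 6))

  ch2 <- run_chain(pr$profiles, pr$markers, pr$spec, n_iter = 100, burn = 50,
                   thin = 5, seed = 2)
  expect_identical(ch$z_draws, ch2$z_draws)
  expect_identical(ch$eps_draws, ch2$eps_draws)

  ch3 <- run_chain(pr$profiles, pr$markers, pr$spec, n_iter = 100, burn = 50,
                   thin = 5, seed = 3)
  expect_false(identical(ch$z_draws, ch3$z_draws))

  # marker assignments never change across retained draws
  expect_true(all(ch$z_draws[, "P1"] == 1))
  expect_true(all(ch$z_draws[, "P2"] == 2))

  expect_error(run_chain(pr$profiles, pr$markers, pr$spec, n_iter = 10,
                         burn = 20), "n_iter > burn")
  expect_error(run_chain(pr$profiles, pr$markers, pr$spec, n_iter = 5,
                         burn = 4, thin = 5), "configuration error")

  chs <- run_chains(pr$profiles, pr$markers, pr$spec, n_chains = 2,
                    n_iter = 60, burn = 20, thin = 2, base_seed = 9)
  expect_length(chs, 2)
  expect_equal(purrr::map_int(chs, "chain_id"), 1:2)
  # chain c is run_chain at seed base_seed + c
  expect_identical(chs[[1]]$z_draws,
                   run_chain(pr$profiles, pr$markers, pr$spec, n_iter = 60,
                             burn = 20, thin = 2, seed = 10)$z_draws)
  expect_false(identical(chs[[1]]$z_draws, chs[[2]]$z_draws))
})

test_that("gibbs sweeps preserve the label constraint and advance the state", {
  pr <- small_problem()
  st <- init_chain(pr$profiles, pr$markers, pr$spec, seed = 4)
  set.seed(99)
  for (i in 1:25) {
    st <- gibbs_sweep(st, pr$profiles, pr$markers, pr$spec)
    expect_equal(st$z[1:2], 1:2)
    expect_true(st$eps >= 0 && st$eps <= 1)
    expect_true(all(st$phi %in% c(0L, 1L)))
  }
})

test_that("a profile at a component mean is allocated there almost surely when eps = 0", {
  L <- 3
  spec <- model_spec(toy_profiles(n = 8, L = L, seed = 31),
                     tibble::tibble(accession = c("Q001", "Q002"),
                                    markers = c("a", "b")),
                     k_novelty = 0)
  mu_a <- c(10, 0, 0); mu_b <- c(-10, 0, 0)
  set.seed(5)
  st <- list(
    n_z = c(20L, 20L),
    stats = list(
      component_stats(sweep(matrix(rnorm(60, sd = 0.5), 20, L), 2, mu_a, "+")),
      component_stats(sweep(matrix(rnorm(60, sd = 0.5), 20, L), 2, mu_b, "+"))
    ),
    eps = 0
  )
  cp <- conditional_probs(mu_a, st, spec)
  expect_gt(cp$component[1], 0.999)
  expect_identical(cp$outlier, 0)
})

test_that("sampler assignment frequencies match the enumerated posterior", {
  pr <- small_problem()
  spec <- model_spec(pr$profiles, pr$markers, k_novelty = 0,
                     niw_prior = pr$spec$niw, outlier = pr$spec$outlier,
                     fix_marker_phi = FALSE)
  ch <- run_chain(pr$profiles, pr$markers, spec, n_iter = 201000, burn = 1000,
                  thin = 10, seed = 13)
  oracle <- oracle_enumerate_posterior(
    matrix(pr$x, ncol = 1), c(1L, 2L, NA, NA, NA, NA), K_max = 2,
    prior = spec$niw, alpha = 1, u = 2, v = 10,
    kappa = 4, M = 0, V = matrix(3), fix_marker_phi = FALSE)
  n <- ch$T
  for (i in 1:6) {
    for (k in 1:2) {
      for (ph in 0:1) {
        p_exact <- sum(oracle$prob[oracle[[paste0("z", i)]] == k &
                                     oracle[[paste0("phi", i)]] == ph])
        freq <- mean(ch$z_draws[, i] == k & ch$phi_draws[, i] == ph)
        sig <- sqrt(p_exact * (1 - p_exact) / n)
        expect_lt(abs(freq - p_exact), max(3 * sig, 1e-3))
      }
    }
  }
})

test_that("the posterior outlier rate recovers the generating contamination", {
  sim <- simulate_spatial_proteome(simulation_design(
    K_visible = 3, K_hidden = 0, n_per_component = 70, L = 5,
    marker_fraction = 0.9, outlier_fraction = 0.1, separation = 5, seed = 4))
  true_frac <- mean(sim$truth$phi == 0)
  fit <- fit_novelty_tagm(sim$profiles, sim$markers, k_novelty = 3, chains = 1,
                          n_iter = 1500, burn = 500, thin = 2, seed = 9)
  ed <- fit$chains[[1]]$eps_draws
  expect_lt(abs(mean(ed) - true_frac), 3 * stats::sd(ed))
})

test_that("occupied-component convergence diagnostics behave at the extremes", {
  mk <- function(trace, id) {
    fake_chain(matrix(1L, length(trace), 2,
                      dimnames = list(NULL, c("A", "B"))), chain_id = id) |>
      (\(ch) { ch$occupied_trace <- trace; ch })()
  }
  # identical chains: scale reduction about 1
  set.seed(8)
  tr <- rpois(200, 5) + 1L
  d_same <- diagnose(list(mk(tr, 1), mk(tr, 2)))
  expect_lt(abs(d_same$rhat - 1), 0.05)
  expect_false(d_same$flagged)

  # constant traces: 1 by convention
  d_const <- diagnose(list(mk(rep(4L, 100), 1), mk(rep(4L, 100), 2)))
  expect_identical(d_const$rhat, 1)

  # one chain stuck at K, one at K + 3: far above the 1.1 threshold
  d_stuck <- diagnose(list(mk(rep(4L, 100), 1), mk(rep(7L, 100), 2)))
  expect_gt(d_stuck$rhat, 1.1)
  expect_true(d_stuck$flagged)

  # single chain: no scale reduction defined, still summarised
  d_one <- diagnose(list(mk(tr, 1)))
  expect_true(is.na(d_one$rhat))
  expect_equal(nrow(d_one$chains), 1)
})

test_that("fits serialise and restore through RDS", {
  pr <- small_problem()
  fit <- fit_novelty_tagm(pr$profiles, pr$markers, spec = pr$spec, chains = 1,
                          n_iter = 60, burn = 20, thin = 2, seed = 1)
  f <- withr::local_tempfile(fileext = ".rds")
  write_fit(fit, f)
  expect_identical(read_fit(f)$chains[[1]]$z_draws, fit$chains[[1]]$z_draws)
})
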