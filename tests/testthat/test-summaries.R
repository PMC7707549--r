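# One moderate fitted model is shared by several blocks in this file:
# 2 visible niches + 1 hidden phenotype, clean Gaussian data.
shared <- quick_sim_fit(K_visible = 2, K_hidden = 1, n_per_component = 12,
                        L = 4, marker_fraction = 2 / 3, separation = 6,
                        k_novelty = 4, seed = 17, n_iter = 1200, burn = 400)

test_that("the PSM is a co-clustering frequency with exact small cases", {
  zd <- matrix(c(1L, 1L, 2L), 1, 3, dimnames = list(NULL, c("a", "b", "c")))
  psm1 <- compute_psm(list(fake_chain(zd)))
  expect_true(all(psm1 %in% c(0, 1)))
  expect_equal(psm1["a", "b"], 1)
  expect_equal(psm1["a", "c"], 0)

  zd2 <- rbind(c(1L, 1L, 2L), c(1L, 2L, 2L))
  colnames(zd2) <- c("a", "b", "c")
  psm2 <- compute_psm(list(fake_chain(zd2)))
  expect_equal(psm2["a", "b"], 0.5)
  expect_equal(psm2["b", "c"], 0.5)
  expect_equal(psm2["a", "c"], 0)
  expect_equal(diag(psm2), c(a = 1, b = 1, c = 1))

  # properties on a genuine fitted output
  psm <- compute_psm(shared$fit)
  expect_equal(psm, t(psm))
  expect_true(all(diag(psm) == 1))
  expect_true(all(psm >= 0 & psm <= 1))
})

test_that("discovery probability implements the Monte-Carlo average identity", {
  # T = 2 draws with known-component conditional sums 0.5 and 0.7 -> 0.4
  alloc <- array(0, dim = c(1, 2, 2))
  alloc[1, , 1] <- c(0.5, 0.3)   # known comp gets 0.5
  alloc[1, , 2] <- c(0.7, 0.2)
  zd <- matrix(1L, 2, 1, dimnames = list(NULL, "a"))
  d <- discovery_probability(fake_fit(list(fake_chain(zd, alloc = alloc, K = 1))))
  expect_equal(d$discovery_prob, 0.4, tolerance = 1e-12)

  # all mass always on known components -> 0
  alloc0 <- array(0, dim = c(1, 2, 2))
  alloc0[1, 1, ] <- 1
  d0 <- discovery_probability(fake_fit(list(fake_chain(zd, alloc = alloc0, K = 1))))
  expect_equal(d0$discovery_prob, 0)

  # per-protein identity with the mean allocation matrix, on a real fit
  fit <- shared$fit
  K <- fit$spec$K
  d_real <- discovery_probability(fit)
  alloc_mean <- mean_allocation(fit)
  expect_equal(d_real$discovery_prob,
               unname(1 - rowSums(alloc_mean[, seq_len(K), drop = FALSE])),
               tolerance = 1e-10)
  # allocation rows sum to at most 1 (remainder is outlier mass)
  expect_true(all(rowSums(alloc_mean) <= 1 + 1e-10))
})

test_that("outlier probability is the phi = 0 frequency and separates contaminants", {
  zd <- matrix(1L, 4, 2, dimnames = list(NULL, c("a", "b")))
  phid <- cbind(a = c(1L, 1L, 1L, 1L), b = c(0L, 1L, 0L, 1L))
  op <- outlier_probability(fake_fit(list(fake_chain(zd, phi_draws = phid))))
  expect_equal(op$outlier_prob, c(0, 0.5))

  sim <- simulate_spatial_proteome(simulation_design(
    K_visible = 3, K_hidden = 0, n_per_component = 30, L = 5,
    marker_fraction = 0.5, outlier_fraction = 0.2, separation = 5, seed = 23))
  fit <- fit_novelty_tagm(sim$profiles, sim$markers, k_novelty = 3, chains = 1,
                          n_iter = 1000, burn = 400, thin = 2, seed = 77)
  m <- dplyr::inner_join(outlier_probability(fit), sim$truth, by = "accession")
  expect_gt(mean(m$outlier_prob[m$phi == 0]), mean(m$outlier_prob[m$phi == 1]))
})

test_that("maxPEAR recovers exact optima and degenerate cases", {
  # block-diagonal PSM with two perfect blocks
  b <- matrix(0, 6, 6, dimnames = list(paste0("p", 1:6), paste0("p", 1:6)))
  b[1:3, 1:3] <- 1; b[4:6, 4:6] <- 1
  cl <- maxpear_clustering(structure(b, class = c("ntagm_psm", "matrix", "array")))
  expect_equal(cl$cluster, rep(1:2, each = 3))

  # identity PSM: singletons, with a warning
  idm <- diag(5)
  dimnames(idm) <- list(paste0("q", 1:5), paste0("q", 1:5))
  expect_warning(
    cl_id <- maxpear_clustering(structure(idm, class = c("ntagm_psm", "matrix", "array"))),
    "degenerate")
  expect_equal(cl_id$cluster, 1:5)

  # fitted PSM, 8 proteins: never beaten by exhaustive set-partition search
  psm <- compute_psm(shared$fit)
  keep <- rownames(psm)[1:8]
  sub <- structure(psm[keep, keep], class = c("ntagm_psm", "matrix", "array"))
  best <- maxpear_clustering(sub)
  score_pkg <- attr(best, "pear")
  scores_all <- vapply(all_partitions(8), function(p) pear_score(sub, p),
                       numeric(1))
  expect_gte(score_pkg + 1e-12, max(scores_all))
})

test_that("putative phenotypes follow the 0.95 discovery rule", {
  expect_equal(formals(identify_phenotypes)$threshold, 0.95)

  clustering <- tibble::tibble(accession = letters[1:6],
                               cluster = rep(1:2, each = 3))
  low <- tibble::tibble(accession = letters[1:6],
                        discovery_prob = rep(0.9, 6))
  expect_equal(nrow(identify_phenotypes(clustering, low)), 0)

  disc <- tibble::tibble(accession = letters[1:6],
                         discovery_prob = c(0.99, 0.97, 0.96, 0.1, 0.2, 0.1))
  ph <- identify_phenotypes(clustering, disc)
  expect_equal(nrow(ph), 1)
  expect_equal(ph$phenotype, "phenotype 1")
  expect_setequal(ph$members[[1]], c("a", "b", "c"))

  # a hidden well-separated niche is recovered nearly whole
  ph_real <- summarise_phenotypes(shared$fit)
  truth <- shared$sim$truth
  hidden_acc <- truth$accession[truth$component == 3]
  expect_gte(nrow(ph_real), 1)
  top <- ph_real$members[[1]]
  expect_gte(sum(hidden_acc %in% top) / length(hidden_acc), 0.9)
})

test_that("the allocation table is a valid per-protein posterior summary", {
  fit <- shared$fit
  tab <- allocation_table(fit)
  expect_true(all(tab$best_component_prob >= 0 & tab$best_component_prob <= 1))
  expect_true(all(tab$outlier_prob >= 0 & tab$outlier_prob <= 1))
  expect_true(all(tab$discovery_prob >= 0 & tab$discovery_prob <= 1))

  # best-label probability is the row maximum over known components
  alloc <- mean_allocation(fit)[, seq_len(fit$spec$K), drop = FALSE]
  expect_equal(tab$best_component_prob, unname(apply(alloc, 1, max)))

  # unlabelled proteins generated from a marked niche are confidently assigned
  truth <- shared$sim$truth
  m <- dplyr::inner_join(tab, truth, by = "accession") |>
    dplyr::filter(.data$component <= 2, .data$phi == 1)
  expect_equal(m$best_component, paste0("niche_", m$component))
  # the marker-adjacent member (closest to its niche centre) is near-certain
  X <- profile_matrix(fit$profiles)
  means <- attr(truth, "means")
  for (k in 1:2) {
    mk <- dplyr::filter(m, .data$component == k)
    d2 <- rowSums((X[mk$accession, , drop = FALSE] -
                     matrix(means[k, ], nrow(mk), ncol(X), byrow = TRUE))^2)
    expect_gt(mk$best_component_prob[which.min(d2)], 0.95)
  }

  expect_identical(tidy(fit), tab)
  g <- glance(fit)
  expect_equal(g$K, 2)
  expect_equal(g$n_unlabelled, nrow(tab))
})

test_that("summaries export to flat files with the documented phenotype schema", {
  dir <- withr::local_tempdir()
  export_summaries(shared$fit, dir)
  expect_true(all(file.exists(file.path(
    dir, c("allocation.csv", "psm.csv", "phenotypes.json", "diagnostics.csv")))))
  ph <- jsonlite::read_json(file.path(dir, "phenotypes.json"))
  expect_gte(length(ph), 1)
  expect_setequal(names(ph[[1]]),
                  c("name", "members", "max_discovery_prob", "mean_discovery_prob"))
  psm_df <- readr::read_csv(file.path(dir, "psm.csv"), show_col_types = FALSE)
  expect_equal(nrow(psm_df), nrow(compute_psm(shared$fit)))
})
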