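# Posterior summaries. All quantities here are label-switching invariant
# (co-clustering frequencies, discovery/outlier probabilities), so chains
# are pooled after their own burn-in without any relabelling step.

pooled_z <- function(fit, unlabelled_only = TRUE) {
  cols <- if (unlabelled_only) fit$chains[[1]]$unlabelled else fit$chains[[1]]$accessions
  do.call(rbind, purrr::map(fit$chains, function(ch) ch$z_draws[, cols, drop = FALSE]))
}

pooled_phi <- function(fit, unlabelled_only = FALSE) {
  cols <- if (unlabelled_only) fit$chains[[1]]$unlabelled else fit$chains[[1]]$accessions
  do.call(rbind, purrr::map(fit$chains, function(ch) ch$phi_draws[, cols, drop = FALSE]))
}

#' Posterior similarity matrix
#'
#' The `(i, j)` entry is the posterior probability that unlabelled proteins
#' `i` and `j` reside in the same mixture component, estimated as the
#' co-clustering frequency across all pooled retained draws. It is the
#' label-switching-invariant summary of the clustering posterior and the
#' basis of the maxPEAR consensus clustering. Only unlabelled proteins enter:
#' marker proteins have fixed assignments, so their co-clustering is
#' degenerate. When the fit's spec sets `psm_exclude_outliers`, draws in
#' which a protein has `phi = 0` do not count as co-clustering; by default
#' the latent component label of outlier draws is used.
#'
#' @param fit A `novelty_tagm` fit (or list of `ntagm_chain`s from
#'   [run_chains()], in which case the default outlier handling applies).
#' @return An `ntagm_psm`: symmetric matrix with unit diagonal and entries
#'   in `[0, 1]`, dimnames the unlabelled accessions.
#' @export
compute_psm <- function(fit) {
  if (!inherits(fit, "novelty_tagm")) fit <- list(chains = fit, spec = NULL)
  ch1 <- fit$chains[[1]]
  if (sum(purrr::map_int(fit$chains, "T")) < 1) abort("no retained draws")
  Z <- pooled_z(fit, unlabelled_only = TRUE)
  exclude <- isTRUE(fit$spec$psm_exclude_outliers)
  Phi <- if (exclude) pooled_phi(fit, unlabelled_only = TRUE) else NULL
  n_u <- ncol(Z)
  co <- matrix(0, n_u, n_u)
  for (k in sort(unique(as.vector(Z)))) {
    A <- Z == k
    if (exclude) A <- A & (Phi == 1)
    co <- co + crossprod(A)
  }
  psm <- co / nrow(Z)
  diag(psm) <- 1
  psm[psm > 1] <- 1
  dimnames(psm) <- list(ch1$unlabelled, ch1$unlabelled)
  structure(psm, class = c("ntagm_psm", "matrix", "array"))
}

#' Posterior mean allocation probabilities
#'
#' Monte-Carlo average of the retained Rao-Blackwellised conditionals
#' `P(z_i = k, phi_i = 1 | ...)` for every unlabelled protein, over the
#' pooled draws of all chains.
#'
#' @param fit A `novelty_tagm` fit.
#' @return `N_U x K_max` matrix; columns named by the known components
#'   followed by `novelty_1, ...`; row sums are at most one (the remainder
#'   is outlier mass).
#' @export
mean_allocation <- function(fit) {
  acc <- fit$chains[[1]]$unlabelled
  K_max <- fit$chains[[1]]$K_max
  tot <- matrix(0, length(acc), K_max)
  T_all <- 0
  for (ch in fit$chains) {
    tot <- tot + apply(ch$alloc_probs, c(1, 2), sum)
    T_all <- T_all + ch$T
  }
  out <- tot / T_all
  k_nov <- K_max - fit$chains[[1]]$K
  colnames(out) <- c(fit$chains[[1]]$components,
                     if (k_nov > 0) paste0("novelty_", seq_len(k_nov)))
  rownames(out) <- acc
  out
}

#' Discovery probability
#'
#' The posterior probability that an unlabelled protein belongs to one of
#' the novelty components rather than any known niche: one minus the
#' Monte-Carlo average of its summed conditional allocation over the K known
#' components. It separates genuinely novel localisation from mere
#' allocation uncertainty and drives the putative-phenotype rule.
#'
#' @param fit A `novelty_tagm` fit.
#' @return Tibble with `accession` and `discovery_prob` for each unlabelled
#'   protein.
#' @export
discovery_probability <- function(fit) {
  K <- fit$chains[[1]]$K
  acc <- fit$chains[[1]]$unlabelled
  tot <- numeric(length(acc))
  T_all <- 0
  for (ch in fit$chains) {
    known <- ch$alloc_probs[, seq_len(K), , drop = FALSE]
    tot <- tot + apply(known, 1, sum)
    T_all <- T_all + ch$T
  }
  tibble::tibble(accession = acc, discovery_prob = unname(1 - tot / T_all))
}

#' Outlier probability
#'
#' Posterior frequency of `phi_i = 0` (protein dispersed, captured by the
#' heavy-tailed Student-t component) across pooled retained draws; reported
#' for every protein, markers included.
#'
#' @param fit A `novelty_tagm` fit.
#' @return Tibble with `accession` and `outlier_prob`.
#' @export
outlier_probability <- function(fit) {
  Phi <- pooled_phi(fit, unlabelled_only = FALSE)
  tibble::tibble(accession = colnames(Phi),
                 outlier_prob = unname(colMeans(Phi == 0)))
}

#' Posterior expected adjusted Rand index of a candidate partition
#'
#' Computable in closed form from the PSM: with pair indicators
#' `I_ij = 1[c_i = c_j]` and PSM entries `p_ij` over pairs `i < j`,
#' `PEAR = (sum I p - sum I sum p / B) / ((sum I + sum p)/2 - sum I sum p / B)`
#' with `B` the number of pairs. Defined as 0 when the denominator vanishes.
#'
#' @param psm An `ntagm_psm` (or plain symmetric matrix).
#' @param labels Integer/character cluster labels, one per PSM row.
#' @return The PEAR score, a scalar.
#' @export
pear_score <- function(psm, labels) {
  n <- nrow(psm)
  stopifnot(length(labels) == n)
  ut <- upper.tri(psm)
  sum_p <- sum(psm[ut])
  I <- outer(labels, labels, "==")
  sum_i <- sum(I[ut])
  sum_ip <- sum(psm[ut][I[ut]])
  B <- n * (n - 1) / 2
  num <- sum_ip - sum_i * sum_p / B
  den <- 0.5 * (sum_i + sum_p) - sum_i * sum_p / B
  if (den == 0) 0 else num / den
}

#' maxPEAR consensus clustering
#'
#' Summarises the clustering posterior into a single partition by maximising
#' the posterior expected adjusted Rand index, evaluated in closed form from
#' the PSM. The candidate set is every cut of an average-linkage dendrogram
#' built on the dissimilarity `1 - PSM` (`N_U` candidates); with
#' `candidate_source = "draws"` the distinct partitions visited by the
#' sampler are screened as well. Deterministic given the PSM.
#'
#' @param psm An `ntagm_psm` from [compute_psm()].
#' @param candidate_source `"hierarchical"` (default) or `"draws"`.
#' @param fit The fit, required when `candidate_source = "draws"`.
#' @return Tibble with `accession` and integer `cluster`; the winning PEAR
#'   score and cluster count are attached as attributes `pear` and `k`.
#' @export
maxpear_clustering <- function(psm, candidate_source = c("hierarchical", "draws"),
                               fit = NULL) {
  candidate_source <- match.arg(candidate_source)
  n <- nrow(psm)
  acc <- rownames(psm)
  off <- psm[upper.tri(psm)]
  if (n > 1 && all(off < 1e-12)) {
    warn("degenerate PSM (no off-diagonal mass): returning singleton clusters")
    out <- tibble::tibble(accession = acc, cluster = seq_len(n))
    attr(out, "pear") <- 0
    attr(out, "k") <- n
    return(out)
  }
  hc <- stats::hclust(stats::as.dist(1 - psm), method = "average")
  candidates <- lapply(seq_len(n), function(k) stats::cutree(hc, k = k))
  if (candidate_source == "draws") {
    if (is.null(fit)) abort("candidate_source = 'draws' needs the fit")
    Z <- pooled_z(fit, unlabelled_only = TRUE)
    Z <- unique(Z)
    candidates <- c(candidates, lapply(seq_len(nrow(Z)), function(t) Z[t, ]))
  }
  scores <- vapply(candidates, function(cl) pear_score(psm, cl), numeric(1))
  best <- candidates[[which.max(scores)]]
  out <- tibble::tibble(accession = acc,
                        cluster = as.integer(factor(best, levels = unique(best))))
  attr(out, "pear") <- max(scores)
  attr(out, "k") <- length(unique(best))
  out
}

#' Extract putative phenotypes
#'
#' A maxPEAR cluster is reported as a putative phenotype when its posterior
#' mass lies predominantly on the novelty components (cluster-mean discovery
#' probability above `novelty_threshold`) and it contains at least one
#' protein whose discovery probability exceeds `threshold` (default 0.95).
#' Phenotypes are returned in decreasing size order and named
#' `"phenotype 1"`, `"phenotype 2"`, ...
#'
#' @param clustering Tibble from [maxpear_clustering()].
#' @param discovery Tibble from [discovery_probability()] over the same
#'   proteins.
#' @param threshold Per-protein discovery-probability threshold (default
#'   0.95).
#' @param novelty_threshold Cluster-mean discovery threshold for calling a
#'   cluster novel (default 0.5).
#' @return Tibble with `phenotype`, `cluster`, `n_members`, `members`
#'   (list-column), `mean_discovery_prob`, `max_discovery_prob`; empty when
#'   nothing qualifies.
#' @export
identify_phenotypes <- function(clustering, discovery, threshold = 0.95,
                                novelty_threshold = 0.5) {
  joined <- dplyr::inner_join(clustering, discovery, by = "accession")
  if (nrow(joined) != nrow(clustering)) {
    abort("clustering and discovery probabilities cover different proteins")
  }
  out <- joined |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      members = list(.data$accession),
      mean_discovery_prob = mean(.data$discovery_prob),
      max_discovery_prob = max(.data$discovery_prob),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$mean_discovery_prob > novelty_threshold,
                  .data$max_discovery_prob > threshold) |>
    dplyr::arrange(dplyr::desc(.data$n_members))
  dplyr::bind_cols(
    tibble::tibble(phenotype = if (nrow(out) > 0) paste("phenotype", seq_len(nrow(out))) else character()),
    out
  )
}

#' One-call posterior summary
#'
#' Runs the whole summarisation cascade: PSM, maxPEAR clustering, discovery
#' and outlier probabilities, mean allocations, and putative phenotypes.
#'
#' @param fit A `novelty_tagm` fit.
#' @param threshold,novelty_threshold Passed to [identify_phenotypes()].
#' @return An `ntagm_summary` list with elements `psm`, `clustering`,
#'   `discovery`, `outlier`, `alloc`, `phenotypes`.
#' @export
summarise_posterior <- function(fit, threshold = 0.95, novelty_threshold = 0.5) {
  psm <- compute_psm(fit)
  clustering <- maxpear_clustering(psm)
  discovery <- discovery_probability(fit)
  structure(
    list(
      psm = psm,
      clustering = clustering,
      discovery = discovery,
      outlier = outlier_probability(fit),
      alloc = mean_allocation(fit),
      phenotypes = identify_phenotypes(clustering, discovery,
                                       threshold = threshold,
                                       novelty_threshold = novelty_threshold)
    ),
    class = "ntagm_summary"
  )
}

#' @rdname summarise_posterior
#' @return For `summarise_phenotypes()`, just the phenotype tibble.
#' @export
summarise_phenotypes <- function(fit, threshold = 0.95, novelty_threshold = 0.5) {
  summarise_posterior(fit, threshold, novelty_threshold)$phenotypes
}

#' Per-protein allocation table
#'
#' For every unlabelled protein: the best-supported known component, its
#' posterior mean allocation probability, and the outlier and discovery
#' probabilities. This is also the [tidy()] method of the fit.
#'
#' @param fit A `novelty_tagm` fit.
#' @return Tibble with columns `accession`, `best_component`,
#'   `best_component_prob`, `outlier_prob`, `discovery_prob`.
#' @export
allocation_table <- function(fit) {
  alloc <- mean_allocation(fit)
  K <- fit$chains[[1]]$K
  known <- alloc[, seq_len(K), drop = FALSE]
  best <- max.col(known, ties.method = "first")
  tibble::tibble(
    accession = rownames(alloc),
    best_component = colnames(known)[best],
    best_component_prob = known[cbind(seq_len(nrow(known)), best)]
  ) |>
    dplyr::left_join(outlier_probability(fit), by = "accession") |>
    dplyr::left_join(discovery_probability(fit), by = "accession")
}

#' @exportS3Method generics::tidy
tidy.novelty_tagm <- function(x, ...) allocation_table(x)

#' @exportS3Method generics::glance
glance.novelty_tagm <- function(x, ...) {
  d <- diagnose(x)
  occ <- unlist(purrr::map(x$chains, "occupied_trace"))
  tibble::tibble(
    n_proteins = length(x$chains[[1]]$accessions),
    n_unlabelled = length(x$chains[[1]]$unlabelled),
    K = x$spec$K,
    k_novelty = x$spec$k_novelty,
    chains = length(x$chains),
    draws = sum(purrr::map_int(x$chains, "T")),
    eps_mean = mean(unlist(purrr::map(x$chains, "eps_draws"))),
    occupied_median = stats::median(occ),
    rhat_occupied = d$rhat
  )
}

#' Export summary tables to flat files
#'
#' Writes `allocation.csv`, `psm.csv`, `phenotypes.json` (schema: `name`,
#' `members`, `max_discovery_prob`, `mean_discovery_prob`), and
#' `diagnostics.csv` into a directory.
#'
#' @param fit A `novelty_tagm` fit.
#' @param dir Output directory (created if absent).
#' @param threshold Phenotype discovery threshold.
#' @return `dir`, invisibly.
#' @export
export_summaries <- function(fit, dir, threshold = 0.95) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- summarise_posterior(fit, threshold = threshold)
  readr::write_csv(allocation_table(fit), file.path(dir, "allocation.csv"),
                   progress = FALSE)
  psm_df <- tibble::as_tibble(as.data.frame(unclass(s$psm)), .name_repair = "minimal")
  psm_df <- dplyr::bind_cols(tibble::tibble(accession = rownames(s$psm)), psm_df)
  readr::write_csv(psm_df, file.path(dir, "psm.csv"), progress = FALSE)
  phen <- purrr::pmap(
    list(s$phenotypes$phenotype, s$phenotypes$members,
         s$phenotypes$max_discovery_prob, s$phenotypes$mean_discovery_prob),
    function(nm, mem, mx, mn) list(name = nm, members = mem,
                                   max_discovery_prob = mx,
                                   mean_discovery_prob = mn)
  )
  jsonlite::write_json(phen, file.path(dir, "phenotypes.json"),
                       auto_unbox = TRUE, digits = NA)
  d <- diagnose(fit)
  readr::write_csv(dplyr::mutate(d$chains, rhat_occupied = d$rhat),
                   file.path(dir, "diagnostics.csv"), progress = FALSE)
  invisible(dir)
}
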