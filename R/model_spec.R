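#' Model specification: priors and fixed hyperparameters
#'
#' Collects every fixed and prior hyperparameter of the augmented mixture:
#' the empirical Student-t outlier parameters, the number of overfitted
#' novelty components, the conjugate Normal-Inverse-Wishart (NIW) prior
#' shared by all Gaussian components, the symmetric Dirichlet concentration
#' on the mixture weights, and the Beta prior on the outlier rate epsilon.
#'
#' Defaults follow the empirical-Bayes conventions of the TAGM lineage:
#' `mu0` is the global data mean, `lambda0 = 0.01` (weak prior mass on the
#' location), `nu0 = L + 2` (weakest proper value retaining a finite prior
#' covariance), and `S0 = cov(X) / Kmax^(2/L)`, which scales the prior
#' scatter to the share of total variance a single component is expected to
#' carry. Novelty components share the same NIW prior as known components:
#' exchangeability across empty components is what makes the overfitted
#' mixture leave unsupported components empty. `dirichlet_concentration`
#' defaults to 1; large values inhibit that emptying and are discouraged.
#' The outlier-rate prior defaults to Beta(2, 10), weakly favouring a small
#' outlier fraction.
#'
#' @param profiles Profile tibble (used for empirical defaults).
#' @param markers Marker tibble defining the K known components.
#' @param k_novelty Number of extra, initially empty novelty components
#'   (default 10, ample in practice for phenotype discovery).
#' @param dirichlet_concentration Symmetric Dirichlet concentration on the
#'   mixture weights.
#' @param eps_prior Length-2 numeric `(u, v)`, shape parameters of the Beta
#'   prior on the outlier rate.
#' @param niw_prior Optional list overriding any of `mu0`, `lambda0`, `nu0`,
#'   `S0`.
#' @param outlier Optional `outlier_params` object; default
#'   [empirical_outlier_params()] of the data.
#' @param outlier_scale Passed to [empirical_outlier_params()] when `outlier`
#'   is not supplied: `"full"` (default) or `"diagonal"`.
#' @param fix_marker_phi If `TRUE`, marker proteins are never re-assigned to
#'   the outlier component; default `FALSE` (markers may be outliers relative
#'   to their own class).
#' @param psm_exclude_outliers If `TRUE`, draws in which a protein carries
#'   `phi = 0` never count as co-clustering for the posterior similarity
#'   matrix; default `FALSE` (the latent component label is used).
#'
#' @return An object of class `ntagm_spec`.
#' @export
model_spec <- function(profiles, markers,
                       k_novelty = 10,
                       dirichlet_concentration = 1,
                       eps_prior = c(u = 2, v = 10),
                       niw_prior = NULL,
                       outlier = NULL,
                       outlier_scale = c("full", "diagonal"),
                       fix_marker_phi = FALSE,
                       psm_exclude_outliers = FALSE) {
  profiles <- validate_profiles(profiles)
  markers <- validate_markers(markers, profiles)
  m <- profile_matrix(profiles)
  L <- ncol(m)
  comps <- component_names(markers)
  K <- length(comps)
  k_novelty <- as.integer(k_novelty)
  if (k_novelty < 0) abort("k_novelty must be >= 0")
  K_max <- K + k_novelty

  if (is.null(outlier)) {
    outlier <- empirical_outlier_params(profiles, scale = match.arg(outlier_scale))
  }
  niw <- list(
    mu0 = colMeans(m),
    lambda0 = 0.01,
    nu0 = L + 2,
    S0 = stats::cov(m) / K_max^(2 / L)
  )
  if (!is.null(niw_prior)) niw[names(niw_prior)] <- niw_prior

  spec <- structure(
    list(
      components = comps, K = K, k_novelty = k_novelty, K_max = K_max, L = L,
      fractions = names(profiles)[-1],
      outlier = outlier, niw = niw,
      dirichlet_concentration = dirichlet_concentration,
      eps_prior = c(u = unname(eps_prior[1]), v = unname(eps_prior[2])),
      fix_marker_phi = isTRUE(fix_marker_phi),
      psm_exclude_outliers = isTRUE(psm_exclude_outliers)
    ),
    class = "ntagm_spec"
  )
  validate_spec(spec)
}

validate_spec <- function(spec) {
  with(spec, {
    if (niw$nu0 <= L - 1) abort("invalid prior: nu0 must exceed L - 1")
    if (niw$lambda0 <= 0) abort("invalid prior: lambda0 must be positive")
    if (dirichlet_concentration <= 0) abort("dirichlet_concentration must be positive")
    if (any(eps_prior <= 0)) abort("eps_prior shapes must be positive")
    if (outlier$kappa <= 0) abort("outlier kappa must be positive")
    if (!isTRUE(all.equal(outlier$V, t(outlier$V), tolerance = 1e-8))) {
      abort("outlier scale V must be symmetric")
    }
    if (min(eigen(outlier$V, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      abort("outlier scale V must be positive semi-definite")
    }
  })
  spec
}

#' @export
print.ntagm_spec <- function(x, ...) {
  cat("Novelty TAGM model specification\n")
  cat("  K known components: ", x$K, " (", paste(head(x$components, 5), collapse = ", "),
      if (x$K > 5) ", ..." else "", ")\n", sep = "")
  cat("  K_novelty:", x$k_novelty, " -> K_max:", x$K_max, "\n")
  cat("  L fractions:", x$L, "\n")
  cat("  NIW prior: lambda0 =", x$niw$lambda0, ", nu0 =", x$niw$nu0, "\n")
  cat("  Dirichlet concentration:", x$dirichlet_concentration,
      "| eps ~ Beta(", x$eps_prior[1], ",", x$eps_prior[2], ")\n")
  invisible(x)
}

#' Serialise / deserialise a model specification to YAML
#'
#' Every hyperparameter is written by name; matrices are stored row-wise.
#'
#' @param spec An `ntagm_spec`.
#' @param path Output YAML path.
#' @return `path` invisibly; for the reader, the restored `ntagm_spec`.
#' @export
write_model_spec <- function(spec, path) {
  ser <- list(
    components = as.list(spec$components),
    k_novelty = spec$k_novelty,
    fractions = as.list(spec$fractions),
    outlier = list(kappa = spec$outlier$kappa,
                   M = as.numeric(spec$outlier$M),
                   V = mat_to_rows(spec$outlier$V)),
    niw = list(mu0 = as.numeric(spec$niw$mu0), lambda0 = spec$niw$lambda0,
               nu0 = spec$niw$nu0, S0 = mat_to_rows(spec$niw$S0)),
    dirichlet_concentration = spec$dirichlet_concentration,
    eps_prior = list(u = unname(spec$eps_prior[1]), v = unname(spec$eps_prior[2])),
    fix_marker_phi = spec$fix_marker_phi,
    psm_exclude_outliers = spec$psm_exclude_outliers
  )
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  y <- yaml::read_yaml(path)
  comps <- unlist(y$components)
  L <- length(y$niw$mu0)
  spec <- structure(
    list(
      components = comps, K = length(comps),
      k_novelty = as.integer(y$k_novelty),
      K_max = length(comps) + as.integer(y$k_novelty), L = L,
      fractions = unlist(y$fractions),
      outlier = structure(list(kappa = y$outlier$kappa,
                               M = as.numeric(y$outlier$M),
                               V = rows_to_mat(y$outlier$V)),
                          class = "outlier_params"),
      niw = list(mu0 = as.numeric(y$niw$mu0), lambda0 = y$niw$lambda0,
                 nu0 = y$niw$nu0, S0 = rows_to_mat(y$niw$S0)),
      dirichlet_concentration = y$dirichlet_concentration,
      eps_prior = c(u = y$eps_prior$u, v = y$eps_prior$v),
      fix_marker_phi = isTRUE(y$fix_marker_phi),
      psm_exclude_outliers = isTRUE(y$psm_exclude_outliers)
    ),
    class = "ntagm_spec"
  )
  validate_spec(spec)
}

mat_to_rows <- function(m) lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
rows_to_mat <- function(rows) do.call(rbind, lapply(rows, as.numeric))
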