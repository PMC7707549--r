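#' Describe a synthetic spatial-proteomics experiment
#'
#' The generator draws data from the model's own generative process:
#' well-separated Gaussian niches, a heavy-tailed Student-t outlier
#' component, and optionally hidden (unannotated) phenotypes that carry no
#' markers. Component means are placed with pairwise distance
#' `separation * sigma * sqrt(L)`: separation is measured in units of the
#' within-component spread, taken as the RMS radius `sqrt(L) * sigma` of an
#' L-dimensional spherical Gaussian so that niche overlap (and hence the
#' difficulty of recovery) is comparable across profile lengths.
#'
#' @param K_visible Number of marker-annotated components.
#' @param K_hidden Number of unannotated (hidden) phenotypes.
#' @param n_per_component Proteins per component.
#' @param L Number of fractions (profile length).
#' @param marker_fraction Share of each visible component's proteins that
#'   receive a marker label; markers are drawn among inlier proteins only,
#'   mimicking curated marker lists.
#' @param outlier_fraction Probability a protein is drawn from the t4
#'   outlier component instead of its niche.
#' @param separation Mean inter-component distance in within-component
#'   standard deviations.
#' @param sigma Within-component standard deviation.
#' @param covariance `"spherical"` (default) or `"anisotropic"` component
#'   covariances.
#' @param simplex If `TRUE`, apply a row-wise softmax so profiles resemble
#'   sum-normalised LOPIT data.
#' @param seed Integer seed; the whole dataset is deterministic given the
#'   design.
#' @return An `ntagm_design` list.
#' @export
simulation_design <- function(K_visible = 5, K_hidden = 0, n_per_component = 40,
                              L = 10, marker_fraction = 0.5,
                              outlier_fraction = 0, separation = 5, sigma = 1,
                              covariance = c("spherical", "anisotropic"),
                              simplex = FALSE, seed = 1) {
  covariance <- match.arg(covariance)
  d <- list(K_visible = as.integer(K_visible), K_hidden = as.integer(K_hidden),
            n_per_component = as.integer(n_per_component), L = as.integer(L),
            marker_fraction = marker_fraction,
            outlier_fraction = outlier_fraction, separation = separation,
            sigma = sigma, covariance = covariance, simplex = isTRUE(simplex),
            seed = as.integer(seed))
  if (d$K_visible < 1 || d$K_hidden < 0 || d$n_per_component < 1 || d$L < 2) {
    abort("invalid design: need K_visible >= 1, K_hidden >= 0, n_per_component >= 1, L >= 2")
  }
  if (d$marker_fraction < 0 || d$marker_fraction > 1 ||
      d$outlier_fraction < 0 || d$outlier_fraction > 1) {
    abort("marker_fraction and outlier_fraction must lie in [0, 1]")
  }
  if (d$separation <= 0 || d$sigma <= 0) abort("separation and sigma must be positive")
  structure(d, class = "ntagm_design")
}

# Component means with guaranteed pairwise distance separation * sigma *
# sqrt(L): separation counts multiples of the within-component RMS radius
# sqrt(L * sigma^2), so the overlap between niches is comparable across
# profile lengths. With K <= L the means sit on scaled orthonormal
# directions (exactly equidistant); otherwise rejection sampling, failing
# with a design error when the space is too crowded.
place_means <- function(K, L, separation, sigma) {
  target <- separation * sigma * sqrt(L)
  if (K <= L) {
    Q <- qr.Q(qr(matrix(stats::rnorm(L * K), L, K)))
    return(t(Q) * target / sqrt(2))
  }
  for (try in 1:2000) {
    M <- matrix(stats::rnorm(K * L, sd = 1.5 * target), K, L)
    if (min(stats::dist(M)) >= target) return(M)
  }
  abort("design error: cannot place this many components at the requested separation for the given L")
}

#' Simulate a spatial-proteomics dataset from the generative model
#'
#' @param design An `ntagm_design` from [simulation_design()].
#' @return List with `profiles` (tibble), `markers` (tibble; labels
#'   `niche_1, ..., niche_Kv` for the visible components), and `truth` — a
#'   tibble recording for every protein its generating `component` (hidden
#'   phenotypes are numbered after the visible niches), the outlier
#'   indicator `phi`, and whether it was given a marker. The generating
#'   component means are attached as attribute `means`.
#' @export
simulate_spatial_proteome <- function(design) {
  stopifnot(inherits(design, "ntagm_design"))
  set.seed(design$seed)
  K <- design$K_visible + design$K_hidden
  L <- design$L
  n <- design$n_per_component
  N <- K * n
  means <- place_means(K, L, design$separation, design$sigma)
  sds <- if (design$covariance == "anisotropic") {
    matrix(stats::runif(K * L, 0.5, 1.5) * design$sigma, K, L)
  } else {
    matrix(design$sigma, K, L)
  }
  comp <- rep(seq_len(K), each = n)
  phi <- stats::rbinom(N, 1, 1 - design$outlier_fraction)
  out_loc <- colMeans(means)
  out_sd <- design$separation * design$sigma * sqrt(L) / 2
  X <- matrix(0, N, L)
  for (i in seq_len(N)) {
    if (phi[i] == 1) {
      X[i, ] <- means[comp[i], ] + stats::rnorm(L) * sds[comp[i], ]
    } else {
      w <- stats::rchisq(1, df = 4) / 4
      X[i, ] <- out_loc + out_sd * stats::rnorm(L) / sqrt(w)
    }
  }
  if (design$simplex) {
    X <- exp(X - apply(X, 1, max))
    X <- X / rowSums(X)
  }
  acc <- sprintf("P%05d", seq_len(N))
  ord <- sample.int(N)
  X <- X[ord, , drop = FALSE]
  comp <- comp[ord]
  phi <- phi[ord]

  is_marker <- rep(FALSE, N)
  for (k in seq_len(design$K_visible)) {
    inliers <- which(comp == k & phi == 1)
    if (length(inliers) == 0) {
      abort("no inlier proteins available to serve as markers; lower outlier_fraction")
    }
    n_mark <- max(1L, round(design$marker_fraction * sum(comp == k)))
    n_mark <- min(n_mark, length(inliers))
    is_marker[sample(inliers, n_mark)] <- TRUE
  }

  profiles <- dplyr::bind_cols(
    tibble::tibble(accession = acc),
    tibble::as_tibble(X, .name_repair = ~ paste0("fraction_", seq_len(L)))
  )
  markers <- tibble::tibble(
    accession = acc[is_marker],
    markers = paste0("niche_", comp[is_marker])
  )
  truth <- tibble::tibble(accession = acc, component = comp, phi = phi,
                          is_marker = is_marker)
  attr(truth, "means") <- means
  list(profiles = profiles, markers = validate_markers(markers, profiles),
       truth = truth)
}

#' Build a masking-validation fixture
#'
#' Simulates one dataset and returns it twice: once with the full marker
#' annotation and once with an entire visible component's markers hidden
#' (via [mask_component()]). Refitting on the masked copy and checking that
#' the hidden niche resurfaces as a putative phenotype is the synthetic
#' analogue of masking a chromatin annotation and rediscovering it.
#'
#' @param design An `ntagm_design`.
#' @param masked Index (in `1..K_visible`) of the component to mask.
#' @return List with `full` and `masked` dataset lists (each `profiles`,
#'   `markers`, `truth`) and `masked_label`.
#' @export
make_masking_fixture <- function(design, masked = 1) {
  stopifnot(inherits(design, "ntagm_design"))
  if (masked < 1 || masked > design$K_visible) {
    abort("masked component index must be in 1..K_visible")
  }
  sim <- simulate_spatial_proteome(design)
  label <- paste0("niche_", masked)
  masked_markers <- mask_component(sim$markers, label)
  list(
    full = sim,
    masked = list(profiles = sim$profiles, markers = masked_markers,
                  truth = sim$truth),
    masked_label = label
  )
}
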