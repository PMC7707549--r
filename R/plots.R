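# The two standard views of a fit: a PCA of the profiles with point size
# tracking the discovery probability, and a heatmap of the PSM restricted to
# confidently novel proteins, ordered by the maxPEAR clustering.

#' Proteins passing the PSM heatmap filters
#'
#' @param summary An `ntagm_summary` from [summarise_posterior()].
#' @param discovery_filter Minimum discovery probability for inclusion
#'   (default 0.99).
#' @param outlier_filter Maximum outlier probability for inclusion
#'   (default 0.95; typical choices range from strict `1e-5` to lenient
#'   `0.95` depending on how dispersed the dataset is).
#' @return Character vector of accessions satisfying both filters.
#' @export
psm_filter <- function(summary, discovery_filter = 0.99, outlier_filter = 0.95) {
  stopifnot(inherits(summary, "ntagm_summary"))
  if (discovery_filter < 0 || discovery_filter > 1 ||
      outlier_filter < 0 || outlier_filter > 1) {
    abort("filters must lie in [0, 1]")
  }
  d <- summary$discovery
  o <- summary$outlier
  keep <- d$accession[d$discovery_prob > discovery_filter]
  intersect(keep, o$accession[o$outlier_prob < outlier_filter])
}

#' PCA of the profiles, scaled by discovery probability
#'
#' Projects all protein profiles onto the first two principal components.
#' Marker proteins are coloured by their annotated niche; unlabelled
#' proteins are grey with point size increasing linearly in their discovery
#' probability, so candidate members of new phenotypes stand out.
#'
#' @param fit A `novelty_tagm` fit.
#' @param min_size,max_size Point-size range for the linear
#'   discovery-probability mapping.
#' @return A ggplot object.
#' @export
plot_pca <- function(fit, min_size = 0.8, max_size = 3.5) {
  X <- profile_matrix(fit$profiles)
  if (ncol(X) < 2) abort("PCA needs at least two fractions")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  disc <- discovery_probability(fit)
  df <- tibble::tibble(
    accession = rownames(X),
    PC1 = unname(pc$x[, 1]), PC2 = unname(pc$x[, 2])
  ) |>
    dplyr::left_join(fit$markers, by = "accession") |>
    dplyr::left_join(disc, by = "accession") |>
    dplyr::mutate(
      markers = dplyr::coalesce(.data$markers, "unknown"),
      discovery_prob = dplyr::coalesce(.data$discovery_prob, 0)
    )
  ve <- 100 * pc$sdev[1:2]^2 / sum(pc$sdev^2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$markers,
                                     size = .data$discovery_prob),
                        alpha = 0.8) +
    ggplot2::scale_size_continuous(range = c(min_size, max_size),
                                   limits = c(0, 1), name = "discovery prob.") +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", ve[1]),
                  y = sprintf("PC2 (%.1f%%)", ve[2]), colour = "component") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.novelty_tagm <- function(object, type = c("pca", "psm"), ...) {
  type <- match.arg(type)
  if (type == "pca") plot_pca(object, ...) else plot_psm(object, ...)
}

#' PSM heatmap of confidently novel proteins
#'
#' Shows the posterior similarity matrix restricted to unlabelled proteins
#' with discovery probability above `discovery_filter` and outlier
#' probability below `outlier_filter`, with rows and columns ordered by the
#' maxPEAR clustering so coherent putative phenotypes appear as blocks.
#'
#' @param fit A `novelty_tagm` fit or a precomputed `ntagm_summary`.
#' @inheritParams psm_filter
#' @return A ggplot object; with zero proteins passing the filters, an empty
#'   annotated sentinel plot is returned with a warning.
#' @export
plot_psm <- function(fit, discovery_filter = 0.99, outlier_filter = 0.95) {
  summary <- if (inherits(fit, "ntagm_summary")) fit else summarise_posterior(fit)
  keep <- psm_filter(summary, discovery_filter, outlier_filter)
  if (length(keep) == 0) {
    warn("no proteins pass the discovery/outlier filters; returning empty plot")
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0,
                               label = "no proteins pass filters") +
             ggplot2::theme_void())
  }
  cl <- summary$clustering
  ord <- cl$accession[cl$accession %in% keep]
  ord <- ord[order(cl$cluster[match(ord, cl$accession)])]
  m <- summary$psm[ord, ord, drop = FALSE]
  df <- tibble::as_tibble(as.data.frame(as.table(m), stringsAsFactors = FALSE),
                          .name_repair = ~ c("protein_i", "protein_j", "prob"))
  df$protein_i <- factor(df$protein_i, levels = ord)
  df$protein_j <- factor(df$protein_j, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$protein_i, y = .data$protein_j,
                                   fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#08306b",
                                 limits = c(0, 1),
                                 name = "posterior\nco-clustering") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   axis.ticks = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = NULL)
}
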