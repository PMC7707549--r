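#' Read a quantitative protein-profile matrix
#'
#' Reads an N-protein by L-fraction table of relative abundances, the standard
#' flat-file export of LOPIT / hyperLOPIT / LOPIT-DC / organellar-map
#' experiments. The first column must hold unique protein accessions; every
#' remaining column is a numeric quantitation channel (fraction).
#'
#' @param path Path to a delimited text file with header
#'   `accession,<fraction1>,...,<fractionL>`.
#' @param dialect `"auto"` (default, by file extension), `"csv"` or `"tsv"`.
#'
#' @return A tibble with a character `accession` column followed by `L >= 2`
#'   numeric fraction columns; one row per protein, row order as on file.
#'
#' @details Cells that are empty, `NA`, or otherwise non-numeric are a parse
#'   error reported with their row and column; duplicated accessions are a
#'   validation error. Profiles are used as supplied — published datasets ship
#'   pre-normalised. Use [normalise_profiles()] if per-row sum-to-one scaling
#'   is wanted.
#'
#' @seealso [write_profiles()], [read_markers()], [empirical_outlier_params()]
#' @export
read_profiles <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("profile file not found: ", path))
  }
  delim <- switch(dialect,
    csv = ",",
    tsv = "\t",
    auto = if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  )
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, na = character())
  if (ncol(raw) < 3) {
    abort("profile file needs an accession column plus at least two fraction columns")
  }
  names(raw)[1] <- "accession"
  vals <- raw[-1]
  for (j in seq_along(vals)) {
    x <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(!is.finite(x))
    if (length(bad) > 0) {
      abort(sprintf(
        "non-numeric or missing value in profile file at row %d, column '%s' (value: '%s')",
        bad[1], names(vals)[j], vals[[j]][bad[1]]
      ))
    }
    vals[[j]] <- x
  }
  out <- dplyr::bind_cols(tibble::tibble(accession = raw$accession), vals)
  validate_profiles(out)
}

#' Write a profile matrix back to CSV
#'
#' Values are written with shortest round-trip decimal representation, so
#' `read_profiles(write_profiles(p))` reproduces `p` to full precision.
#'
#' @param profiles A profile tibble as returned by [read_profiles()].
#' @param path Output file path (CSV).
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  profiles <- validate_profiles(profiles)
  readr::write_csv(profiles, path, progress = FALSE)
  invisible(path)
}

#' Validate an in-memory profile tibble
#'
#' @param profiles Data frame with character first column `accession` and
#'   numeric fraction columns.
#' @return The validated tibble (invisibly coerced to tibble).
#' @export
validate_profiles <- function(profiles) {
  profiles <- tibble::as_tibble(profiles)
  if (ncol(profiles) < 2 || names(profiles)[1] != "accession") {
    abort("profiles must have an 'accession' first column and >= 1 fraction column")
  }
  if (anyDuplicated(profiles$accession) > 0) {
    dup <- profiles$accession[duplicated(profiles$accession)][1]
    abort(paste0("duplicate accession in profiles: ", dup))
  }
  if (anyDuplicated(names(profiles)) > 0) {
    abort("fraction identifiers must be unique")
  }
  num_ok <- vapply(profiles[-1], is.numeric, logical(1))
  if (!all(num_ok)) {
    abort(paste0("fraction column is not numeric: ", names(profiles)[-1][!num_ok][1]))
  }
  if (!all(vapply(profiles[-1], function(x) all(is.finite(x)), logical(1)))) {
    abort("profiles contain non-finite values; imputation is out of scope")
  }
  if (nrow(profiles) < 1) abort("profiles must contain at least one protein")
  profiles
}

#' Extract the numeric N x L matrix from a profile tibble
#'
#' @param profiles A profile tibble.
#' @return Numeric matrix with accessions as rownames.
#' @export
profile_matrix <- function(profiles) {
  profiles <- validate_profiles(profiles)
  m <- as.matrix(profiles[-1])
  rownames(m) <- profiles$accession
  m
}

#' Per-row sum-to-one normalisation
#'
#' Optional; off by default throughout the package since published spatial
#' proteomics matrices are distributed pre-normalised.
#'
#' @param profiles A profile tibble.
#' @return The profile tibble with each row rescaled to sum to one.
#' @export
normalise_profiles <- function(profiles) {
  profiles <- validate_profiles(profiles)
  m <- as.matrix(profiles[-1])
  rs <- rowSums(m)
  if (any(rs == 0)) abort("cannot normalise a row with zero total signal")
  profiles[-1] <- tibble::as_tibble(m / rs)
  profiles
}

#' Read a marker map
#'
#' Reads the curated marker annotation: a two-column `accession,markers` table
#' assigning a subset of proteins to K known sub-cellular components. These
#' labelled proteins form the training set `X_L`; every profile row without a
#' marker is unlabelled (`X_U`). The literal label `unknown` is treated as
#' unlabelled, for compatibility with pRoloc-style exports.
#'
#' @param path Path to a CSV/TSV file with header `accession,markers`.
#' @param profiles The companion profile tibble; every marker accession must
#'   occur in it (case-sensitive exact match).
#' @return A marker tibble with columns `accession`, `markers`.
#' @export
read_markers <- function(path, profiles) {
  if (!file.exists(path)) abort(paste0("marker file not found: ", path))
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  if (ncol(raw) != 2) abort("marker file must have exactly two columns: accession, markers")
  names(raw) <- c("accession", "markers")
  raw <- dplyr::filter(raw, .data$markers != "unknown")
  validate_markers(raw, profiles)
}

#' Validate a marker tibble against its profile matrix
#'
#' @param markers Tibble with columns `accession`, `markers`.
#' @param profiles The companion profile tibble.
#' @return The validated marker tibble.
#' @export
validate_markers <- function(markers, profiles) {
  markers <- tibble::as_tibble(markers)
  if (!all(c("accession", "markers") %in% names(markers))) {
    abort("markers must have columns 'accession' and 'markers'")
  }
  markers <- markers[c("accession", "markers")]
  profiles <- validate_profiles(profiles)
  missing <- setdiff(markers$accession, profiles$accession)
  if (length(missing) > 0) {
    abort(paste0("marker accession absent from profiles: ", missing[1]))
  }
  if (anyDuplicated(markers$accession) > 0) {
    abort("a protein may carry at most one marker label")
  }
  tab <- table(markers$markers)
  if (length(tab) < 1) abort("marker map must define at least one component")
  if (any(tab < 1)) abort("every component must have at least one marker")
  markers
}

#' Component labels of a marker map
#' @param markers A marker tibble.
#' @return Character vector of the K distinct component names, sorted.
#' @export
component_names <- function(markers) sort(unique(markers$markers))

#' Hide the annotation of an entire component
#'
#' Moves all marker proteins of one component into the unlabelled set,
#' reducing K by one. This is the masking device used to validate novelty
#' detection: hide a whole niche, refit, and ask whether it is rediscovered
#' as a putative phenotype. The removed rows are retained (as an attribute)
#' so [unmask_component()] restores the original map exactly.
#'
#' @param markers A marker tibble.
#' @param label Name of the component to mask.
#' @return The marker tibble without that component's rows.
#' @export
mask_component <- function(markers, label) {
  comps <- component_names(markers)
  if (!label %in% comps) {
    abort(paste0("unknown component label: ", label))
  }
  if (length(comps) == 1) {
    abort("cannot mask the only component: at least one marker class must remain")
  }
  keep_idx <- which(markers$markers != label)
  drop_idx <- which(markers$markers == label)
  out <- markers[keep_idx, ]
  masked <- attr(markers, "masked")
  if (is.null(masked)) masked <- list()
  masked[[label]] <- list(rows = markers[drop_idx, ], at = drop_idx)
  attr(out, "masked") <- masked
  out
}

#' Restore a previously masked component
#'
#' @param markers A marker tibble produced by [mask_component()].
#' @param label Component to restore; default restores the most recent mask.
#' @return The marker tibble with the component re-inserted at its original
#'   row positions; `mask_component()` then `unmask_component()` is the
#'   identity.
#' @export
unmask_component <- function(markers, label = NULL) {
  masked <- attr(markers, "masked")
  if (is.null(masked) || length(masked) == 0) {
    abort("no masked component to restore")
  }
  if (is.null(label)) label <- names(masked)[length(masked)]
  if (!label %in% names(masked)) {
    abort(paste0("component was not masked: ", label))
  }
  entry <- masked[[label]]
  n_out <- nrow(markers) + nrow(entry$rows)
  out <- tibble::tibble(accession = character(n_out), markers = character(n_out))
  out[entry$at, ] <- entry$rows
  out[setdiff(seq_len(n_out), entry$at), ] <- markers[c("accession", "markers")]
  masked[[label]] <- NULL
  if (length(masked) > 0) attr(out, "masked") <- masked
  out
}

#' Empirical parameters of the Student-t outlier component
#'
#' The heavy-tailed outlier component is fixed empirically from the data
#' (labelled and unlabelled proteins together): degrees of freedom
#' `kappa = 4`, location `M` the global column mean, and scale `V` half the
#' global empirical covariance (unbiased, N - 1 denominator).
#'
#' @param profiles A profile tibble with N >= 2 proteins.
#' @param scale `"full"` (default) uses the full L x L covariance;
#'   `"diagonal"` keeps only its diagonal.
#' @return An object of class `outlier_params`: list with `kappa`, `M`, `V`.
#' @export
empirical_outlier_params <- function(profiles, scale = c("full", "diagonal")) {
  scale <- match.arg(scale)
  m <- profile_matrix(profiles)
  if (nrow(m) < 2) abort("need at least two proteins to estimate the outlier scale")
  V <- 0.5 * stats::cov(m)
  if (scale == "diagonal") V <- diag(diag(V), ncol(m))
  structure(
    list(kappa = 4, M = colMeans(m), V = V),
    class = "outlier_params"
  )
}

#' @export
print.outlier_params <- function(x, ...) {
  cat("Student-t outlier component: kappa =", x$kappa,
      "| L =", length(x$M), "fractions\n")
  invisible(x)
}
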