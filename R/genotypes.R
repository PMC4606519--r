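#' Centre a raw genotype matrix
#'
#' Builds the genotype container used by all samplers.  Each column of the
#' raw matrix (individuals in rows, markers in columns; codes 0/1/2 or real
#' dosages) is centred by subtracting its observed mean, so that every
#' column is exactly orthogonal to the intercept.  Missing values (`NA`) are
#' mean-imputed before centring (they become exactly 0 afterwards) and the
#' imputed count is reported.  Per-marker cross-products \eqn{X_j'X_j} are
#' cached, and markers with a (numerically) zero cross-product are flagged
#' as monomorphic: their inclusion indicator is pinned to 0 by the samplers.
#'
#' @param raw numeric matrix or data frame, individuals x markers.  Row
#'   names are taken as individual IDs, column names as marker IDs.
#' @param means optional numeric vector of per-column centring means (e.g.
#'   the *training* means when centring a test set).  Default: observed
#'   column means of `raw` (after imputation).
#' @return an object of class `genotype_matrix` with elements `values`
#'   (centred matrix), `n_individuals`, `n_markers`, `marker_ids`,
#'   `individual_ids`, `xtx`, `col_means`, `monomorphic`, `is_centered`,
#'   `n_imputed`.
#' @examples
#' G <- center_genotypes(matrix(c(0, 1, 2, 2, 2, 2), ncol = 2))
#' G$values
#' G$xtx
#' @export
center_genotypes <- function(raw, means = NULL) {
  if (is.data.frame(raw)) raw <- as.matrix(raw)
  if (!is.matrix(raw)) stop("`raw` must be a matrix or data frame")
  if (!is.numeric(raw)) {
    bad <- which(!vapply(as.vector(raw), is.numeric, logical(1)))[1]
    stop(sprintf("non-numeric genotype code at cell %d", bad))
  }
  n <- nrow(raw); k <- ncol(raw)
  marker_ids <- colnames(raw)
  if (is.null(marker_ids) && k > 0) marker_ids <- paste0("mrk_", seq_len(k))
  individual_ids <- rownames(raw)
  if (is.null(individual_ids) && n > 0)
    individual_ids <- paste0("ind_", seq_len(n))

  bad <- which(!is.na(raw) & !is.finite(raw))
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(raw))
    stop(sprintf("non-finite genotype code at row %d, column %d (%s)",
                 ij[1], ij[2], marker_ids[ij[2]]))
  }

  n_imputed <- 0L
  if (anyNA(raw)) {
    n_imputed <- sum(is.na(raw))
    cm <- colMeans(raw, na.rm = TRUE)
    cm[is.nan(cm)] <- 0
    idx <- which(is.na(raw), arr.ind = TRUE)
    raw[idx] <- cm[idx[, 2]]
    message(sprintf("mean-imputed %d missing genotype code(s)", n_imputed))
  }

  if (is.null(means)) {
    means <- if (n > 0) colMeans(raw) else rep(0, k)
  } else {
    if (length(means) != k) stop("`means` must have one entry per marker")
  }
  values <- sweep(raw, 2, means, "-")
  dimnames(values) <- list(individual_ids, marker_ids)
  xtx <- colSums(values^2)
  names(xtx) <- marker_ids

  structure(list(values = values,
                 n_individuals = n,
                 n_markers = k,
                 marker_ids = marker_ids,
                 individual_ids = individual_ids,
                 xtx = xtx,
                 col_means = stats::setNames(as.numeric(means), marker_ids),
                 monomorphic = stats::setNames(xtx < 1e-12, marker_ids),
                 is_centered = TRUE,
                 n_imputed = n_imputed),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d markers (%d monomorphic)\n",
              x$n_individuals, x$n_markers, sum(x$monomorphic)))
  invisible(x)
}

#' Phenotype vector constructor
#'
#' A phenotype set is a named numeric vector (names = individual IDs).  This
#' helper validates finiteness and attaches IDs.
#'
#' @param y numeric trait values.
#' @param individual_ids character IDs, defaults to existing names or
#'   `ind_1..n`.
#' @return named numeric vector.
#' @export
phenotypes <- function(y, individual_ids = NULL) {
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop("phenotypes must all be finite")
  if (is.null(individual_ids)) individual_ids <- names(y)
  if (is.null(individual_ids)) individual_ids <- paste0("ind_", seq_along(y))
  stats::setNames(y, individual_ids)
}

check_dims <- function(G, y) {
  if (length(y) != G$n_individuals)
    stop(sprintf("phenotype length (%d) does not match genotype rows (%d)",
                 length(y), G$n_individuals))
  invisible(TRUE)
}
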