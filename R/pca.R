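#' Project samples by SVD of the row-centered gene-set Z matrix
#'
#' Implements sample projection of gene-set analysis output: the data are
#' arranged as an m-row (gene sets) by n-column (samples) matrix, the mean
#' of each row is subtracted, and the singular value decomposition of the
#' centered matrix is computed.  Sample coordinates are the right singular
#' vectors scaled by their singular values; the variance fraction of each
#' component is its squared singular value over the sum of all squared
#' singular values.  Singular-vector signs are fixed deterministically (the
#' largest-magnitude loading of each component is made positive) so repeated
#' runs give identical output.
#'
#' @param zmatrix Numeric gene-set-by-sample matrix (finite values).
#' @param components Number of components to report (default 2, capped at
#'   the matrix rank bound).
#' @param scale_rows Additionally scale each centered row to unit sample
#'   variance (zero-variance rows are dropped with a message).  Default
#'   `FALSE`: centering only.
#' @return Object of class `pheno_projection`: list with `sample_ids`,
#'   `coordinates` (samples x components), `loadings` (rows x components),
#'   `variance_fraction` (all components, nonincreasing), and
#'   `components_kept`.
#' @export
project_samples <- function(zmatrix, components = 2, scale_rows = FALSE) {
  X <- as.matrix(zmatrix)
  if (nrow(X) < 2L || ncol(X) < 2L) {
    stop("need at least 2 rows and 2 samples", call. = FALSE)
  }
  if (any(!is.finite(X))) stop("matrix must be finite", call. = FALSE)
  X <- X - rowMeans(X)
  if (scale_rows) {
    s <- apply(X, 1L, stats::sd)
    drop <- s == 0
    if (any(drop)) {
      ps_log("dropping %d zero-variance row(s) before scaling", sum(drop))
      X <- X[!drop, , drop = FALSE]
      s <- s[!drop]
      if (nrow(X) < 2L) stop("fewer than 2 rows after dropping", call. = FALSE)
    }
    X <- X / s
  }
  if (all(X == 0)) {
    stop("degenerate projection: centered matrix is identically zero",
         call. = FALSE)
  }
  sv <- svd(X)
  # deterministic signs: largest-|.| loading of each component positive
  for (j in seq_along(sv$d)) {
    i_star <- which.max(abs(sv$u[, j]))
    if (sv$u[i_star, j] < 0) {
      sv$u[, j] <- -sv$u[, j]
      sv$v[, j] <- -sv$v[, j]
    }
  }
  k <- max(1L, min(components, length(sv$d)))
  coords <- sv$v[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  dimnames(coords) <- list(colnames(zmatrix),
                           paste0("PC", seq_len(k)))
  loadings <- sv$u[, seq_len(k), drop = FALSE]
  rownames(loadings) <- rownames(X)
  colnames(loadings) <- paste0("PC", seq_len(k))
  structure(
    list(sample_ids = colnames(zmatrix), coordinates = coords,
         loadings = loadings,
         variance_fraction = sv$d^2 / sum(sv$d^2),
         components_kept = k),
    class = "pheno_projection"
  )
}

#' @export
print.pheno_projection <- function(x, ...) {
  vf <- x$variance_fraction[seq_len(x$components_kept)]
  cat(sprintf("<pheno_projection> %d samples, %d component(s)\n",
              length(x$sample_ids), x$components_kept))
  cat(sprintf("  variance explained: %s\n",
              paste(sprintf("PC%d %.1f%%", seq_along(vf), 100 * vf),
                    collapse = ", ")))
  invisible(x)
}
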