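#' Per-sample Z-score normalization of an expression matrix
#'
#' Each sample column is centered to mean 0 and scaled to sample standard
#' deviation 1 (n - 1 denominator).  Expression values are assumed to be on
#' a log scale.
#'
#' @param expr Numeric gene-by-sample matrix with unique row (gene) and
#'   column (sample) names.
#' @return Matrix of the same shape with columns standardized.
#' @export
zscore_normalize <- function(expr) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2L) stop("need at least 2 genes", call. = FALSE)
  sds <- apply(expr, 2L, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds)) || any(sds == 0)) {
    bad <- colnames(expr)[!is.finite(sds) | sds == 0]
    stop("zero-variance sample column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- scale(expr)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Z-ratio contrast between two sample groups
#'
#' For each gene, the difference of mean Z-normalized expression between
#' group A and group B, divided by the standard deviation of those per-gene
#' differences across all genes.  Genes with a missing value in either group
#' are dropped.
#'
#' @param exprZ Z-normalized gene-by-sample matrix (see
#'   [zscore_normalize()]).
#' @param group_a,group_b Disjoint, non-empty vectors of sample labels.
#' @return Named numeric vector of Z-ratios (one per retained gene), an
#'   object usable anywhere a contrast-score vector is expected.
#' @export
z_ratio <- function(exprZ, group_a, group_b) {
  exprZ <- as.matrix(exprZ)
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (length(intersect(group_a, group_b)) > 0L) {
    stop("groups must be disjoint", call. = FALSE)
  }
  missing_labels <- setdiff(c(group_a, group_b), colnames(exprZ))
  if (length(missing_labels)) {
    stop("unknown sample label(s): ", paste(missing_labels, collapse = ", "),
         call. = FALSE)
  }
  ma <- rowMeans(exprZ[, group_a, drop = FALSE])
  mb <- rowMeans(exprZ[, group_b, drop = FALSE])
  diff <- ma - mb
  keep <- is.finite(diff)
  if (sum(keep) < 2L) stop("fewer than 2 genes with complete values",
                           call. = FALSE)
  diff <- diff[keep]
  s <- stats::sd(diff)
  if (s == 0) {
    stop("degenerate contrast: per-gene differences have zero spread",
         call. = FALSE)
  }
  diff / s
}

#' PAGE Z statistic for one gene set
#'
#' The parametric gene-set statistic `Z = sqrt(n_i) * diff_i / sigma_a`,
#' where `diff_i` is the mean change score of the set's matched genes minus
#' the mean over all genes, `sigma_a` the sample standard deviation of all
#' change scores, and `n_i` the number of set genes present in the scores.
#' Matching is case-insensitive on canonical gene identifiers.
#'
#' A `"literal"` variant `(n_i - 1) * diff_i / sigma_a` is provided for
#' comparison with software that uses that scaling; it is not the default.
#'
#' @param scores Named numeric vector of per-gene change scores (log-ratios
#'   or Z-ratios); names are gene identifiers.
#' @param geneset A [gene_set()] (or character vector of gene identifiers).
#' @param statistic `"sqrt_n"` (default) or `"literal"`.
#' @return List with `z`, `diff_i`, `n_i`, `sigma_i`, `sigma_a`, `n_a`.
#' @export
page_z <- function(scores, geneset, statistic = c("sqrt_n", "literal")) {
  statistic <- match.arg(statistic)
  scores <- scores[is.finite(scores)]
  n_a <- length(scores)
  if (n_a < 2L) stop("need at least 2 finite change scores", call. = FALSE)
  genes <- if (inherits(geneset, "gene_set")) geneset$genes
           else as.character(geneset)
  hit <- canonical_id(names(scores)) %in% unique(canonical_id(genes))
  n_i <- sum(hit)
  if (n_i == 0L) stop("no gene-set genes matched the change scores",
                      call. = FALSE)
  sigma_a <- stats::sd(scores)
  if (sigma_a == 0) stop("degenerate contrast: zero score variance",
                         call. = FALSE)
  diff_i <- mean(scores[hit]) - mean(scores)
  mult <- if (statistic == "sqrt_n") sqrt(n_i) else (n_i - 1)
  list(z = mult * diff_i / sigma_a, diff_i = diff_i, n_i = n_i,
       sigma_i = if (n_i >= 2L) stats::sd(scores[hit]) else NA_real_,
       sigma_a = sigma_a, n_a = n_a)
}

#' Normal-theory p-value for a gene-set mean difference
#'
#' Two-sided tail probability `p = 2 * (1 - Phi(|diff_i| / sigma(diff_i)))`
#' with `sigma(diff_i) = sqrt(sigma_i^2 / n_i + sigma_a^2 / n_a)`, treating
#' the set and array means as independent normal averages.
#'
#' @param diff_i Set mean minus array mean (vectorized).
#' @param sigma_i Sample SD of the set's change scores.
#' @param n_i Number of matched set genes (>= 2).
#' @param sigma_a Sample SD of all change scores.
#' @param n_a Total number of change scores (>= 2).
#' @return p-values in `[0, 1]`.  A zero `sigma(diff_i)` returns 1 when
#'   `diff_i` is 0 and 0 otherwise (limit convention, logged).
#' @export
empirical_p <- function(diff_i, sigma_i, n_i, sigma_a, n_a) {
  if (any(n_i < 2L) || any(n_a < 2L)) {
    stop("n_i and n_a must be >= 2", call. = FALSE)
  }
  sdd <- sqrt(sigma_i^2 / n_i + sigma_a^2 / n_a)
  p <- ifelse(sdd == 0, ifelse(diff_i == 0, 1, 0),
              2 * (1 - stats::pnorm(abs(diff_i) / sdd)))
  if (any(sdd == 0)) {
    ps_log("zero sigma(diff) encountered; limit convention applied")
  }
  p
}

#' Parametric gene-set analysis of a contrast
#'
#' Scores every gene set in a collection against per-gene change scores with
#' the PAGE statistic, computes normal-theory p-values, and adjusts them by
#' Benjamini--Hochberg across the surviving sets.  The size filter counts
#' genes matched to the scores (not nominal set size): sets with fewer than
#' `min_genes` or more than `max_genes` matched genes are excluded.
#'
#' @param coll A [geneset_collection()].
#' @param scores Named numeric vector of per-gene change scores.
#' @param min_genes,max_genes Inclusive bounds on matched set size
#'   (defaults 3 and 500).
#' @param statistic Passed to [page_z()].
#' @param sort_by `"abs_z"` (default), `"z"`, or `"none"` (collection
#'   order).
#' @return Data frame with one row per surviving set: `set`, `n`, `diff`,
#'   `z`, `p`, `q`.
#' @export
run_gsa <- function(coll, scores, min_genes = 3, max_genes = 500,
                    statistic = c("sqrt_n", "literal"),
                    sort_by = c("abs_z", "z", "none")) {
  stopifnot(inherits(coll, "geneset_collection"))
  statistic <- match.arg(statistic)
  sort_by <- match.arg(sort_by)
  scores <- scores[is.finite(scores)]
  if (length(scores) < 2L) stop("need at least 2 finite change scores",
                                call. = FALSE)
  key <- canonical_id(names(scores))
  n_unmatched <- 0L
  rows <- lapply(coll$sets, function(s) {
    n_i <- sum(key %in% unique(canonical_id(s$genes)))
    if (n_i == 0L) {
      n_unmatched <<- n_unmatched + 1L
      return(NULL)
    }
    if (n_i < min_genes || n_i > max_genes) return(NULL)
    pz <- page_z(scores, s, statistic = statistic)
    data.frame(set = s$name, n = pz$n_i, diff = pz$diff_i, z = pz$z,
               p = if (pz$n_i >= 2L) {
                 empirical_p(pz$diff_i, pz$sigma_i, pz$n_i, pz$sigma_a,
                             pz$n_a)
               } else NA_real_,
               stringsAsFactors = FALSE)
  })
  if (n_unmatched > 0L) {
    ps_log("%d gene set(s) had no genes matching the scores", n_unmatched)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    stop("no gene sets survived matching and the size filter", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- stats::p.adjust(out$p, method = "BH")
  switch(sort_by,
         abs_z = out[order(-abs(out$z)), , drop = FALSE],
         z = out[order(-out$z), , drop = FALSE],
         none = out)
}

#' Gene-set Z matrix across multiple contrasts
#'
#' Runs [run_gsa()] on each labeled contrast and assembles the Z scores of
#' the sets surviving every contrast into a set-by-contrast matrix.
#'
#' @param coll A [geneset_collection()].
#' @param contrasts Named list of change-score vectors (one per contrast).
#' @param min_genes,max_genes Size filter passed to [run_gsa()].
#' @param statistic Passed to [run_gsa()].
#' @param q_threshold If non-`NULL`, keep only sets with `q` below the
#'   threshold in at least one contrast.
#' @return Numeric matrix (sets x contrasts) of Z scores.
#' @export
gsa_matrix <- function(coll, contrasts, min_genes = 3, max_genes = 500,
                       statistic = c("sqrt_n", "literal"),
                       q_threshold = NULL) {
  statistic <- match.arg(statistic)
  if (length(contrasts) < 1L) stop("need at least one contrast",
                                   call. = FALSE)
  if (is.null(names(contrasts)) || any(!nzchar(names(contrasts)))) {
    stop("contrasts must be a named list", call. = FALSE)
  }
  res <- lapply(contrasts, function(sc) {
    run_gsa(coll, sc, min_genes = min_genes, max_genes = max_genes,
            statistic = statistic, sort_by = "none")
  })
  common <- Reduce(intersect, lapply(res, `[[`, "set"))
  if (length(common) == 0L) stop("no gene set survives every contrast",
                                 call. = FALSE)
  Z <- vapply(res, function(r) r$z[match(common, r$set)],
              numeric(length(common)))
  Z <- matrix(Z, nrow = length(common),
              dimnames = list(common, names(contrasts)))
  if (!is.null(q_threshold)) {
    Q <- vapply(res, function(r) r$q[match(common, r$set)],
                numeric(length(common)))
    Q <- matrix(Q, nrow = length(common))
    Z <- Z[apply(Q < q_threshold, 1L, any), , drop = FALSE]
  }
  Z
}
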