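#' Overlap-coefficient distance between two gene sets
#'
#' The distance between gene sets is one minus the overlap coefficient: the
#' number of shared genes divided by the size of the smaller set,
#' `d = 1 - |A n B| / min(N(A), N(B))`, so identical sets (and any set
#' nested inside another) are at distance 0 and disjoint sets at distance 1.
#' Genes are compared case-insensitively.
#'
#' @param a,b [gene_set()] objects (or plain character vectors of gene
#'   identifiers).
#' @return A distance in `[0, 1]`.
#' @examples
#' pairwise_distance(gene_set("p1", c("g1", "g2")),
#'                   gene_set("p2", c("g2", "g3", "g4")))
#' @export
pairwise_distance <- function(a, b) {
  ga <- if (inherits(a, "gene_set")) a$genes else as.character(a)
  gb <- if (inherits(b, "gene_set")) b$genes else as.character(b)
  if (length(ga) == 0L || length(gb) == 0L) {
    stop("distance undefined for an empty gene set", call. = FALSE)
  }
  ka <- unique(canonical_id(ga))
  kb <- unique(canonical_id(gb))
  1 - length(intersect(ka, kb)) / min(length(ka), length(kb))
}

#' Pairwise distance matrix over a collection
#'
#' @param coll A [geneset_collection()] with at least two non-empty sets.
#' @return A symmetric numeric matrix with zero diagonal, rows and columns
#'   labeled by phenotype term in lexicographic order.
#' @export
distance_matrix <- function(coll) {
  stopifnot(inherits(coll, "geneset_collection"))
  labs <- sort(names(coll$sets))
  if (length(labs) < 2L) {
    stop("need at least two gene sets for a distance matrix", call. = FALSE)
  }
  keys <- lapply(coll$sets[labs], function(s) unique(canonical_id(s$genes)))
  n <- length(labs)
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    ki <- keys[[i]]
    for (j in seq.int(i + 1L, n)) {
      kj <- keys[[j]]
      d <- 1 - length(intersect(ki, kj)) / min(length(ki), length(kj))
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Configuration for least-squares tree fitting
#'
#' @param P Exponent of the `1/D^P` weight in the fit criterion: `2`
#'   (Fitch--Margoliash weighting, the default) or `0` (unweighted least
#'   squares).
#' @param n_replicates Replicate count `n_ij`: a single number (default 1)
#'   or a symmetric matrix matching the distance matrix.
#' @param allow_negative_branches If `FALSE` (default) negative branch-length
#'   solutions are clamped to zero and the remaining branches re-fit.
#' @param zero_distance_epsilon Substitute for zero off-diagonal observed
#'   distances in the weight denominator (identical or nested gene sets
#'   otherwise give an infinite weight).
#' @return An object of class `tree_fit_config`.
#' @export
tree_fit_config <- function(P = 2, n_replicates = 1,
                            allow_negative_branches = FALSE,
                            zero_distance_epsilon = 1e-6) {
  if (!P %in% c(0, 2)) stop("P must be 2 or 0", call. = FALSE)
  if (zero_distance_epsilon <= 0) {
    stop("zero_distance_epsilon must be positive", call. = FALSE)
  }
  if (is.matrix(n_replicates)) {
    if (any(n_replicates < 1)) stop("n_replicates must be >= 1", call. = FALSE)
  } else if (n_replicates < 1) {
    stop("n_replicates must be >= 1", call. = FALSE)
  }
  structure(list(P = P, n_replicates = n_replicates,
                 allow_negative_branches = allow_negative_branches,
                 zero_distance_epsilon = zero_distance_epsilon),
            class = "tree_fit_config")
}

# ---- internal tree plumbing -------------------------------------------------

# Unrooted star over three labels in ape's phylo encoding (root = Ntip + 1).
star3 <- function(labels) {
  stopifnot(length(labels) == 3L)
  structure(list(edge = cbind(c(4L, 4L, 4L), 1:3),
                 tip.label = as.character(labels), Nnode = 1L),
            class = "phylo")
}

# Insert a new leaf into edge `edge_idx` by splitting it with a new internal
# node.  Keeps ape's numbering convention (tips first, root = Ntip + 1).
attach_leaf <- function(tree, edge_idx, label) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  e <- tree$edge
  # shift internal node ids up by one to make room for the new tip id n + 1
  e[e > n] <- e[e > n] + 1L
  newtip <- n + 1L
  newnode <- n + m + 2L
  u <- e[edge_idx, 1L]; v <- e[edge_idx, 2L]
  e[edge_idx, ] <- c(u, newnode)
  e <- rbind(e, c(newnode, v), c(newnode, newtip))
  structure(list(edge = e, tip.label = c(tree$tip.label, label),
                 Nnode = m + 1L),
            class = "phylo")
}

# Logical matrix (edges x tips): which tips lie below each edge's child.
edge_tip_matrix <- function(tree) {
  n <- length(tree$tip.label)
  e <- tree$edge
  nE <- nrow(e)
  children <- split(seq_len(nE), e[, 1L])
  S <- matrix(FALSE, nE, n)
  tips_under <- function(node) {
    if (node <= n) {
      out <- logical(n); out[node] <- TRUE
      return(out)
    }
    rows <- children[[as.character(node)]]
    out <- logical(n)
    for (r in rows) {
      s <- tips_under(e[r, 2L])
      S[r, ] <<- s
      out <- out | s
    }
    out
  }
  root <- setdiff(unique(e[, 1L]), e[, 2L])
  tips_under(root[[1L]])
  S
}

# Pair-by-edge path indicator matrix; rows follow pairs (i < j) over `labs`.
path_design <- function(tree, labs) {
  S <- edge_tip_matrix(tree)
  tip <- match(labs, tree$tip.label)
  if (anyNA(tip)) stop("tree leaves do not match distance labels",
                       call. = FALSE)
  n <- length(labs)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pr <- pr[order(pr[, 1L], pr[, 2L]), , drop = FALSE]
  A <- matrix(FALSE, nrow(pr), nrow(S))
  for (k in seq_len(nrow(S))) {
    A[, k] <- S[k, tip[pr[, 1L]]] != S[k, tip[pr[, 2L]]]
  }
  storage.mode(A) <- "double"
  list(A = A, pairs = pr)
}

# Criterion weights n_ij / D_ij^P over pairs i < j, with zero-distance
# substitution.
criterion_weights <- function(Dvec, config, warn = TRUE) {
  nrep <- config$n_replicates
  n_ij <- if (is.matrix(nrep)) stop("matrix n_replicates handled by caller")
          else rep(nrep, length(Dvec))
  if (config$P == 0) return(n_ij)
  dz <- Dvec
  if (any(dz == 0)) {
    if (warn) {
      warning(sprintf(
        "%d zero off-diagonal distance(s) replaced by epsilon %g in weights",
        sum(dz == 0), config$zero_distance_epsilon), call. = FALSE)
    }
    dz[dz == 0] <- config$zero_distance_epsilon
  }
  n_ij / dz^config$P
}

pair_vectors <- function(D, config, warn = TRUE) {
  labs <- rownames(D)
  n <- length(labs)
  ut <- upper.tri(D)
  # row-major over (i, j), i < j: transpose trick keeps (1,2), (1,3), ...
  pr <- which(ut, arr.ind = TRUE)
  ord <- order(pr[, 1L], pr[, 2L])
  Dvec <- D[ut][ord]
  pr <- pr[ord, , drop = FALSE]
  nrep <- config$n_replicates
  if (is.matrix(nrep)) {
    nvec <- nrep[cbind(pr[, 1L], pr[, 2L])]
    cfg1 <- config; cfg1$n_replicates <- 1
    w <- nvec * criterion_weights(Dvec, cfg1, warn = warn)
  } else {
    w <- criterion_weights(Dvec, config, warn = warn)
  }
  list(labs = labs, Dvec = Dvec, w = w, pairs = pr)
}

# Weighted least squares on the path-incidence design with optional
# nonnegativity by clamp-and-refit.
wls_branch_lengths <- function(A, Dvec, w, allow_negative) {
  nE <- ncol(A)
  free <- rep(TRUE, nE)
  sw <- sqrt(w)
  b_free <- numeric(0)
  repeat {
    if (!any(free)) break
    qrx <- qr(sw * A[, free, drop = FALSE])
    b_free <- qr.coef(qrx, sw * Dvec)
    b_free[is.na(b_free)] <- 0
    if (allow_negative || all(b_free >= -1e-12)) break
    idx <- which(free)
    free[idx[b_free < -1e-12]] <- FALSE
  }
  b <- numeric(nE)
  if (any(free)) b[free] <- if (allow_negative) b_free else pmax(b_free, 0)
  b
}

new_pheno_tree <- function(tree, fitted, sos, config) {
  structure(list(tree = tree, fitted = fitted, sum_of_squares = sos,
                 config = config),
            class = "pheno_tree")
}

#' @export
print.pheno_tree <- function(x, ...) {
  cat(sprintf(
    "<pheno_tree> %d leaves, criterion (P = %g) = %.6g\n",
    length(x$tree$tip.label), x$config$P, x$sum_of_squares))
  invisible(x)
}

# ---- exported fitting operations -------------------------------------------

#' Weighted least-squares criterion of a tree against observed distances
#'
#' Evaluates `sum over pairs i < j of n_ij (D_ij - d_ij)^2 / D_ij^P`, where
#' `D` is the observed distance and `d` the expected distance, the sum of
#' branch lengths on the tree path between leaves `i` and `j`.  Each
#' unordered pair is counted once.  With `P = 2` this is the
#' Fitch--Margoliash criterion; `P = 0` gives the unweighted residual sum of
#' squares.
#'
#' @param D Symmetric distance matrix with labeled rows and columns.
#' @param tree A [fit_branch_lengths()] result (`pheno_tree`) or an `ape`
#'   `phylo` object with branch lengths, with leaves matching `D`'s labels.
#' @param config A [tree_fit_config()].
#' @return The criterion value (>= 0).
#' @export
sum_of_squares <- function(D, tree, config = tree_fit_config()) {
  phy <- if (inherits(tree, "pheno_tree")) tree$tree else tree
  if (is.null(phy$edge.length)) {
    stop("tree must carry branch lengths", call. = FALSE)
  }
  if (!setequal(rownames(D), phy$tip.label)) {
    stop("tree leaves do not match distance labels", call. = FALSE)
  }
  pv <- pair_vectors(D, config)
  des <- path_design(phy, pv$labs)
  dvec <- as.vector(des$A %*% phy$edge.length)
  sum(pv$w * (pv$Dvec - dvec)^2)
}

#' Fit branch lengths on a fixed topology by weighted least squares
#'
#' Branch lengths minimizing the [sum_of_squares()] criterion for the given
#' topology, solved as a weighted linear least-squares problem on the
#' path-incidence structure.  Negative solutions are clamped to zero and the
#' remaining branches re-fit unless the configuration allows negative
#' branches.
#'
#' @param topology An `ape` `phylo` object (branch lengths ignored) whose
#'   leaves match `D`'s labels; at least 3 leaves.
#' @param D Symmetric observed distance matrix.
#' @param config A [tree_fit_config()].
#' @return An object of class `pheno_tree`: list with elements `tree` (the
#'   `phylo` with fitted `edge.length`), `fitted` (expected-distance
#'   matrix), `sum_of_squares`, and `config`.
#' @export
fit_branch_lengths <- function(topology, D, config = tree_fit_config()) {
  if (length(topology$tip.label) < 3L) {
    stop("need at least 3 leaves", call. = FALSE)
  }
  if (anyDuplicated(topology$tip.label)) {
    stop("fit error: duplicate leaf labels", call. = FALSE)
  }
  if (!setequal(rownames(D), topology$tip.label)) {
    stop("tree leaves do not match distance labels", call. = FALSE)
  }
  pv <- pair_vectors(D, config)
  des <- path_design(topology, pv$labs)
  b <- wls_branch_lengths(des$A, pv$Dvec, pv$w,
                          config$allow_negative_branches)
  topology$edge.length <- b
  dvec <- as.vector(des$A %*% b)
  sos <- sum(pv$w * (pv$Dvec - dvec)^2)
  n <- length(pv$labs)
  fitted <- matrix(0, n, n, dimnames = list(pv$labs, pv$labs))
  fitted[cbind(des$pairs[, 1L], des$pairs[, 2L])] <- dvec
  fitted[cbind(des$pairs[, 2L], des$pairs[, 1L])] <- dvec
  new_pheno_tree(topology, fitted, sos, config)
}

# All nearest-neighbor-interchange rearrangements of a binary unrooted tree
# in rooted-at-trifurcation encoding.
nni_neighbors <- function(tree) {
  n <- length(tree$tip.label)
  e <- tree$edge
  out <- list()
  internal_child <- which(e[, 2L] > n)
  for (r in internal_child) {
    u <- e[r, 1L]; v <- e[r, 2L]
    b_row <- which(e[, 1L] == u & e[, 2L] != v)[1L]  # another subtree at u
    if (is.na(b_row)) next
    c_rows <- which(e[, 1L] == v)                    # the two subtrees at v
    for (cr in c_rows) {
      e2 <- e
      tmp <- e2[b_row, 2L]
      e2[b_row, 2L] <- e2[cr, 2L]
      e2[cr, 2L] <- tmp
      t2 <- tree
      t2$edge <- e2
      t2$edge.length <- NULL
      out[[length(out) + 1L]] <- t2
    }
  }
  out
}

# Deterministic canonical Newick string of an (unrooted) topology; used for
# tie-breaking and split-free topology comparison.
canonical_newick <- function(tree) {
  n <- length(tree$tip.label)
  e <- tree$edge
  nodes <- max(e)
  adj <- vector("list", nodes)
  for (r in seq_len(nrow(e))) {
    adj[[e[r, 1L]]] <- c(adj[[e[r, 1L]]], e[r, 2L])
    adj[[e[r, 2L]]] <- c(adj[[e[r, 2L]]], e[r, 1L])
  }
  t0 <- which(tree$tip.label == min(tree$tip.label))[[1L]]
  recurse <- function(node, parent) {
    if (node <= n) return(tree$tip.label[[node]])
    kids <- setdiff(adj[[node]], parent)
    subs <- sort(vapply(kids, recurse, character(1), parent = node))
    paste0("(", paste(subs, collapse = ","), ")")
  }
  paste0("(", tree$tip.label[[t0]], ",", recurse(adj[[t0]][[1L]], t0), ");")
}

#' Fit an unrooted least-squares tree to a distance matrix
#'
#' Builds the genome-wide phenotype model: an unrooted leaf-labeled tree
#' whose path lengths approximate the observed gene-set distances under the
#' [sum_of_squares()] criterion.  The topology is found by stepwise leaf
#' addition in deterministic lexicographic label order (each placement
#' scored by a full branch-length refit) followed by
#' nearest-neighbor-interchange hill climbing; ties are broken by the
#' lexicographically smallest canonical Newick string.  A neighbor-joining
#' starting topology (via \pkg{ape}) is available as a faster alternative
#' for large collections.
#'
#' @param D Symmetric distance matrix with at least 3 labeled rows.
#' @param config A [tree_fit_config()].
#' @param start `"stepwise"` (default) or `"nj"`.
#' @param refine Run NNI refinement (default `TRUE`).
#' @return A `pheno_tree` (see [fit_branch_lengths()]).
#' @export
fit_tree <- function(D, config = tree_fit_config(),
                     start = c("stepwise", "nj"), refine = TRUE) {
  start <- match.arg(start)
  labs <- sort(rownames(D))
  if (length(labs) < 3L) stop("need at least 3 labels", call. = FALSE)
  D <- D[labs, labs]
  # quench repeated zero-distance warnings during the search
  fit_quiet <- function(topo, Dsub) {
    suppressWarnings(fit_branch_lengths(topo, Dsub, config))
  }
  if (start == "stepwise") {
    cur <- fit_quiet(star3(labs[1:3]), D[labs[1:3], labs[1:3]])
    if (length(labs) > 3L) {
      for (k in seq.int(4L, length(labs))) {
        Dsub <- D[labs[1:k], labs[1:k]]
        best <- NULL; best_nwk <- NULL
        for (ei in seq_len(nrow(cur$tree$edge))) {
          cand <- fit_quiet(attach_leaf(cur$tree, ei, labs[[k]]), Dsub)
          nwk <- canonical_newick(cand$tree)
          if (is.null(best) || cand$sum_of_squares < best$sum_of_squares -
                1e-12 ||
              (abs(cand$sum_of_squares - best$sum_of_squares) <= 1e-12 &&
                 nwk < best_nwk)) {
            best <- cand; best_nwk <- nwk
          }
        }
        cur <- best
      }
    }
  } else {
    phy <- ape::unroot(ape::nj(stats::as.dist(D)))
    phy$edge.length <- NULL
    cur <- fit_quiet(phy, D)
  }
  if (refine && length(labs) > 3L) {
    for (iter in seq_len(200L)) {
      improved <- FALSE
      for (cand_topo in nni_neighbors(cur$tree)) {
        cand <- fit_quiet(cand_topo, D)
        if (cand$sum_of_squares < cur$sum_of_squares - 1e-12) {
          cur <- cand
          improved <- TRUE
        }
      }
      if (!improved) break
    }
  }
  # surface the zero-distance note once, outside the search loop
  if (config$P > 0 && any(D[upper.tri(D)] == 0)) {
    warning(sprintf(
      "%d zero off-diagonal distance(s) replaced by epsilon %g in weights",
      sum(D[upper.tri(D)] == 0), config$zero_distance_epsilon),
      call. = FALSE)
  }
  cur
}

#' Leaf bipartitions induced by a tree's internal edges
#'
#' @param tree A `pheno_tree` or `phylo`.
#' @return List of character vectors: for each internal edge, the sorted
#'   leaf labels on the child side.
#' @export
tree_bipartitions <- function(tree) {
  phy <- if (inherits(tree, "pheno_tree")) tree$tree else tree
  n <- length(phy$tip.label)
  S <- edge_tip_matrix(phy)
  internal <- which(phy$edge[, 2L] > n)
  lapply(internal, function(r) sort(phy$tip.label[S[r, ]]))
}

#' Does a tree contain a branch separating a group from the rest?
#'
#' @param tree A `pheno_tree` or `phylo`.
#' @param group Character vector of leaf labels.
#' @return `TRUE` if some internal edge bipartitions the leaves into exactly
#'   `group` versus the rest.
#' @export
has_bipartition <- function(tree, group) {
  phy <- if (inherits(tree, "pheno_tree")) tree$tree else tree
  group <- sort(as.character(group))
  other <- sort(setdiff(phy$tip.label, group))
  any(vapply(tree_bipartitions(phy), function(s) {
    identical(s, group) || identical(s, other)
  }, logical(1)))
}

# ---- serialization ---------------------------------------------------------

#' Write a fitted tree as Newick
#'
#' @param tree A `pheno_tree` or `phylo` with branch lengths.
#' @param file Output path.
#' @return Invisibly, the output path.
#' @export
write_newick <- function(tree, file) {
  phy <- if (inherits(tree, "pheno_tree")) tree$tree else tree
  if (any(grepl("\\s", phy$tip.label))) {
    phy$tip.label <- paste0("'", phy$tip.label, "'")
  }
  ape::write.tree(phy, file = file, digits = 15)
  invisible(file)
}

#' Read a Newick tree
#'
#' @param file Path to a Newick file.
#' @return An `ape` `phylo` object.
#' @export
read_newick <- function(file) {
  ape::read.tree(file)
}

#' Write / read a labeled distance matrix as TSV
#'
#' @param D Symmetric labeled matrix.
#' @param file Path.
#' @param header Optional comment lines (written first; skipped on read).
#' @return `write_distance_tsv` invisibly returns the path;
#'   `read_distance_tsv` returns the matrix.
#' @export
write_distance_tsv <- function(D, file, header = NULL) {
  con <- base::file(file, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  writeLines(paste(c("", colnames(D)), collapse = "\t"), con)
  utils::write.table(format(D, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(file) {
  m <- utils::read.delim(file, row.names = 1, check.names = FALSE,
                         comment.char = "#")
  as.matrix(m)
}
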