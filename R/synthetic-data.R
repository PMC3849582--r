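#' Specification for a planted-structure gene-set collection
#'
#' Describes a synthetic gene--phenotype association table in which
#' phenotypes are partitioned into blocks that share genes preferentially
#' within a block.  The gene pool is split into disjoint per-block shared
#' pools plus a background pool; each gene of a set is drawn from the set's
#' own block pool with probability `within_block_sharing`, from the other
#' blocks' pools with probability `between_block_sharing`, and from the
#' background otherwise.
#'
#' @param n_phenotypes Number of phenotype terms (partitioned evenly into
#'   blocks).
#' @param gene_pool_size Total number of distinct gene identifiers.
#' @param set_size_range Length-2 integer range of per-set sizes (inclusive).
#' @param n_blocks Number of blocks.
#' @param within_block_sharing Probability a gene is drawn from the block's
#'   shared pool.
#' @param between_block_sharing Probability a gene is drawn from another
#'   block's shared pool; must not exceed `within_block_sharing`, and the
#'   two must sum to at most 1.
#' @param seed Integer seed; all randomness flows from it.
#' @return Object of class `planted_collection_spec`.
#' @export
planted_collection_spec <- function(n_phenotypes = 20, gene_pool_size = 150,
                                    set_size_range = c(8, 15), n_blocks = 2,
                                    within_block_sharing = 0.8,
                                    between_block_sharing = 0.05, seed = 1) {
  stopifnot(n_phenotypes >= 1, gene_pool_size >= 1, n_blocks >= 1,
            length(set_size_range) == 2, set_size_range[1] >= 1,
            set_size_range[1] <= set_size_range[2])
  if (between_block_sharing < 0 ||
      between_block_sharing > within_block_sharing ||
      within_block_sharing > 1) {
    stop("need 0 <= between_block_sharing <= within_block_sharing <= 1",
         call. = FALSE)
  }
  if (within_block_sharing + between_block_sharing > 1) {
    stop("within_block_sharing + between_block_sharing must be <= 1",
         call. = FALSE)
  }
  structure(list(n_phenotypes = n_phenotypes,
                 gene_pool_size = gene_pool_size,
                 set_size_range = as.integer(set_size_range),
                 n_blocks = n_blocks,
                 within_block_sharing = within_block_sharing,
                 between_block_sharing = between_block_sharing,
                 seed = as.integer(seed)),
            class = "planted_collection_spec")
}

# Worm-locus-tag-styled synthetic identifiers ("SYN3.7"), exercising the
# same label-normalization path as real data.
synthetic_gene_ids <- function(n) {
  sprintf("SYN%d.%d", ((seq_len(n) - 1L) %/% 9L) + 1L,
          ((seq_len(n) - 1L) %% 9L) + 1L)
}

#' Simulate a gene--phenotype association table with planted blocks
#'
#' Generates a worm-dialect association table (columns: gene, phenotype)
#' whose phenotype blocks share genes according to the spec, together with a
#' ledger recording every generated pair, the block assignment of every
#' phenotype, and the gene pools.  Deterministic given the spec's seed.
#'
#' @param spec A [planted_collection_spec()].
#' @param path If non-`NULL`, the table is written there as TSV and the
#'   ledger as JSON at `paste0(path, ".ledger.json")`.
#' @return List with `pairs` (data frame: `gene`, `phenotype`), `ledger`
#'   (list: `blocks`, `membership`, `pools`, `spec`), and `path`.
#' @export
simulate_association_table <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "planted_collection_spec"))
  pool <- synthetic_gene_ids(spec$gene_pool_size)
  nb <- spec$n_blocks
  # half the pool split across block-shared pools, the rest is background
  block_pool_size <- max(1L, spec$gene_pool_size %/% (2L * nb))
  if (max(spec$set_size_range) > block_pool_size) {
    stop("infeasible spec: set size exceeds the block shared-pool size",
         call. = FALSE)
  }
  pools <- lapply(seq_len(nb), function(b) {
    pool[seq.int((b - 1L) * block_pool_size + 1L, b * block_pool_size)]
  })
  background <- pool[seq.int(nb * block_pool_size + 1L, spec$gene_pool_size)]
  p_bg <- 1 - spec$within_block_sharing - spec$between_block_sharing
  if (p_bg > 0 && max(spec$set_size_range) > length(background)) {
    stop("infeasible spec: set size exceeds the background pool",
         call. = FALSE)
  }
  blocks <- sort(rep_len(seq_len(nb), spec$n_phenotypes))
  terms <- sprintf("block%d_phen%03d", blocks, seq_len(spec$n_phenotypes))
  membership <- with_seed(spec$seed, {
    lapply(seq_len(spec$n_phenotypes), function(k) {
      s <- if (spec$set_size_range[1] == spec$set_size_range[2]) {
        spec$set_size_range[1]
      } else {
        sample(seq.int(spec$set_size_range[1], spec$set_size_range[2]), 1L)
      }
      u <- stats::runif(s)
      n_other <- sum(u < spec$between_block_sharing)
      n_own <- sum(u < spec$between_block_sharing +
                     spec$within_block_sharing) - n_other
      n_bg <- s - n_own - n_other
      other_pool <- unlist(pools[-blocks[k]], use.names = FALSE)
      genes <- c(
        if (n_own > 0) sample(pools[[blocks[k]]], n_own),
        if (n_other > 0 && length(other_pool)) {
          sample(other_pool, min(n_other, length(other_pool)))
        },
        if (n_bg > 0) sample(background, n_bg)
      )
      unique(genes)
    })
  })
  names(membership) <- terms
  pairs <- data.frame(
    gene = unlist(membership, use.names = FALSE),
    phenotype = rep(terms, lengths(membership)),
    stringsAsFactors = FALSE
  )
  ledger <- list(blocks = stats::setNames(blocks, terms),
                 membership = membership,
                 pools = c(pools, list(background = background)),
                 spec = unclass(spec))
  if (!is.null(path)) {
    writeLines(paste(pairs$gene, pairs$phenotype, sep = "\t"), path)
    jsonlite::write_json(
      list(blocks = as.list(ledger$blocks), membership = membership,
           spec = unclass(spec)),
      paste0(path, ".ledger.json"), auto_unbox = TRUE, pretty = TRUE
    )
  }
  list(pairs = pairs, ledger = ledger, path = path)
}

#' Specification for a planted-shift expression matrix
#'
#' @param n_genes Total genes in the simulated platform (at least the number
#'   of distinct genes in the accompanying collection).
#' @param groups Named integer vector of per-group sample counts (each
#'   >= 2).
#' @param target_shifts Named list: for each group name, a named numeric
#'   vector mapping gene-set names (from the accompanying collection) to the
#'   additive shift applied to that set's genes in that group's samples.
#' @param noise_sd Baseline noise standard deviation (> 0).
#' @param seed Integer seed.
#' @return Object of class `planted_expression_spec`.
#' @export
planted_expression_spec <- function(n_genes = 2000,
                                    groups = c(A = 4, B = 4),
                                    target_shifts = list(), noise_sd = 1,
                                    seed = 1) {
  stopifnot(n_genes >= 2, length(groups) >= 1, noise_sd > 0)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be named", call. = FALSE)
  }
  if (any(groups < 2)) stop("each group needs at least 2 samples",
                            call. = FALSE)
  if (length(target_shifts) &&
      !all(names(target_shifts) %in% names(groups))) {
    stop("target_shifts names must be group names", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes), groups = groups,
                 target_shifts = target_shifts, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "planted_expression_spec")
}

#' Simulate an expression matrix with planted gene-set shifts
#'
#' Baseline values are iid normal with mean 0 and the spec's noise SD.  For
#' every (group, target set) entry of the spec, the set's genes get the
#' stated additive shift in that group's sample columns.  The ledger records
#' the per-gene true shift in every group.
#'
#' @param spec A [planted_expression_spec()].
#' @param coll The [geneset_collection()] the target sets are drawn from.
#' @return List with `expr` (gene-by-sample matrix; sample names
#'   `"<group>_s<i>"`), `groups` (named list of sample labels per group),
#'   and `ledger` (list with per-group named shift vectors and the spec).
#' @export
simulate_expression <- function(spec, coll) {
  stopifnot(inherits(spec, "planted_expression_spec"),
            inherits(coll, "geneset_collection"))
  target_names <- unique(unlist(lapply(spec$target_shifts, names)))
  unknown <- setdiff(target_names, names(coll$sets))
  if (length(unknown)) {
    stop("unknown target set(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  coll_genes <- unique(unlist(lapply(coll$sets, `[[`, "genes"),
                              use.names = FALSE))
  coll_genes <- coll_genes[!duplicated(canonical_id(coll_genes))]
  if (length(coll_genes) > spec$n_genes) {
    stop("n_genes smaller than the collection's gene universe",
         call. = FALSE)
  }
  filler <- sprintf("BGX%d.%d",
                    ((seq_len(spec$n_genes - length(coll_genes)) - 1L) %/%
                       9L) + 1L,
                    ((seq_len(spec$n_genes - length(coll_genes)) - 1L) %%
                       9L) + 1L)
  genes <- c(coll_genes, filler)
  samples <- unlist(lapply(names(spec$groups), function(g) {
    sprintf("%s_s%d", g, seq_len(spec$groups[[g]]))
  }), use.names = FALSE)
  group_of <- rep(names(spec$groups), spec$groups)
  expr <- with_seed(spec$seed, {
    matrix(stats::rnorm(length(genes) * length(samples), 0, spec$noise_sd),
           nrow = length(genes), dimnames = list(genes, samples))
  })
  shifts <- lapply(names(spec$groups), function(g) {
    sh <- stats::setNames(numeric(length(genes)), genes)
    tg <- spec$target_shifts[[g]]
    if (!is.null(tg)) {
      for (set_name in names(tg)) {
        idx <- canonical_id(genes) %in%
          canonical_id(coll$sets[[set_name]]$genes)
        sh[idx] <- sh[idx] + tg[[set_name]]
      }
    }
    sh
  })
  names(shifts) <- names(spec$groups)
  for (g in names(spec$groups)) {
    cols <- samples[group_of == g]
    expr[, cols] <- expr[, cols] + shifts[[g]]
  }
  list(expr = expr,
       groups = split(samples, group_of)[names(spec$groups)],
       ledger = list(shifts = shifts, spec = unclass(spec)))
}
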