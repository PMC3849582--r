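#' Split a printed gene label into identifier and optional symbol
#'
#' Curated phenotype tables print worm genes as `"locus_tag(symbol)"` (for
#' example `"AC7.1(tag-49)"`) and fall back to the bare locus tag where no
#' symbol exists.  This helper splits such labels into the canonical gene
#' identifier and the optional symbol.  Identifier comparison everywhere in
#' the package is case-insensitive (`"B0035.8(HIS-48)"` and
#' `"B0035.8(his-48)"` denote the same gene); the casing of the first
#' occurrence is what gets stored.
#'
#' @param raw Character vector of raw gene labels.
#' @return A data frame with columns `gene_id` (never empty, internal
#'   whitespace removed) and `gene_symbol` (`NA` where the label carries no
#'   parenthesized symbol).
#' @examples
#' normalize_gene_label(c("AC7.1(tag-49)", "arm"))
#' @export
normalize_gene_label <- function(raw) {
  if (length(raw) == 0L) {
    stop("invalid gene label: empty input", call. = FALSE)
  }
  raw <- as.character(raw)
  trimmed <- trimws(raw)
  if (any(is.na(trimmed)) || any(!nzchar(trimmed))) {
    stop("invalid gene label: empty or all-whitespace entry", call. = FALSE)
  }
  has_sym <- grepl("^(.*)\\((.+)\\)\\s*$", trimmed)
  id <- ifelse(has_sym, sub("^(.*)\\((.+)\\)\\s*$", "\\1", trimmed), trimmed)
  sym <- ifelse(has_sym, sub("^(.*)\\((.+)\\)\\s*$", "\\2", trimmed),
                NA_character_)
  # printed tables occasionally break an identifier across a space
  id <- gsub("\\s+", "", id)
  sym <- ifelse(is.na(sym), sym, trimws(sym))
  if (any(!nzchar(id))) {
    stop("invalid gene label: no identifier before '(' in: ",
         paste(utils::head(trimmed[!nzchar(id)], 3), collapse = ", "),
         call. = FALSE)
  }
  data.frame(gene_id = id, gene_symbol = sym, stringsAsFactors = FALSE)
}

#' Construct a phenotype gene set
#'
#' A gene set is a phenotype term together with the unique gene identifiers
#' annotated to it.  Duplicate identifiers (compared case-insensitively) are
#' collapsed to the first-seen casing with a warning.
#'
#' @param name Phenotype term (whitespace is normalized to underscores).
#' @param genes Character vector of gene identifiers.
#' @param symbols Optional character vector of gene symbols aligned with
#'   `genes` (`NA` where absent).
#' @return An object of class `gene_set` with elements `name`, `genes` and
#'   `symbols` (named by canonical identifier).
#' @export
gene_set <- function(name, genes, symbols = NULL) {
  name <- normalize_term(name)
  if (!nzchar(name)) stop("gene set name must be non-empty", call. = FALSE)
  genes <- as.character(genes)
  if (length(genes) == 0L) {
    stop("gene set '", name, "' must contain at least one gene", call. = FALSE)
  }
  if (is.null(symbols)) symbols <- rep(NA_character_, length(genes))
  key <- canonical_id(genes)
  if (anyDuplicated(key)) {
    warning("gene set '", name, "': duplicate gene identifiers collapsed",
            call. = FALSE)
    keep <- !duplicated(key)
    # retain the first non-missing symbol per canonical gene
    sym_by_key <- tapply(symbols, key, function(s) {
      s <- s[!is.na(s)]
      if (length(s)) s[[1L]] else NA_character_
    })
    genes <- genes[keep]
    key <- key[keep]
    symbols <- unname(sym_by_key[key])
  }
  structure(
    list(name = name, genes = genes,
         symbols = stats::setNames(symbols, key)),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$genes)))
  cat("  ", paste(utils::head(x$genes, 8), collapse = ", "),
      if (length(x$genes) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Construct a gene-set collection
#'
#' @param sets List of [gene_set()] objects.
#' @param label Collection label (e.g. a file-style name).
#' @param provenance Free-text record of source files and dates.
#' @return An object of class `geneset_collection`: a non-redundant named map
#'   from phenotype term to gene set.
#' @export
geneset_collection <- function(sets, label = "collection", provenance = "") {
  stopifnot(is.list(sets))
  if (!all(vapply(sets, inherits, logical(1), "gene_set"))) {
    stop("all elements must be gene_set objects", call. = FALSE)
  }
  nm <- vapply(sets, function(s) s$name, character(1))
  if (anyDuplicated(nm)) {
    stop("non-redundancy violated: duplicate phenotype terms: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  structure(
    list(label = label, sets = stats::setNames(sets, nm),
         provenance = provenance),
    class = "geneset_collection"
  )
}

#' @export
print.geneset_collection <- function(x, ...) {
  sz <- collection_sizes(x)
  cat(sprintf("<geneset_collection> %s: %d gene sets, %d unique genes\n",
              x$label, length(x$sets), length(collection_genes(x))))
  if (length(sz)) {
    cat(sprintf("  set sizes: min %d, median %g, max %d\n",
                min(sz), stats::median(sz), max(sz)))
  }
  invisible(x)
}

#' @export
length.geneset_collection <- function(x) length(x$sets)

#' Per-set sizes of a collection
#'
#' @param coll A [geneset_collection()].
#' @return Named integer vector of set sizes N(C_i).
#' @export
collection_sizes <- function(coll) {
  stopifnot(inherits(coll, "geneset_collection"))
  vapply(coll$sets, function(s) length(s$genes), integer(1))
}

#' Unique genes of a collection (canonical, case-insensitive)
#'
#' @param coll A [geneset_collection()].
#' @return Character vector of unique canonical gene identifiers.
#' @export
collection_genes <- function(coll) {
  stopifnot(inherits(coll, "geneset_collection"))
  unique(canonical_id(unlist(lapply(coll$sets, `[[`, "genes"),
                             use.names = FALSE)))
}

#' Summary table of a collection
#'
#' @param coll A [geneset_collection()].
#' @return Data frame with columns `term` and `size`.
#' @export
collection_summary <- function(coll) {
  sz <- collection_sizes(coll)
  data.frame(term = names(sz), size = unname(sz), stringsAsFactors = FALSE)
}

#' Parse a gene--phenotype association table
#'
#' Reads a delimited table of curated gene--phenotype records into a tidy
#' pair list.  Two dialects are supported: `"worm_pairs"` (WormBase-style
#' RNAi/variant exports: first column gene, second column phenotype term) and
#' `"fly_alleles"` (FlyBase-style allele phenotype rows: first column allele
#' symbol, second column the phenotypic descriptor; alleles are mapped to
#' genes by `allele_to_gene`).  Malformed rows (fewer than two non-empty
#' fields) are skipped, counted, and reported with a single warning.
#'
#' @param file Path to a delimited text file (lines starting `#` ignored).
#' @param dialect `"worm_pairs"` or `"fly_alleles"`.
#' @param sep Field separator; `NULL` auto-detects tab versus comma from the
#'   first data line.
#' @param text Optional character vector of lines, used instead of `file`.
#' @param allele_to_gene Function mapping an allele symbol to its gene, used
#'   by the fly dialect only.  The default strips a bracketed allele
#'   designation (`"arm[4]"` to `"arm"`); FlyBase does not publish the
#'   mapping used for its descriptor lists, so callers can supply their own.
#' @return Data frame with columns `phenotype_term`, `gene_id`,
#'   `gene_symbol`, in file order, with attribute `n_skipped`.
#' @export
parse_association_table <- function(file = NULL,
                                    dialect = c("worm_pairs", "fly_alleles"),
                                    sep = NULL, text = NULL,
                                    allele_to_gene = NULL) {
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) stop("unknown dialect", call. = FALSE))
  if (is.null(text)) {
    if (is.null(file) || !file.exists(file)) {
      stop("cannot read association table: ", file %||% "<missing path>",
           call. = FALSE)
    }
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- strsplit(paste(as.character(text), collapse = "\n"),
                      "\n", fixed = TRUE)[[1]]
  }
  lines <- lines[!grepl("^\\s*#", lines)]
  data_lines <- lines[nzchar(trimws(lines))]
  n_blank <- length(lines) - length(data_lines)
  if (is.null(sep)) {
    sep <- if (length(data_lines) && grepl("\t", data_lines[[1]])) "\t" else ","
  }
  fields <- strsplit(data_lines, sep, fixed = TRUE)
  ok <- vapply(fields, function(f) {
    length(f) >= 2L && nzchar(trimws(f[[1]])) && nzchar(trimws(f[[2]]))
  }, logical(1))
  n_skipped <- n_blank + sum(!ok)
  fields <- fields[ok]
  if (n_skipped > 0) {
    warning(sprintf("skipped %d malformed or blank row(s)", n_skipped),
            call. = FALSE)
  }
  if (length(fields) == 0L) {
    out <- data.frame(phenotype_term = character(), gene_id = character(),
                      gene_symbol = character(), stringsAsFactors = FALSE)
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  col1 <- trimws(vapply(fields, `[[`, character(1), 1L))
  col2 <- trimws(vapply(fields, `[[`, character(1), 2L))
  if (dialect == "worm_pairs") {
    lab <- normalize_gene_label(col1)
    phen <- normalize_term(col2)
  } else {
    map <- allele_to_gene %||% function(a) sub("\\[[^]]*\\]\\s*$", "", a)
    lab <- normalize_gene_label(vapply(col1, function(a) {
      g <- map(a)
      if (is.na(g) || !nzchar(trimws(g))) a else g
    }, character(1), USE.NAMES = FALSE))
    phen <- normalize_term(col2)
  }
  out <- data.frame(phenotype_term = phen, gene_id = lab$gene_id,
                    gene_symbol = lab$gene_symbol, stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Build a non-redundant gene-set collection from a pair list
#'
#' Redundant (phenotype, gene) combinations are collapsed; one gene set per
#' unique phenotype term is produced, containing that term's unique genes.
#'
#' @param pairs Data frame with columns `phenotype_term` and `gene_id`
#'   (optionally `gene_symbol`), e.g. from [parse_association_table()].
#' @param label Collection label.
#' @param provenance Optional provenance string.
#' @return A [geneset_collection()].
#' @export
build_collection <- function(pairs, label = "collection", provenance = "") {
  if (is.null(pairs) || nrow(pairs) == 0L) {
    stop("cannot build a collection from an empty pair list", call. = FALSE)
  }
  term <- normalize_term(pairs$phenotype_term)
  id <- pairs$gene_id
  sym <- if ("gene_symbol" %in% names(pairs)) pairs$gene_symbol
         else rep(NA_character_, nrow(pairs))
  key <- paste(term, canonical_id(id), sep = "\r")
  keep <- !duplicated(key)
  term <- term[keep]; id <- id[keep]; sym <- sym[keep]
  sets <- lapply(split(seq_along(term), term), function(ix) {
    gene_set(term[ix[[1]]], id[ix], sym[ix])
  })
  # split() orders terms lexicographically, which fixes downstream ordering
  geneset_collection(unname(sets), label = label, provenance = provenance)
}

#' Merge two collections into one non-redundant collection
#'
#' The phenotype-term namespace of the result is the union of the two
#' inputs; sets sharing a term contain the union of their genes (compared
#' case-insensitively).
#'
#' @param a,b [geneset_collection()] objects.
#' @param label Label for the merged collection.
#' @return A [geneset_collection()].
#' @export
merge_collections <- function(a, b, label = NULL) {
  stopifnot(inherits(a, "geneset_collection"),
            inherits(b, "geneset_collection"))
  label <- label %||% paste(a$label, b$label, sep = "+")
  terms <- sort(union(names(a$sets), names(b$sets)))
  sets <- lapply(terms, function(t) {
    sa <- a$sets[[t]]; sb <- b$sets[[t]]
    if (is.null(sa)) return(sb)
    if (is.null(sb)) return(sa)
    genes <- c(sa$genes, sb$genes)
    syms <- c(unname(sa$symbols), unname(sb$symbols))
    suppressWarnings(gene_set(t, genes, syms))
  })
  geneset_collection(sets, label = label,
                     provenance = paste0("merge(", a$label, ", ", b$label, ")"))
}

#' Overlap between two collections
#'
#' @param a,b [geneset_collection()] objects.
#' @return List with `shared_genes` (count of canonical gene identifiers in
#'   both collections) and `shared_phenotypes` (count of phenotype terms in
#'   both).
#' @export
collection_overlap <- function(a, b) {
  stopifnot(inherits(a, "geneset_collection"),
            inherits(b, "geneset_collection"))
  list(
    shared_genes = length(intersect(collection_genes(a), collection_genes(b))),
    shared_phenotypes = length(intersect(names(a$sets), names(b$sets)))
  )
}

#' Filter a collection by set size
#'
#' Retains exactly the sets with `min_genes <= N(C_i) <= max_genes`
#' (inclusive bounds).  The input collection is not modified.
#'
#' @param coll A [geneset_collection()].
#' @param min_genes Minimum set size (>= 1).
#' @param max_genes Maximum set size, or `Inf` for unbounded.
#' @return A filtered [geneset_collection()].
#' @export
filter_by_size <- function(coll, min_genes = 1, max_genes = Inf) {
  stopifnot(inherits(coll, "geneset_collection"))
  if (min_genes < 1) stop("min_genes must be >= 1", call. = FALSE)
  if (is.finite(max_genes) && max_genes < min_genes) {
    stop("min_genes must not exceed max_genes", call. = FALSE)
  }
  sz <- collection_sizes(coll)
  keep <- sz >= min_genes & sz <= max_genes
  geneset_collection(unname(coll$sets[keep]), label = coll$label,
                     provenance = sprintf("%s | size filter [%s, %s]",
                                          coll$provenance, min_genes,
                                          max_genes))
}

#' Derivation counts against a directory of deposited gene-set files
#'
#' Computes the summary counts used to describe a deposited pair of worm
#' collections (RNAi and variant curation), their combination, and a fly
#' collection: set counts, size-filtered set counts, the sizes of two named
#' sets, and the gene/phenotype overlap between the two worm files.
#'
#' @param rnai,var,combined,fly Paths to GMT files.
#' @return Named list of counts.
#' @export
reference_derivation_counts <- function(rnai, var, combined, fly) {
  cr <- read_gmt(rnai)
  cv <- read_gmt(var)
  cc <- read_gmt(combined)
  cf <- read_gmt(fly)
  ov <- collection_overlap(cr, cv)
  list(
    n_sets_rnai = length(cr),
    n_sets_var = length(cv),
    n_sets_combined = length(cc),
    n_sets_fly = length(cf),
    n_sets_combined_min3 = length(filter_by_size(cc, 3)),
    n_sets_fly_min5 = length(filter_by_size(cf, 5)),
    size_life_span_variant = length(cc$sets[["life_span_variant"]]$genes %||%
                                      character()),
    size_long_lived = length(cf$sets[["long_lived"]]$genes %||% character()),
    overlap_genes = ov$shared_genes,
    overlap_phenotypes = ov$shared_phenotypes
  )
}
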