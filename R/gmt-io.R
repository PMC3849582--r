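#' Read a gene-set collection from a GMT file
#'
#' GMT is the tab-delimited one-set-per-line format: set name, description,
#' then the genes.  Gene tokens may carry a parenthesized symbol
#' (`"AC7.1(tag-49)"`), which is split off via [normalize_gene_label()].
#' Lines starting with `#` are treated as comments.
#'
#' @param file Path to a GMT file.
#' @param label Collection label; default is the file name.
#' @param split_symbols Split `"id(symbol)"` gene tokens (the worm
#'   convention).  Set `FALSE` for nomenclatures where parentheses are part
#'   of the gene name itself (fly names such as `"E(z)"`).
#' @return A [geneset_collection()].  Duplicate set names abort with the
#'   offending names; duplicated genes within a line are stored once with a
#'   warning.
#' @export
read_gmt <- function(file, label = NULL, split_symbols = TRUE) {
  if (!file.exists(file)) stop("cannot read GMT file: ", file, call. = FALSE)
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (length(lines) == 0L) stop("GMT file has no sets: ", file, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nm <- normalize_term(vapply(fields, `[[`, character(1), 1L))
  if (anyDuplicated(nm)) {
    stop("non-redundancy violated in GMT file; duplicate set names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  sets <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    genes <- trimws(f[-(1:2)][nzchar(trimws(f[-(1:2)]))])
    if (length(genes) == 0L) {
      stop("GMT set '", nm[[i]], "' has no genes", call. = FALSE)
    }
    if (split_symbols) {
      lab <- normalize_gene_label(genes)
      gene_set(nm[[i]], lab$gene_id, lab$gene_symbol)
    } else {
      gene_set(nm[[i]], genes)
    }
  })
  descr <- vapply(fields, function(f) if (length(f) >= 2) f[[2]] else "",
                  character(1))
  coll <- geneset_collection(sets, label = label %||% basename(file),
                             provenance = paste0("read_gmt(", file, ")"))
  attr(coll, "descriptions") <- stats::setNames(descr, nm)
  coll
}

#' Write a gene-set collection to a GMT file
#'
#' @param coll A [geneset_collection()].
#' @param file Output path.
#' @param description Either a single string recycled to every set, a named
#'   character vector keyed by set name, or `NULL` to use the collection's
#'   provenance.
#' @param header Optional character vector of comment lines written first.
#' @return Invisibly, the output path.
#' @export
write_gmt <- function(coll, file, description = NULL, header = NULL) {
  stopifnot(inherits(coll, "geneset_collection"))
  nm <- names(coll$sets)
  desc <- if (is.null(description)) {
    rep(if (nzchar(coll$provenance)) coll$provenance else coll$label,
        length(nm))
  } else if (!is.null(names(description))) {
    unname(ifelse(nm %in% names(description), description[nm], ""))
  } else {
    rep(as.character(description), length.out = length(nm))
  }
  lines <- vapply(seq_along(nm), function(i) {
    paste(c(nm[[i]], desc[[i]], coll$sets[[i]]$genes), collapse = "\t")
  }, character(1))
  writeLines(c(header, lines), file)
  invisible(file)
}

#' Write a collection summary (term, size) TSV
#'
#' @param coll A [geneset_collection()].
#' @param file Output path.
#' @param header Optional comment lines.
#' @return Invisibly, the output path.
#' @export
write_collection_summary <- function(coll, file, header = NULL) {
  s <- collection_summary(coll)
  con <- base::file(file, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(s, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
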