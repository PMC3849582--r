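# Internal helpers shared across modules.

# Case-insensitive canonical form used for all gene-identifier comparisons.
canonical_id <- function(x) toupper(x)

# Phenotype term normalization: trim, collapse internal whitespace runs to a
# single underscore ("life span variant" and "life_span_variant" collide).
normalize_term <- function(x) {
  gsub("\\s+", "_", trimws(x))
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

ps_log <- function(fmt, ...) {
  message(sprintf(paste0("phenosets: ", fmt), ...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Comment header recording provenance, written at the top of CLI output files.
provenance_header <- function(config = NULL, timestamp = TRUE) {
  h <- sprintf("# phenosets %s", as.character(packageVersion("phenosets")))
  if (!is.null(config)) {
    h <- c(h, sprintf("# config: %s", config))
  }
  if (timestamp) {
    h <- c(h, sprintf("# date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")))
  }
  h
}
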