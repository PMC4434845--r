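# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a local RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Gene identity is the uppercased symbol; no alias resolution.
as_gene_symbols <- function(x, context = "gene symbol") {
  x <- as.character(x)
  x <- trimws(x)
  bad <- !nzchar(x) | grepl("[[:space:]]", x)
  if (any(bad)) {
    stop(sprintf("invalid %s(s): %s", context,
                 paste(sQuote(utils::head(x[bad], 5)), collapse = ", ")),
         call. = FALSE)
  }
  toupper(x)
}

stop_line <- function(path, line, msg) {
  stop(sprintf("%s:%d: %s", path, line, msg), call. = FALSE)
}

check_catalog <- function(catalog) {
  if (!is.list(catalog) || is.null(names(catalog)) ||
      any(!nzchar(names(catalog))))
    stop("catalog must be a named list of gene-symbol vectors", call. = FALSE)
  if (anyDuplicated(names(catalog)))
    stop("duplicate disease labels in catalog", call. = FALSE)
  if (any(lengths(catalog) == 0L))
    stop("every disease gene set must be non-empty", call. = FALSE)
  lapply(catalog, as_gene_symbols)
}
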