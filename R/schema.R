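#' Column schema for tabular summary statistics
#'
#' GWAS analysis tools emit summary statistics in many tabular layouts with
#' no shared column naming. Rather than guessing column semantics, the
#' converter requires an explicit, user-supplied schema that maps semantic
#' fields to source columns. Mandatory mappings: `chrom`, `pos`,
#' `effect_allele`, `other_allele` and `es` (or `or`, an odds ratio, stored
#' as `es = log(OR)`); at least one of `p` / `lp` must also be mapped.
#' Optional: `se`, `af` (effect-allele frequency), `ss` (sample size),
#' `rsid`, `ident` (unique variant identifier for the VCF ID column).
#'
#' A schema document is a JSON object:
#' ```
#' {
#'   "delimiter": "\t",
#'   "header_row": true,
#'   "position_base": 1,
#'   "missing_values": ["NA", "", "."],
#'   "columns": {
#'     "chrom": "CHR", "pos": "BP",
#'     "effect_allele": "A1", "other_allele": "A2",
#'     "es": "BETA", "se": "SE", "p": "P",
#'     "af": "AF", "ss": "N", "rsid": "RSID"
#'   }
#' }
#' ```
#' Column values are header names (when `header_row` is true) or 1-based
#' column indexes. `position_base = 0` declares 0-based input positions,
#' corrected to 1-based at ingest; the package's public surface is always
#' 1-based inclusive. Unknown keys, at either level, are rejected loudly.
#'
#' @param x path to a JSON schema document, or a list with the same shape.
#' @return a validated `gwas_schema` object.
#' @examples
#' load_schema(list(columns = list(
#'   chrom = "CHR", pos = "BP", effect_allele = "A1",
#'   other_allele = "A2", es = "BETA", se = "SE", p = "P"
#' )))
#' @export
load_schema <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("schema file not found: ", x, call. = FALSE)
    x <- jsonlite::read_json(x, simplifyVector = TRUE)
  }
  if (!is.list(x)) stop("schema must be a file path or a list", call. = FALSE)

  top_known <- c("delimiter", "header_row", "position_base",
                 "missing_values", "columns")
  unknown <- setdiff(names(x), top_known)
  if (length(unknown)) {
    stop("unknown schema key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cols <- x$columns
  if (is.null(cols)) stop("schema is missing the 'columns' block", call. = FALSE)
  col_known <- c("chrom", "pos", "effect_allele", "other_allele",
                 "es", "or", "se", "p", "lp", "af", "ss", "rsid", "ident")
  unknown <- setdiff(names(cols), col_known)
  if (length(unknown)) {
    stop("unknown schema column key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (f in c("chrom", "pos", "effect_allele", "other_allele")) {
    if (is.null(cols[[f]])) {
      stop(sprintf("%s_UNMAPPED: schema must map the '%s' column",
                   toupper(f), f), call. = FALSE)
    }
  }
  if (is.null(cols[["es"]]) && is.null(cols[["or"]])) {
    stop("ES_UNMAPPED: schema must map an effect-size column ('es' or 'or')",
         call. = FALSE)
  }
  if (!is.null(cols[["es"]]) && !is.null(cols[["or"]])) {
    stop("schema maps both 'es' and 'or'; choose one", call. = FALSE)
  }
  if (is.null(cols[["p"]]) && is.null(cols[["lp"]])) {
    stop("P_UNMAPPED: schema must map 'p' or 'lp'", call. = FALSE)
  }
  schema <- list(
    delimiter = x$delimiter %||% "\t",
    header_row = isTRUE(x$header_row %||% TRUE),
    position_base = as.integer(x$position_base %||% 1L),
    missing_values = unique(c(as.character(x$missing_values %||% character()),
                              c("NA", "", "."))),
    columns = cols
  )
  if (!schema$position_base %in% c(0L, 1L)) {
    stop("position_base must be 0 or 1", call. = FALSE)
  }
  structure(schema, class = "gwas_schema")
}

#' @export
print.gwas_schema <- function(x, ...) {
  cat("<gwas_schema>", if (x$header_row) "header row," else "no header,",
      sprintf("%d-based positions\n", x$position_base))
  cat("  columns:", paste(sprintf("%s=%s", names(x$columns),
                                  unlist(x$columns)), collapse = ", "), "\n")
  invisible(x)
}

#' Write a schema document to JSON
#' @param schema a `gwas_schema`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "gwas_schema"))
  jsonlite::write_json(unclass(schema), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
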