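# Dual indexing: positional (tabix) and rsid -> locus.

#' Build the positional (tabix) index
#'
#' Produces a `.tbi` index over a BGZF-compressed, coordinate-sorted
#' GWAS-VCF, usable by this package's query functions and by any
#' htslib-family tool.
#'
#' @param path BGZF-compressed, karyotypically sorted VCF.
#' @return path of the index file, invisibly.
#' @export
index_positions <- function(path) {
  idx <- tryCatch(
    Rsamtools::indexTabix(path, format = "vcf"),
    error = function(e) {
      stop("cannot tabix-index '", path, "': ", conditionMessage(e),
           "\n  the file must be BGZF-compressed (write_gwasvcf) and ",
           "karyotypically sorted (sort_karyotypic)", call. = FALSE)
    }
  )
  invisible(idx)
}

#' Default rsid-index location for a GWAS-VCF file
#' @param path the GWAS-VCF path.
#' @return `<path>.rsidx`.
#' @export
rsid_index_path <- function(path) paste0(path, ".rsidx")

#' Build the rsid index
#'
#' Scans the file body and writes a persistent map from integer rsid to
#' `(chrom, pos)`: a tab-separated three-column table (`rsid`, `chrom`,
#' `pos`) sorted by rsid for keyed binary-search lookup. rsids identify
#' loci, so a multiallelic site split across several records contributes one
#' index entry; a positional fetch at the mapped locus returns all sibling
#' records. Records without an rsid are simply absent from the index;
#' malformed rsids are skipped with a warning.
#'
#' @param path GWAS-VCF file (BGZF-compressed).
#' @param out index file path; defaults to `<path>.rsidx`.
#' @return (invisibly) list `path`, `n_indexed`, `n_without_rsid`,
#'   `n_malformed`.
#' @export
index_rsids <- function(path, out = rsid_index_path(path)) {
  lines <- readLines(gzfile(path))
  body <- lines[!startsWith(lines, "#")]
  f <- data.table::tstrsplit(body, "\t", fixed = TRUE, keep = c(1L, 2L, 8L))
  rsid <- info_field(f[[3]], "RSID")
  n_without <- sum(is.na(rsid))
  malformed <- !is.na(rsid) & !grepl("^rs[0-9]+$", rsid)
  if (any(malformed)) {
    warning(sum(malformed), " malformed rsid(s) skipped from the rsid index",
            call. = FALSE)
  }
  keep <- !is.na(rsid) & !malformed
  map <- unique(data.table(
    rsid = as.integer(sub("^rs", "", rsid[keep])),
    chrom = f[[1]][keep],
    pos = as.integer(f[[2]][keep])
  ))
  setorderv(map, c("rsid", "chrom", "pos"))
  fwrite(map, out, sep = "\t")
  invisible(list(path = out, n_indexed = nrow(map),
                 n_without_rsid = n_without, n_malformed = sum(malformed)))
}

#' Load an rsid index
#' @param path the `.rsidx` file (or the VCF path, from which the default
#'   index location is derived).
#' @return keyed data.table (`rsid`, `chrom`, `pos`).
#' @export
read_rsid_index <- function(path) {
  if (!file.exists(path) && file.exists(rsid_index_path(path))) {
    path <- rsid_index_path(path)
  }
  if (!file.exists(path)) {
    stop("rsid index not found: ", path,
         "; run index_rsids() on the GWAS-VCF first", call. = FALSE)
  }
  idx <- fread(path, header = TRUE,
               colClasses = list(character = "chrom", integer = c("rsid", "pos")))
  setkeyv(idx, "rsid")
  idx
}

#' Look up the locus of an rsid
#'
#' @param index a loaded rsid index ([read_rsid_index()]) or a `.rsidx` path.
#' @param rsid rsid as `"rs123"` or integer 123.
#' @return data.table of loci (`chrom`, `pos`) with attribute `found`;
#'   zero rows and `found = FALSE` when the rsid is not in the index (a
#'   not-found result, distinct from an empty locus).
#' @export
lookup_rsid <- function(index, rsid) {
  if (is.character(index)) index <- read_rsid_index(index)
  key <- if (is.character(rsid)) as.integer(sub("^rs", "", rsid)) else as.integer(rsid)
  if (is.na(key)) stop("malformed rsid: ", rsid, call. = FALSE)
  hit <- index[list(key), nomatch = NULL]
  res <- hit[, .(chrom, pos)]
  setattr(res, "found", nrow(res) > 0L)
  res
}
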