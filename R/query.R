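# Retrieval over indexed GWAS-VCF: point, interval, rsid and P-value queries.
#
# Interval semantics are pos-anchored and 1-based inclusive: a record belongs
# to the region iff its POS lies inside it; a deletion whose REF allele spans
# into the region but whose POS precedes it is excluded. This matches how the
# positional index keys records and keeps naive-scan equivalence exact.

parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)$", region))[[1]]
    if (length(m) != 3L) stop("cannot parse region '", region,
                              "'; expected CHR:START-END or CHR:POS", call. = FALSE)
    m <- c(m, m[3L])
  }
  list(chrom = m[2L], start = as.integer(m[3L]), end = as.integer(m[4L]))
}

#' Query records in a genomic interval
#'
#' @param path indexed GWAS-VCF (a `.tbi` from [index_positions()] must
#'   exist).
#' @param chrom chromosome name, or a region string `"CHR:START-END"` (then
#'   `start`/`end` are ignored).
#' @param start,end 1-based inclusive interval bounds; `start == end` is a
#'   single-position query.
#' @return [gwas_records()] table of matching records, in file order.
#' @export
query_interval <- function(path, chrom, start = NULL, end = NULL) {
  if (is.null(start)) {
    r <- parse_region(chrom)
    chrom <- r$chrom; start <- r$start; end <- r$end
  }
  if (is.null(end)) end <- start
  stopifnot(start >= 1L, end >= start)
  if (!file.exists(paste0(path, ".tbi"))) {
    stop("positional index missing for '", path,
         "'; run index_positions() first", call. = FALSE)
  }
  hdr <- read_vcf_header(path)
  tf <- Rsamtools::TabixFile(path)
  lines <- tryCatch(
    unlist(Rsamtools::scanTabix(
      tf, param = GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))),
      use.names = FALSE),
    error = function(e) character()   # contig absent from index -> no records
  )
  recs <- parse_vcf_body(lines, hdr$samples)
  gwas_records(recs, traits = hdr$traits, contigs = hdr$contigs,
               assembly = hdr$assembly)
}

#' Query a single genomic position
#' @inheritParams query_interval
#' @param pos 1-based position.
#' @return matching records.
#' @export
query_position <- function(path, chrom, pos) {
  query_interval(path, chrom, pos, pos)
}

#' Query records by rsid
#'
#' Looks the rsid up in the rsid index, then fetches all records at the
#' mapped locus. Because rsids identify loci rather than allelic
#' substitutions, a split multiallelic site returns every sibling record;
#' use `ref`/`alt` to filter the output down to one target substitution.
#'
#' @param path indexed GWAS-VCF (both `.tbi` and `.rsidx` required).
#' @param rsid rsid string (`"rs123"`) or integer.
#' @param ref,alt optional allele filters applied to the result.
#' @return matching records; attribute `found` is `FALSE` when the rsid is
#'   absent from the index.
#' @export
query_rsid <- function(path, rsid, ref = NULL, alt = NULL) {
  loci <- lookup_rsid(rsid_index_path(path), rsid)
  if (!attr(loci, "found", exact = TRUE)) {
    out <- query_interval(path, "___none___", 1L, 1L)[0L]
    setattr(out, "found", FALSE)
    return(out)
  }
  out <- rbindlist(lapply(seq_len(nrow(loci)), function(i)
    query_position(path, loci$chrom[i], loci$pos[i])))
  keep <- rep(TRUE, nrow(out))
  if (!is.null(ref)) keep <- keep & out[["ref"]] == ref
  if (!is.null(alt)) keep <- keep & out[["alt"]] == alt
  out <- out[which(keep)]
  setattr(out, "found", TRUE)
  out[]
}

#' Query records by association P value
#'
#' A full linear scan (no index assists this query class): returns the
#' (variant, trait) rows whose stored LP satisfies `lp > -log10(p_threshold)`
#' -- i.e. P strictly below the threshold. Missing LP never matches.
#'
#' @param path GWAS-VCF file.
#' @param p_threshold P-value threshold in (0, 1\].
#' @param trait_id restrict to one trait; default scans every trait.
#' @param chunk_size body lines parsed per chunk (memory bound).
#' @return matching records (long rows for the matching traits).
#' @export
query_pvalue <- function(path, p_threshold, trait_id = NULL,
                         chunk_size = 200000L) {
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1) {
    stop("p_threshold must lie in (0, 1]", call. = FALSE)
  }
  lp_min <- -log10(p_threshold)
  hdr <- read_vcf_header(path)
  if (!is.null(trait_id) && !trait_id %in% hdr$samples) {
    stop("trait '", trait_id, "' not in file (traits: ",
         paste(hdr$samples, collapse = ", "), ")", call. = FALSE)
  }
  con <- gzfile(path, "rt")
  on.exit(close(con), add = TRUE)
  hits <- list()
  repeat {
    lines <- readLines(con, n = chunk_size)
    if (!length(lines)) break
    lines <- lines[!startsWith(lines, "#")]
    if (!length(lines)) next
    recs <- parse_vcf_body(lines, hdr$samples)
    if (!is.null(trait_id)) recs <- recs[trait == trait_id]
    recs <- recs[!is.na(lp) & lp > lp_min]
    if (nrow(recs)) hits[[length(hits) + 1L]] <- recs
  }
  out <- if (length(hits)) rbindlist(hits) else
    parse_vcf_body(character(), hdr$samples)
  gwas_records(out, traits = hdr$traits, contigs = hdr$contigs,
               assembly = hdr$assembly)
}
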