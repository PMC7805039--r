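# End-to-end conversion: tabular summary statistics -> validated, harmonised,
# sorted, BGZF-compressed, dually indexed GWAS-VCF.

#' Convert tabular summary statistics to GWAS-VCF
#'
#' Runs the full pipeline: ingest under the schema, harmonise against the
#' reference genome, left-align and trim indels, optionally annotate rsids
#' from a dbSNP-style mapping, sort karyotypically, write BGZF-compressed
#' VCF and build the positional (tabix) and rsid indexes.
#'
#' Records whose harmonisation fails (`incompatible`, `not_in_reference`,
#' `normalize_failed`) are excluded from the output with a logged count by
#' default; with `keep_incompatible = TRUE` they are written with the FILTER
#' label `HARMONISATION_FAILED` instead. Rows rejected at ingest (malformed)
#' never fail the conversion unless `strict = TRUE` -- real summary
#' statistics are messy, and the report carries the counts.
#'
#' @param sumstats path to the summary-statistics table (TSV/CSV, plain or
#'   gzipped).
#' @param schema path to a schema JSON, or a [load_schema()] object/list.
#' @param reference path to an indexed FASTA, or a reference object.
#' @param out output GWAS-VCF path (`.vcf.gz`).
#' @param metadata a [study_metadata()] block for the trait.
#' @param assembly genome assembly name recorded in the header.
#' @param keep_incompatible keep harmonisation failures, FILTER-labelled.
#' @param strict fail (error) on any rejected or failed row.
#' @param chrom_style `"none"` (default: contig names must match the
#'   reference as-is), `"strip-chr"` or `"add-chr"` to reconcile a "chr"
#'   prefix between input and reference -- never applied silently.
#' @param dbsnp optional rsid mapping (path to 3-column TSV or VCF) used to
#'   fill missing rsids; see [annotate_rsids()].
#' @return report list: `path`, ingest `counts`, `issues`, harmonisation
#'   `status_counts`, `n_written`, `n_excluded`, index paths.
#' @export
convert_sumstats <- function(sumstats, schema, reference, out,
                             metadata = study_metadata(trait_id = "trait_1"),
                             assembly = "synthetic",
                             keep_incompatible = FALSE,
                             strict = FALSE,
                             chrom_style = c("none", "strip-chr", "add-chr"),
                             dbsnp = NULL) {
  chrom_style <- match.arg(chrom_style)
  if (!inherits(schema, "gwas_schema")) schema <- load_schema(schema)
  if (!inherits(reference, "reference_genome")) reference <- ref_fasta(reference)
  stopifnot(inherits(metadata, "study_metadata"))
  trait_id <- metadata$trait_id
  contigs <- ref_contigs(reference)

  ing <- read_sumstats(sumstats, schema, trait_id = trait_id)
  cand <- ing$candidates
  if (chrom_style == "strip-chr") cand[, chrom := sub("^chr", "", chrom)]
  if (chrom_style == "add-chr") {
    cand[!startsWith(chrom, "chr"), chrom := paste0("chr", chrom)]
  }

  harm <- harmonize_records(cand, reference)
  harm <- normalize_records(harm, reference)
  if (!is.null(dbsnp)) harm <- annotate_rsids(harm, dbsnp)

  failed <- !harm$status %in% c("unchanged", "swapped")
  status_counts <- as.list(table(harm$status))
  if (keep_incompatible) {
    harm[failed, filter := "HARMONISATION_FAILED"]
    keep <- harm
  } else {
    keep <- harm[!failed]
  }
  n_excluded <- if (keep_incompatible) 0L else sum(failed)

  if (strict && (nrow(ing$issues) > 0L || any(failed))) {
    stop(sprintf(
      "strict mode: %d row(s) rejected at ingest, %d harmonisation failure(s)",
      nrow(ing$issues), sum(failed)), call. = FALSE)
  }

  traits <- stats::setNames(list(metadata), trait_id)
  recs <- gwas_records(keep, traits = traits, contigs = contigs,
                       assembly = assembly)
  recs <- sort_karyotypic(recs)
  filters <- if (keep_incompatible && any(failed)) {
    c(HARMONISATION_FAILED = "Neither allele matches the reference genome or the variant could not be normalised")
  } else NULL
  wr <- write_gwasvcf(recs, out, extra_filters = filters)
  tbi <- index_positions(out)
  rsx <- index_rsids(out)

  structure(list(
    path = out, counts = ing$counts, issues = ing$issues,
    status_counts = status_counts,
    n_written = wr$n_records, n_variants = wr$n_variants,
    n_excluded = n_excluded,
    tbi = tbi, rsidx = rsx$path, n_rsid_indexed = rsx$n_indexed
  ), class = "gwas_convert_report")
}

#' @export
print.gwas_convert_report <- function(x, ...) {
  cat("GWAS-VCF conversion report\n")
  cat(sprintf("  output: %s\n", x$path))
  cat(sprintf("  rows read %d | emitted %d | rejected at ingest %d\n",
              x$counts$read, x$counts$emitted, x$counts$rejected))
  sc <- x$status_counts
  cat("  harmonisation:",
      paste(sprintf("%s=%d", names(sc), unlist(sc)), collapse = ", "), "\n")
  cat(sprintf("  written %d record(s) at %d variant(s); excluded %d\n",
              x$n_written, x$n_variants, x$n_excluded))
  invisible(x)
}

#' Validate a GWAS-VCF file
#'
#' Runs four checks and reports PASS/FAIL for each: the header parses with
#' contigs and at least one trait column; every body record satisfies the
#' data-model invariants ([validate_records()]); non-null IDs are unique;
#' and the body is karyotypically sorted.
#'
#' @param path GWAS-VCF file.
#' @return data.table (`check`, `pass`, `detail`) with attribute `pass`
#'   (overall).
#' @export
validate_gwasvcf <- function(path) {
  checks <- list()
  hdr_ok <- TRUE
  hdr <- tryCatch(read_vcf_header(path), error = function(e) e)
  if (inherits(hdr, "error")) {
    checks[["header"]] <- list(FALSE, conditionMessage(hdr))
    res <- data.table(check = "header", pass = FALSE,
                      detail = conditionMessage(hdr))
    setattr(res, "pass", FALSE)
    return(res)
  }
  checks[["header"]] <- list(
    nrow(hdr$contigs) > 0L && length(hdr$samples) >= 1L,
    sprintf("%d contig(s), %d trait column(s)", nrow(hdr$contigs),
            length(hdr$samples)))

  recs <- read_gwasvcf(path)
  viol <- validate_records(recs, contigs = hdr$contigs)
  checks[["records"]] <- list(
    nrow(viol) == 0L,
    if (nrow(viol)) paste0(nrow(viol), " violation(s), e.g. ", viol$code[1L])
    else sprintf("%d record(s) valid", nrow(recs)))

  dup <- check_id_uniqueness(recs)
  checks[["id_uniqueness"]] <- list(
    length(dup) == 0L,
    if (length(dup)) paste("duplicated:", paste(dup, collapse = ", "))
    else "all non-null IDs unique")

  key <- unique(as.data.table(recs)[, .(chrom, pos, ref, alt)])
  rnk <- match(key$chrom, hdr$contigs$name)
  sorted <- !anyNA(rnk) && !is.unsorted(rnk) &&
    !any(diff(key$pos) < 0 & diff(rnk) == 0)
  checks[["sort_order"]] <- list(sorted,
    if (sorted) "karyotypically sorted" else "position regression detected")

  res <- data.table(
    check = names(checks),
    pass = vapply(checks, function(x) isTRUE(x[[1L]]), TRUE),
    detail = vapply(checks, function(x) as.character(x[[2L]]), "")
  )
  setattr(res, "pass", all(res$pass))
  res[]
}
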