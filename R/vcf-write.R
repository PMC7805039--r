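# GWAS-VCF serialization: VCF 4.2 text, BGZF-compressed, one variant per row,
# per-trait association statistics in the sample columns.

PKG_VERSION <- function() as.character(utils::packageVersion("gwasvcfkit"))

FORMAT_DEFS <- c(
  ES = '##FORMAT=<ID=ES,Number=A,Type=Float,Description="Effect size estimate relative to the alternative (effect) allele">',
  SE = '##FORMAT=<ID=SE,Number=A,Type=Float,Description="Standard error of effect size estimate">',
  LP = '##FORMAT=<ID=LP,Number=A,Type=Float,Description="-log10 P value for effect estimate">',
  AF = '##FORMAT=<ID=AF,Number=A,Type=Float,Description="Effect-allele frequency in the trait analysis sample">',
  SS = '##FORMAT=<ID=SS,Number=A,Type=Integer,Description="Sample size used to estimate genetic effect">'
)
INFO_DEFS <- c(
  AF = '##INFO=<ID=AF,Number=A,Type=Float,Description="Alternative (effect) allele frequency">',
  RSID = '##INFO=<ID=RSID,Number=1,Type=String,Description="dbSNP locus identifier; rsids identify loci, not allelic substitutions">'
)

quote_meta <- function(x) paste0('"', gsub('"', "'", x), '"')

#' Build a GWAS-VCF header
#'
#' Emits a VCF-4.2-conformant header: the fileformat line; one contig line
#' per declared contig (with length and assembly); FORMAT definitions
#' (ID/Number/Type/Description) for every per-trait field used -- ES, SE, LP
#' at minimum, plus AF and SS when present; INFO definitions (AF, RSID);
#' one structured SAMPLE line per trait carrying the study metadata; and the
#' #CHROM column line ending with FORMAT and one sample column per trait.
#'
#' @param traits named list of [study_metadata()] blocks (>= 1); names are
#'   the sample column ids and must be unique.
#' @param contigs data.frame `name`, `length` (non-empty); order defines the
#'   karyotypic sort order of the file body.
#' @param assembly genome assembly name (stored on contig lines and as a
#'   dedicated meta line).
#' @param format_fields FORMAT fields to declare, a subset of
#'   `c("ES","SE","LP","AF","SS")`; ES/SE/LP are always included.
#' @param info_fields INFO fields to declare (subset of `c("AF","RSID")`).
#' @param filters extra FILTER ids to declare, named by id with description
#'   values.
#' @param file_date date stamped into the header.
#' @return character vector of header lines (the last is the #CHROM line).
#' @export
build_header <- function(traits, contigs, assembly = NA_character_,
                         format_fields = c("ES", "SE", "LP"),
                         info_fields = c("AF", "RSID"),
                         filters = character(),
                         file_date = format(Sys.Date(), "%Y%m%d")) {
  stopifnot(length(traits) >= 1L)
  contigs <- as.data.table(contigs)
  if (!nrow(contigs)) stop("contig list is empty", call. = FALSE)
  ids <- names(traits)
  if (is.null(ids)) ids <- vapply(traits, `[[`, "", "trait_id")
  if (anyDuplicated(ids)) {
    stop("duplicate trait_id in header: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  format_fields <- union(c("ES", "SE", "LP"), format_fields)
  format_fields <- names(FORMAT_DEFS)[names(FORMAT_DEFS) %in% format_fields]
  bad <- setdiff(info_fields, names(INFO_DEFS))
  if (length(bad)) stop("undeclared INFO field(s): ", paste(bad, collapse = ", "))

  h <- c(
    "##fileformat=VCFv4.2",
    paste0("##fileDate=", file_date),
    paste0("##source=gwasvcfkit-", PKG_VERSION())
  )
  if (!is.na(assembly)) h <- c(h, paste0("##genome_assembly=", assembly))
  h <- c(h, sprintf("##contig=<ID=%s,length=%d%s>", contigs$name,
                    as.integer(contigs$length),
                    if (!is.na(assembly)) paste0(",assembly=", assembly) else ""))
  if (length(filters)) {
    h <- c(h, sprintf('##FILTER=<ID=%s,Description=%s>', names(filters),
                      quote_meta(unname(filters))))
  }
  h <- c(h, unname(INFO_DEFS[info_fields]), unname(FORMAT_DEFS[format_fields]))
  for (i in seq_along(traits)) {
    md <- traits[[i]]
    kv <- c(ID = ids[i])
    pairs <- c(TraitLabel = "trait_label", TraitOntology = "trait_ontology",
               StudyID = "study_id", TotalSamples = "sample_size",
               Ancestry = "ancestry", Units = "units",
               AssociationTest = "association_test",
               SourceFile = "source_file", FileDate = "file_date")
    for (k in names(pairs)) {
      v <- md[[pairs[[k]]]]
      if (!is.null(v) && !is.na(v)) {
        kv[k] <- if (k == "TotalSamples") as.character(v) else quote_meta(v)
      }
    }
    h <- c(h, paste0("##SAMPLE=<", paste(names(kv), kv, sep = "=",
                                         collapse = ","), ">"))
  }
  c(h, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
               "INFO", "FORMAT", ids), collapse = "\t"))
}

# serialize numerics: ES/SE at full double precision (15 significant digits,
# round-trips well past the 4-significant-figure export guarantee); LP and
# frequencies at 6 significant digits.
fmt_full <- function(x) {
  out <- as.character(x)
  out[is.na(x)] <- "."
  out
}
fmt_sig6 <- function(x) {
  out <- as.character(signif(x, 6L))
  out[is.na(x)] <- "."
  out
}
fmt_int <- function(x) {
  out <- as.character(as.integer(x))
  out[is.na(x)] <- "."
  out
}

#' Write records to a BGZF-compressed GWAS-VCF file
#'
#' Serializes a karyotypically sorted record table to VCF 4.2, BGZF
#' compresses it, and reports what was written. Every body line carries a
#' value (or ".") for every declared FORMAT field in every sample column, in
#' the fixed order ES:SE:LP\[:AF\]\[:SS\] so identical inputs produce
#' byte-identical files. Optional fields (FORMAT AF/SS, INFO AF/RSID) are
#' declared only when some record uses them. Unsorted input and duplicate
#' non-null IDs are fatal.
#'
#' @param records long-form record table (see [gwas_records()]).
#' @param path output path, conventionally ending `.vcf.gz`.
#' @param traits,contigs,assembly header metadata; default to the records'
#'   attributes.
#' @param extra_filters named character vector of FILTER definitions used by
#'   the records' `filter` column.
#' @param file_date date stamped into the header.
#' @return (invisibly) a report list: `path`, `n_variants`, `n_records`,
#'   `status_counts` (when the table carries a `status` column).
#' @export
write_gwasvcf <- function(records, path,
                          traits = attr(records, "traits", exact = TRUE),
                          contigs = attr(records, "contigs", exact = TRUE),
                          assembly = attr(records, "assembly", exact = TRUE),
                          extra_filters = NULL,
                          file_date = format(Sys.Date(), "%Y%m%d")) {
  dt <- as.data.table(records)
  if (is.null(contigs)) stop("write_gwasvcf: contig list required", call. = FALSE)
  contigs <- as.data.table(contigs)
  if (is.null(assembly)) assembly <- NA_character_
  trait_ids <- if (!is.null(traits)) names(traits) else sort(unique(dt$trait))
  if (is.null(traits)) {
    traits <- lapply(trait_ids, function(tid) study_metadata(trait_id = tid))
    names(traits) <- trait_ids
  }
  if (!all(dt$trait %in% trait_ids)) {
    stop("records contain trait(s) absent from header metadata: ",
         paste(setdiff(unique(dt$trait), trait_ids), collapse = ", "),
         call. = FALSE)
  }

  # sortedness: contig rank must be non-decreasing, pos non-decreasing per contig
  key <- unique(dt[, .(chrom, pos, ref, alt)])
  rnk <- match(key$chrom, contigs$name)
  if (anyNA(rnk)) {
    stop("undeclared contig(s): ",
         paste(unique(key$chrom[is.na(rnk)]), collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(rnk) ||
      any(diff(key$pos) < 0 & diff(rnk) == 0)) {
    stop("records are not karyotypically sorted; run sort_karyotypic() first",
         call. = FALSE)
  }
  dup <- check_id_uniqueness(dt)
  if (length(dup)) {
    stop("duplicate variant ID(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }

  use_af_fmt <- any(!is.na(dt$eaf))
  use_ss <- any(!is.na(dt$ss))
  fmt_ids <- c("ES", "SE", "LP", if (use_af_fmt) "AF", if (use_ss) "SS")
  info_ids <- c(if (any(!is.na(dt$af))) "AF", if (any(!is.na(dt$rsid))) "RSID")
  filt <- character()
  if (!is.null(extra_filters)) filt <- extra_filters

  hdr <- build_header(traits, contigs, assembly,
                      format_fields = fmt_ids, info_fields = info_ids,
                      filters = filt, file_date = file_date)

  # per (variant, trait) sample cell
  cell <- paste(fmt_full(dt$es), fmt_full(dt$se), fmt_sig6(dt$lp), sep = ":")
  if (use_af_fmt) cell <- paste(cell, fmt_sig6(dt$eaf), sep = ":")
  if (use_ss) cell <- paste(cell, fmt_int(dt$ss), sep = ":")
  missing_cell <- paste(rep(".", length(fmt_ids)), collapse = ":")

  body_dt <- copy(dt)[, value := cell]
  wide <- data.table::dcast(
    body_dt, chrom + pos + id + ref + alt + filter + af + rsid ~ trait,
    value.var = "value", fill = missing_cell
  )
  for (tid in trait_ids) {
    if (!tid %in% names(wide)) wide[, (tid) := missing_cell]
  }
  # dcast sorts by the LHS keys lexicographically; restore karyotypic order
  wide[, rank__ := match(chrom, contigs$name)]
  setorderv(wide, c("rank__", "pos", "ref", "alt"))
  wide[, rank__ := NULL]

  info <- rep("", nrow(wide))
  if ("AF" %in% info_ids) {
    has <- !is.na(wide$af)
    info[has] <- paste0("AF=", fmt_sig6(wide$af[has]))
  }
  if ("RSID" %in% info_ids) {
    has <- !is.na(wide$rsid)
    info[has] <- paste0(info[has], ifelse(nzchar(info[has]), ";", ""),
                        "RSID=", wide$rsid[has])
  }
  info[!nzchar(info)] <- "."

  idc <- wide$id; idc[is.na(idc)] <- "."
  fc <- wide$filter; fc[is.na(fc)] <- "."
  lines <- paste(wide$chrom, wide$pos, idc, wide$ref, wide$alt, ".",
                 fc, info, paste(fmt_ids, collapse = ":"), sep = "\t")
  for (tid in trait_ids) lines <- paste(lines, wide[[tid]], sep = "\t")

  tmp <- tempfile(fileext = ".vcf")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(c(hdr, lines), tmp)
  if (file.exists(path)) unlink(path)
  Rsamtools::bgzip(tmp, dest = path, overwrite = TRUE)

  report <- list(path = path, n_variants = nrow(wide), n_records = nrow(dt))
  if ("status" %in% names(dt)) {
    report$status_counts <- as.list(table(dt$status))
  }
  invisible(report)
}
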