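#' GWAS association records
#'
#' The central container of the package: a `data.table` in long form with one
#' row per variant x trait. A variant is identified by `(chrom, pos, ref,
#' alt)`; `ref` is the non-effect allele (matching the reference genome after
#' harmonisation) and `alt` is the effect allele, so the sign of `es` is
#' always with respect to `alt`.
#'
#' Columns:
#' \describe{
#'   \item{chrom}{chromosome name (character).}
#'   \item{pos}{1-based base position (integer).}
#'   \item{id}{unique variant identifier or `NA` (VCF ID column; never an
#'     rsid, which identifies a locus, not an allelic substitution).}
#'   \item{ref, alt}{uppercase A/C/G/T allele sequences, length >= 1.}
#'   \item{qual}{always `NA`; no per-variant quality model is defined.}
#'   \item{filter}{filter label or `NA` meaning PASS/null.}
#'   \item{af}{site-level alternative-allele frequency in \[0,1\] or `NA`.}
#'   \item{rsid}{dbSNP locus identifier (`rs[0-9]+`) or `NA`.}
#'   \item{trait}{trait identifier (the VCF sample column this row belongs to).}
#'   \item{es}{effect size on the `alt` (effect) allele.}
#'   \item{se}{standard error of `es` (> 0 when present).}
#'   \item{lp}{-log10 association P value (>= 0 when present).}
#'   \item{eaf}{per-trait effect-allele frequency in \[0,1\] or `NA`.}
#'   \item{ss}{per-trait sample size (positive integer) or `NA`.}
#' }
#'
#' Attributes carry file-level metadata: `traits` (named list of
#' [study_metadata()] blocks), `contigs` (data.table of `name`, `length`
#' whose order defines the karyotypic sort), and `assembly` (genome assembly
#' name).
#'
#' @param x data.frame/data.table with at least `chrom, pos, ref, alt, trait`.
#' @param traits named list of [study_metadata()], one per trait id.
#' @param contigs data.frame with columns `name`, `length`.
#' @param assembly genome assembly label (character scalar).
#' @return a `gwas_records` data.table.
#' @export
gwas_records <- function(x, traits = NULL, contigs = NULL, assembly = NA_character_) {
  dt <- as.data.table(x)
  defaults <- list(
    id = NA_character_, qual = NA_real_, filter = NA_character_,
    af = NA_real_, rsid = NA_character_, trait = "trait_1",
    es = NA_real_, se = NA_real_, lp = NA_real_, eaf = NA_real_,
    ss = NA_integer_
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(dt)) dt[, (nm) := defaults[[nm]]]
  }
  dt[, chrom := as.character(chrom)]
  dt[, pos := as.integer(pos)]
  dt[, ss := as.integer(ss)]
  cols <- c("chrom", "pos", "id", "ref", "alt", "qual", "filter", "af",
            "rsid", "trait", "es", "se", "lp", "eaf", "ss")
  dt <- dt[, cols, with = FALSE]
  if (is.null(traits)) {
    traits <- lapply(unique(dt$trait), function(tid) study_metadata(trait_id = tid))
    names(traits) <- unique(dt$trait)
  }
  setattr(dt, "traits", traits)
  setattr(dt, "contigs", if (is.null(contigs)) NULL else as.data.table(contigs))
  setattr(dt, "assembly", assembly)
  setattr(dt, "class", c("gwas_records", class(dt)))
  dt[]
}

#' @export
print.gwas_records <- function(x, ...) {
  nv <- nrow(unique(x[, c("chrom", "pos", "ref", "alt")]))
  cat(sprintf("<gwas_records> %d variants x %d trait(s), assembly %s\n",
              nv, length(unique(x$trait)),
              attr(x, "assembly", exact = TRUE)))
  NextMethod()
}

#' Per-trait study metadata
#'
#' One metadata block per VCF sample column (= trait), serialized into the
#' header so the file carries a full audit trail: where the statistics came
#' from, which study, which trait ontology, sample size, ancestry, units and
#' association test.
#'
#' @param trait_id short unique trait identifier (the sample column name).
#' @param trait_label free-text trait description.
#' @param trait_ontology ontology source and version, e.g. `"EFO 3.26"`.
#' @param study_id PMID / DOI / repository accession of the study.
#' @param sample_size total study sample size.
#' @param ancestry ancestry description.
#' @param units measurement units of the effect size.
#' @param association_test association test used, e.g. `"linear regression"`.
#' @param source_file provenance of the original summary-statistics file.
#' @param file_date ISO date of conversion.
#' @return list with class `study_metadata`.
#' @export
study_metadata <- function(trait_id,
                           trait_label = trait_id,
                           trait_ontology = NA_character_,
                           study_id = NA_character_,
                           sample_size = NA_integer_,
                           ancestry = NA_character_,
                           units = NA_character_,
                           association_test = NA_character_,
                           source_file = NA_character_,
                           file_date = format(Sys.Date(), "%Y-%m-%d")) {
  stopifnot(is.character(trait_id), length(trait_id) == 1L, nzchar(trait_id))
  structure(list(
    trait_id = trait_id, trait_label = trait_label,
    trait_ontology = trait_ontology, study_id = study_id,
    sample_size = if (is.na(sample_size)) NA_integer_ else as.integer(sample_size),
    ancestry = ancestry, units = units,
    association_test = association_test,
    source_file = source_file, file_date = file_date
  ), class = "study_metadata")
}

allele_ok <- function(a) {
  !is.na(a) & nzchar(a) & !grepl("[^ACGT]", a)
}

#' Validate GWAS records against the data-model invariants
#'
#' Violations are data, not exceptions: the function always returns a table
#' of machine-readable violation codes (empty when every invariant holds),
#' one row per (record row, code). Checked invariants: positions are 1-based
#' (`POSITION_NOT_ONE_BASED`), alleles differ (`ALLELES_IDENTICAL`) and are
#' non-empty uppercase A/C/G/T (`ALLELE_INVALID_CHARS`), the chromosome is a
#' declared contig (`CONTIG_UNDECLARED`) and the position does not exceed its
#' length (`POSITION_EXCEEDS_CONTIG`), frequencies lie in \[0,1\]
#' (`AF_OUT_OF_RANGE`), `lp` is non-negative (`LP_NEGATIVE`), `se` is
#' positive when present (`SE_NOT_POSITIVE`), and rsids match `rs[0-9]+`
#' (`RSID_MALFORMED`).
#'
#' @param records a [gwas_records()] table (or any data.frame with the same
#'   columns).
#' @param contigs data.frame of declared contigs (`name`, `length`); defaults
#'   to the records' own `contigs` attribute. `NULL` skips contig checks.
#' @return data.table with columns `row` (index into `records`), `code`,
#'   `message`.
#' @export
validate_records <- function(records, contigs = attr(records, "contigs", exact = TRUE)) {
  dt <- as.data.table(records)
  n <- nrow(dt)
  out <- list()
  add <- function(rows, code, msg) {
    if (length(rows)) {
      out[[length(out) + 1L]] <<- data.table(
        row = rows, code = code,
        message = sprintf(msg, rows)
      )
    }
  }
  add(which(!is.na(dt$pos) & dt$pos < 1L), "POSITION_NOT_ONE_BASED",
      "row %d: base position must start at one")
  add(which(is.na(dt$pos)), "POSITION_MISSING", "row %d: position missing")
  bad_allele <- which(!allele_ok(dt$ref) | !allele_ok(dt$alt))
  add(bad_allele, "ALLELE_INVALID_CHARS",
      "row %d: alleles must be non-empty strings over A/C/G/T")
  same <- which(allele_ok(dt$ref) & allele_ok(dt$alt) & dt$ref == dt$alt)
  add(same, "ALLELES_IDENTICAL", "row %d: REF and ALT alleles are identical")
  add(which(!is.na(dt$af) & (dt$af < 0 | dt$af > 1)), "AF_OUT_OF_RANGE",
      "row %d: site allele frequency outside [0,1]")
  if ("eaf" %in% names(dt)) {
    add(which(!is.na(dt$eaf) & (dt$eaf < 0 | dt$eaf > 1)), "AF_OUT_OF_RANGE",
        "row %d: effect-allele frequency outside [0,1]")
  }
  if ("lp" %in% names(dt)) {
    add(which(!is.na(dt$lp) & dt$lp < 0), "LP_NEGATIVE",
        "row %d: LP (-log10 P) must be >= 0")
  }
  if ("se" %in% names(dt)) {
    add(which(!is.na(dt$se) & dt$se <= 0), "SE_NOT_POSITIVE",
        "row %d: standard error must be > 0 when present")
  }
  add(which(!is.na(dt$rsid) & !grepl("^rs[0-9]+$", dt$rsid)), "RSID_MALFORMED",
      "row %d: rsid does not match rs[0-9]+")
  if (!is.null(contigs)) {
    ct <- as.data.table(contigs)
    idx <- match(dt$chrom, ct$name)
    add(which(is.na(idx)), "CONTIG_UNDECLARED",
        "row %d: chromosome is not a declared contig")
    over <- which(!is.na(idx) & !is.na(dt$pos) & dt$pos > ct$length[idx])
    add(over, "POSITION_EXCEEDS_CONTIG",
        "row %d: position exceeds declared contig length")
  }
  if (!length(out)) {
    return(data.table(row = integer(), code = character(), message = character()))
  }
  res <- rbindlist(out)
  setorderv(res, c("row", "code"))
  res[]
}

#' Report duplicated variant identifiers
#'
#' The VCF ID column must be unique across the file body: a non-null
#' identifier may appear in at most one row. Null identifiers (`NA` / ".")
#' are exempt and never reported.
#'
#' @param ids character vector of identifiers (or a records table, in which
#'   case the `id` column of its unique variants is used).
#' @return character vector of identifiers occurring two or more times.
#' @export
check_id_uniqueness <- function(ids) {
  if (is.data.frame(ids)) {
    dt <- unique(as.data.table(ids)[, c("chrom", "pos", "ref", "alt", "id")])
    ids <- dt$id
  }
  ids <- as.character(ids)
  ids <- ids[!is.na(ids) & ids != "."]
  sort(unique(ids[duplicated(ids)]))
}
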