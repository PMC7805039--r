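# Tabular export for tools that do not read VCF.

EXPORT_FIELDS <- c(
  "chromosome", "base_pair_location", "variant_id", "rsid",
  "effect_allele", "other_allele", "beta", "standard_error",
  "p_value", "neg_log_10_p_value", "effect_allele_frequency", "n", "trait"
)

GWAS_CATALOG_SPEC <- c(
  "chromosome", "base_pair_location", "effect_allele", "other_allele",
  "beta", "standard_error", "p_value", "effect_allele_frequency", "rsid"
)

#' Export records to a delimited table
#'
#' Projects records onto standardised column names. The named spec
#' `"gwascatalog"` follows the NHGRI-EBI GWAS Catalog summary-statistics
#' headings (chromosome, base_pair_location, effect_allele, other_allele,
#' beta, standard_error, p_value, effect_allele_frequency, rsid); any subset
#' of the available fields can be requested instead. The effect allele is
#' ALT and the other (non-effect) allele is REF; P values are recomputed on
#' demand from the stored LP.
#'
#' @param records a record table, or a path to a GWAS-VCF file.
#' @param path optional output file (TSV, written with [data.table::fwrite]).
#' @param spec `"gwascatalog"` or a character vector of field names from:
#'   chromosome, base_pair_location, variant_id, rsid, effect_allele,
#'   other_allele, beta, standard_error, p_value, neg_log_10_p_value,
#'   effect_allele_frequency, n, trait.
#' @param layout `"long"` (one row per variant x trait, with a `trait`
#'   column when several traits are present) or `"wide"` (one row per
#'   variant; per-trait statistics columns suffixed `_<trait>`).
#' @return the exported data.table (invisibly when `path` is given).
#' @export
export_tsv <- function(records, path = NULL, spec = "gwascatalog",
                       layout = c("long", "wide")) {
  layout <- match.arg(layout)
  if (is.character(records) && length(records) == 1L) {
    records <- read_gwasvcf(records)
  }
  dt <- as.data.table(records)
  dt <- dt[!(is.na(es) & is.na(se) & is.na(lp) & is.na(eaf) & is.na(ss))]
  if (identical(spec, "gwascatalog")) spec <- GWAS_CATALOG_SPEC
  bad <- setdiff(spec, EXPORT_FIELDS)
  if (length(bad)) {
    stop("unknown export field(s): ", paste(bad, collapse = ", "),
         "\n  available: ", paste(EXPORT_FIELDS, collapse = ", "),
         call. = FALSE)
  }
  long <- data.table(
    chromosome = dt$chrom, base_pair_location = dt$pos,
    variant_id = dt$id, rsid = dt$rsid,
    effect_allele = dt$alt, other_allele = dt$ref,
    beta = dt$es, standard_error = dt$se,
    p_value = p_from_lp(dt$lp), neg_log_10_p_value = dt$lp,
    effect_allele_frequency = dt$eaf, n = dt$ss, trait = dt$trait
  )
  traits <- unique(long$trait)
  if (layout == "long") {
    cols <- spec
    if (length(traits) > 1L && !"trait" %in% cols) cols <- c(cols, "trait")
    out <- long[, cols, with = FALSE]
  } else {
    site_cols <- intersect(spec, c("chromosome", "base_pair_location",
                                   "variant_id", "rsid", "effect_allele",
                                   "other_allele"))
    stat_cols <- intersect(spec, c("beta", "standard_error", "p_value",
                                   "neg_log_10_p_value",
                                   "effect_allele_frequency", "n"))
    out <- data.table::dcast(
      long, chromosome + base_pair_location + variant_id + rsid +
        effect_allele + other_allele ~ trait,
      value.var = stat_cols
    )
    if (length(traits) == 1L && length(stat_cols) > 1L) {
      # dcast drops the value-variable prefix when a single value var is used;
      # normalise names to <stat>_<trait> in all cases
      setnames(out, as.character(traits), paste0(stat_cols[1L], "_", traits),
               skip_absent = TRUE)
    }
    out <- out[, c(site_cols, setdiff(names(out), EXPORT_FIELDS)), with = FALSE]
  }
  if (!is.null(path)) {
    fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
    return(invisible(out))
  }
  out[]
}
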