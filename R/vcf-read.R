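# Reading GWAS-VCF back into the long-form record table.

unquote_meta <- function(x) sub('^"(.*)"$', "\\1", x)

# split a structured meta line value "<ID=x,length=1,...>" into a named vector
parse_structured <- function(x) {
  inner <- sub("^<", "", sub(">$", "", x))
  # split on commas not inside quotes
  parts <- regmatches(inner, gregexpr('[A-Za-z_]+=(?:"[^"]*"|[^,]*)', inner))[[1]]
  kv <- sub("=.*$", "", parts)
  vv <- unquote_meta(sub("^[A-Za-z_]+=", "", parts))
  stats::setNames(vv, kv)
}

#' Read the header of a GWAS-VCF file
#'
#' @param path a (BGZF- or GZIP-compressed, or plain) VCF file.
#' @return list with `lines` (raw header lines), `samples` (trait ids),
#'   `contigs` (data.table `name`, `length`), `assembly`, `traits` (named
#'   list of [study_metadata()] recovered from SAMPLE lines), and
#'   `format_ids` (declared FORMAT field ids).
#' @export
read_vcf_header <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con), add = TRUE)
  lines <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) stop("no #CHROM line found in ", path, call. = FALSE)
    lines <- c(lines, ln)
    if (startsWith(ln, "#CHROM")) break
    if (!startsWith(ln, "#")) stop("malformed header in ", path, call. = FALSE)
  }
  chrom_line <- strsplit(lines[length(lines)], "\t", fixed = TRUE)[[1]]
  if (length(chrom_line) < 10L || chrom_line[9L] != "FORMAT") {
    stop("GWAS-VCF requires FORMAT and at least one trait column", call. = FALSE)
  }
  samples <- chrom_line[10:length(chrom_line)]

  ctg <- lines[startsWith(lines, "##contig=")]
  contigs <- rbindlist(lapply(ctg, function(l) {
    kv <- parse_structured(sub("^##contig=", "", l))
    data.table(name = kv[["ID"]], length = as.integer(kv[["length"]]))
  }))
  assembly <- NA_character_
  al <- lines[startsWith(lines, "##genome_assembly=")]
  if (length(al)) assembly <- sub("^##genome_assembly=", "", al[1L])

  smp <- lines[startsWith(lines, "##SAMPLE=")]
  traits <- list()
  for (l in smp) {
    kv <- parse_structured(sub("^##SAMPLE=", "", l))
    g <- function(k) if (k %in% names(kv)) kv[[k]] else NA_character_
    md <- study_metadata(
      trait_id = kv[["ID"]], trait_label = g("TraitLabel"),
      trait_ontology = g("TraitOntology"), study_id = g("StudyID"),
      sample_size = if ("TotalSamples" %in% names(kv))
        as.integer(kv[["TotalSamples"]]) else NA_integer_,
      ancestry = g("Ancestry"), units = g("Units"),
      association_test = g("AssociationTest"),
      source_file = g("SourceFile"),
      file_date = g("FileDate")
    )
    traits[[kv[["ID"]]]] <- md
  }
  for (s in samples) {
    if (is.null(traits[[s]])) traits[[s]] <- study_metadata(trait_id = s)
  }
  traits <- traits[samples]

  fmt <- lines[startsWith(lines, "##FORMAT=")]
  format_ids <- vapply(fmt, function(l)
    parse_structured(sub("^##FORMAT=", "", l))[["ID"]], character(1),
    USE.NAMES = FALSE)

  list(lines = lines, samples = samples, contigs = contigs,
       assembly = assembly, traits = traits, format_ids = format_ids)
}

info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexpr(pat, info, perl = TRUE))
  out <- rep(NA_character_, length(info))
  hit <- grepl(pat, info, perl = TRUE)
  out[hit] <- sub(pat, "\\1", m, perl = TRUE)
  out
}

dot_na_num <- function(x) {
  x[x == "."] <- NA_character_
  as.numeric(x)
}

#' Parse GWAS-VCF body lines into long-form records
#'
#' One output row per (variant, trait). A sample cell of "." or with every
#' field "." yields a row whose statistics are all `NA` (the trait is absent
#' at that variant but the grid row is kept; see [records_for_trait()]).
#'
#' @param lines character vector of body lines (no "#" lines).
#' @param samples trait/sample column ids, in column order.
#' @return data.table in [gwas_records()] long form.
#' @export
parse_vcf_body <- function(lines, samples) {
  if (!length(lines)) {
    return(gwas_records(data.table(chrom = character(), pos = integer(),
                                   ref = character(), alt = character(),
                                   trait = character())))
  }
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  if (length(f) != 9L + length(samples)) {
    stop(sprintf("body has %d columns, header declares %d",
                 length(f), 9L + length(samples)), call. = FALSE)
  }
  base <- data.table(
    chrom = f[[1]], pos = as.integer(f[[2]]),
    id = ifelse(f[[3]] == ".", NA_character_, f[[3]]),
    ref = f[[4]], alt = f[[5]],
    qual = dot_na_num(f[[6]]),
    filter = ifelse(f[[7]] %in% c(".", "PASS"), NA_character_, f[[7]]),
    af = dot_na_num(info_field(f[[8]], "AF")),
    rsid = info_field(f[[8]], "RSID"),
    format = f[[9]]
  )
  out <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    cells <- f[[9L + si]]
    rows <- copy(base)[, format := NULL]
    rows[, trait := samples[si]]
    rows[, c("es", "se", "lp", "eaf") := NA_real_]
    rows[, ss := NA_integer_]
    for (fstr in unique(base$format)) {
      sel <- which(base$format == fstr)
      ids <- strsplit(fstr, ":", fixed = TRUE)[[1]]
      vals <- data.table::tstrsplit(cells[sel], ":", fixed = TRUE)
      length(vals) <- length(ids)   # short cells (e.g. ".") pad with NULL -> NA
      for (j in seq_along(ids)) {
        v <- if (is.null(vals[[j]])) rep(".", length(sel)) else vals[[j]]
        v[is.na(v)] <- "."
        col <- switch(ids[j], ES = "es", SE = "se", LP = "lp",
                      AF = "eaf", SS = "ss", NULL)
        if (is.null(col)) next
        if (col == "ss") {
          rows[sel, ss := as.integer(suppressWarnings(dot_na_num(v)))]
        } else {
          rows[sel, (col) := dot_na_num(v)]
        }
      }
    }
    out[[si]] <- rows
  }
  rbindlist(out)
}

#' Read a GWAS-VCF file into records
#'
#' @param path GWAS-VCF file (BGZF-compressed or plain).
#' @return a [gwas_records()] table with header metadata in its attributes.
#' @export
read_gwasvcf <- function(path) {
  hdr <- read_vcf_header(path)
  all_lines <- readLines(gzfile(path))
  body <- all_lines[!startsWith(all_lines, "#")]
  recs <- parse_vcf_body(body, hdr$samples)
  gwas_records(recs, traits = hdr$traits, contigs = hdr$contigs,
               assembly = hdr$assembly)
}

#' Extract one trait's records from a multi-trait table
#'
#' Drops grid rows where the trait has no data at the variant (all of
#' `es, se, lp, eaf, ss` missing).
#'
#' @param records long-form record table.
#' @param trait_id trait to extract.
#' @return records for that trait only.
#' @export
records_for_trait <- function(records, trait_id) {
  dt <- as.data.table(records)[trait == trait_id]
  dt[!(is.na(es) & is.na(se) & is.na(lp) & is.na(eaf) & is.na(ss))]
}
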