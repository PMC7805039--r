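# Allele harmonisation and indel normalisation.
#
# Harmonisation makes the non-effect allele equal the reference-genome
# sequence at the variant position, so effect directionality is consistent
# across studies: if the input's *effect* allele is the one matching the
# reference, the alleles are swapped, the effect size negated and every
# allele frequency complemented. Alleles are assumed to be reported on the
# forward strand; records whose alleles would match only after
# reverse-complement are reported as incompatible with a distinguishing
# message, never silently strand-flipped (palindromic A/T and C/G variants
# make strand inference unsafe).

HARMONISE_STATUSES <- c("unchanged", "swapped", "incompatible", "not_in_reference")

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, "", fixed = TRUE), function(s)
    paste(rev(s), collapse = ""), character(1)))
}

#' Harmonise candidate records against a reference genome
#'
#' For each candidate (input orientation: `other` = non-effect allele,
#' `effect` = effect allele) the reference sequence at `pos` is compared to
#' both alleles:
#' \itemize{
#'   \item non-effect allele matches the reference: `unchanged`;
#'     `REF = other`, `ALT = effect`.
#'   \item effect allele matches the reference: `swapped`; alleles exchanged,
#'     `es := -es`, site and per-trait allele frequencies `:= 1 - af`.
#'   \item neither matches: `incompatible` (the detail message notes when a
#'     reverse-complement match exists, but no strand flip is performed).
#'   \item chromosome or position absent from the reference:
#'     `not_in_reference`.
#' }
#' Harmonisation is idempotent: re-running it on its own output yields
#' `unchanged` for every record.
#'
#' @param candidates data.table from [read_sumstats()] (columns `chrom, pos,
#'   other, effect, es, se, lp, af, ss, rsid, ident, trait`).
#' @param ref a reference genome ([ref_fasta()] / [ref_memory()]).
#' @return data.table of records (columns as in [gwas_records()]) plus
#'   `status` and `detail`. All input rows are returned; filtering of
#'   `incompatible` / `not_in_reference` records is the caller's choice
#'   (see `keep_incompatible` in [convert_sumstats()]).
#' @export
harmonize_records <- function(candidates, ref) {
  dt <- as.data.table(candidates)
  n <- nrow(dt)
  contigs <- ref_contigs(ref)
  clen <- contigs$length[match(dt$chrom, contigs$name)]
  in_ref <- !is.na(clen) & !is.na(dt$pos) & dt$pos >= 1L & dt$pos <= clen

  o_len <- nchar(dt$other)
  e_len <- nchar(dt$effect)
  seq_o <- ref_fetch_safe(ref, dt$chrom, dt$pos, dt$pos + o_len - 1L)
  seq_e <- ref_fetch_safe(ref, dt$chrom, dt$pos, dt$pos + e_len - 1L)

  match_o <- !is.na(seq_o) & seq_o == dt$other
  match_e <- !is.na(seq_e) & seq_e == dt$effect

  status <- rep("incompatible", n)
  status[!in_ref] <- "not_in_reference"
  status[in_ref & match_o] <- "unchanged"
  status[in_ref & !match_o & match_e] <- "swapped"

  detail <- rep("non-effect allele matches reference", n)
  detail[status == "swapped"] <-
    "effect allele matched reference; alleles swapped, ES negated, AF complemented"
  detail[status == "not_in_reference"] <-
    "chromosome/position not present in the reference genome"
  inc <- which(status == "incompatible")
  if (length(inc)) {
    rc_o <- revcomp(dt$other[inc])
    rc_e <- revcomp(dt$effect[inc])
    rc_hit <- (!is.na(seq_o[inc]) & seq_o[inc] == rc_o) |
              (!is.na(seq_e[inc]) & seq_e[inc] == rc_e)
    detail[inc] <- ifelse(rc_hit,
      "alleles match the reference only after reverse-complement; forward-strand rule applied, record not flipped",
      "neither allele matches the reference sequence")
  }

  sw <- status == "swapped"
  out <- data.table(
    chrom = dt$chrom, pos = dt$pos,
    id = dt$ident,
    ref = ifelse(sw, dt$effect, dt$other),
    alt = ifelse(sw, dt$other, dt$effect),
    qual = NA_real_, filter = NA_character_,
    af = ifelse(sw, 1 - dt$af, dt$af),
    rsid = dt$rsid, trait = dt$trait,
    es = ifelse(sw, -dt$es, dt$es),
    se = dt$se, lp = dt$lp,
    eaf = ifelse(sw, 1 - dt$af, dt$af),
    ss = dt$ss,
    status = status, detail = detail
  )
  if ("line" %in% names(dt)) out[, line := dt$line]
  out[]
}

#' Left-align and trim an indel to its canonical spelling
#'
#' The same insertion or deletion can be written at many positions inside a
#' repeat tract. The canonical form is the unique leftmost, minimal
#' representation, reached by iterating: (1) while both alleles end with the
#' same base, drop it, first extending both alleles leftward with the
#' reference base at `pos - 1` whenever a drop would empty an allele;
#' (2) once the final bases differ, trim shared leading bases (keeping both
#' alleles length >= 1), incrementing `pos`. Applying the returned spelling
#' to the reference yields a haplotype identical to the input spelling's.
#' SNVs are fixed points.
#'
#' Precondition: `ref_allele` equals the reference sequence at
#' `pos .. pos + nchar(ref_allele) - 1` (run after [harmonize_records()]).
#'
#' @param chrom chromosome name.
#' @param pos 1-based position of the first reference base of the spelling.
#' @param ref_allele,alt_allele allele strings (uppercase A/C/G/T).
#' @param ref reference genome object.
#' @return list `(pos, ref, alt)` with the canonical spelling.
#' @section Errors: a variant whose left-extension reaches the start of the
#'   contig cannot be anchored; a condition of class
#'   `gwasvcfkit_normalize_error` is signalled.
#' @export
normalize_variant <- function(chrom, pos, ref_allele, alt_allele, ref) {
  r <- ref_allele; a <- alt_allele
  if (ref_fetch(ref, chrom, pos, pos + nchar(r) - 1L) != r) {
    stop("normalize_variant: ref allele does not match reference at ",
         chrom, ":", pos, call. = FALSE)
  }
  repeat {
    rl <- nchar(r); al <- nchar(a)
    if (substr(r, rl, rl) != substr(a, al, al)) break
    if (rl == 1L || al == 1L) {
      if (pos == 1L) {
        stop(structure(class = c("gwasvcfkit_normalize_error", "error", "condition"),
                       list(message = sprintf(
                         "variant at %s:%d cannot be left-anchored (contig start reached)",
                         chrom, pos), call = NULL)))
      }
      b <- ref_fetch(ref, chrom, pos - 1L, pos - 1L)
      r <- paste0(b, r); a <- paste0(b, a)
      pos <- pos - 1L
      rl <- rl + 1L; al <- al + 1L
    }
    r <- substr(r, 1L, rl - 1L); a <- substr(a, 1L, al - 1L)
  }
  while (nchar(r) >= 2L && nchar(a) >= 2L && substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
    r <- substr(r, 2L, nchar(r)); a <- substr(a, 2L, nchar(a))
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = r, alt = a)
}

#' Normalise every indel record in a table
#'
#' Applies [normalize_variant()] to each record whose alleles are not both
#' single bases. Records that cannot be anchored (contig start) get
#' `status = "normalize_failed"`.
#'
#' @param records record table (post-harmonisation; `ref` column matches the
#'   reference).
#' @param ref reference genome object.
#' @return the table with `pos`, `ref`, `alt` canonicalised (and `status`
#'   updated on failure).
#' @export
normalize_records <- function(records, ref) {
  dt <- as.data.table(records)
  if (!"status" %in% names(dt)) dt[, status := "unchanged"]
  todo <- which((nchar(dt$ref) > 1L | nchar(dt$alt) > 1L) &
                  dt$status %in% c("unchanged", "swapped"))
  for (i in todo) {
    res <- tryCatch(
      normalize_variant(dt$chrom[i], dt$pos[i], dt$ref[i], dt$alt[i], ref),
      gwasvcfkit_normalize_error = function(e) e
    )
    if (inherits(res, "condition")) {
      dt[i, `:=`(status = "normalize_failed", detail = conditionMessage(res))]
    } else {
      dt[i, `:=`(pos = res$pos, ref = res$ref, alt = res$alt)]
    }
  }
  dt[]
}

#' Enumerate all equivalent spellings of a variant within a window
#'
#' Brute-force enumeration: the edit is applied to the reference inside a
#' window of `flank` bases around the variant, and every `(pos, ref, alt)`
#' triple whose substitution reproduces the identical edited haplotype is
#' returned. Used by the synthetic-data generator to emit non-canonical
#' indel spellings, and as an independent check of [normalize_variant()]
#' (the canonical spelling is the one minimising total allele length, then
#' position).
#'
#' @param ref reference genome object.
#' @param chrom,pos,ref_allele,alt_allele the variant (any valid spelling).
#' @param flank window half-width in bases; must exceed the repeat-tract
#'   length around the variant for the enumeration to be exhaustive.
#' @return data.table with columns `pos`, `ref`, `alt`, one row per spelling
#'   (the input spelling included).
#' @export
enumerate_spellings <- function(ref, chrom, pos, ref_allele, alt_allele,
                                flank = 16L) {
  clen <- ref_contigs(ref)[name == chrom, length]
  if (!length(clen)) stop("unknown contig: ", chrom, call. = FALSE)
  ws <- max(1L, pos - flank)
  we <- min(clen, pos + nchar(ref_allele) - 1L + flank)
  W <- ref_fetch(ref, chrom, ws, we)
  p0 <- pos - ws + 1L
  if (substr(W, p0, p0 + nchar(ref_allele) - 1L) != ref_allele) {
    stop("ref allele does not match reference at ", chrom, ":", pos,
         call. = FALSE)
  }
  H <- paste0(substr(W, 1L, p0 - 1L), alt_allele,
              substr(W, p0 + nchar(ref_allele), nchar(W)))
  L <- nchar(W); LH <- nchar(H)
  # common prefix/suffix lengths of W and H (byte-wise)
  wc <- charToRaw(W); hc <- charToRaw(H)
  m <- min(L, LH)
  eqp <- wc[seq_len(m)] == hc[seq_len(m)]
  cpl <- if (all(eqp)) m else which(!eqp)[1L] - 1L
  eqs <- rev(wc)[seq_len(m)] == rev(hc)[seq_len(m)]
  csl <- if (all(eqs)) m else which(!eqs)[1L] - 1L

  # a spelling exists for every (start p, shared suffix length s) pair whose
  # implied allele lengths are positive; distinct pairs give distinct triples
  np <- min(cpl + 1L, L)
  p <- rep(seq_len(np), each = csl + 1L)
  s <- rep(0:csl, times = np)
  rl <- L - p + 1L - s
  al <- LH - p + 1L - s
  ok <- rl >= 1L & al >= 1L
  p <- p[ok]; rl <- rl[ok]; al <- al[ok]
  data.table(pos = ws + p - 1L,
             ref = substring(W, p, p + rl - 1L),
             alt = substring(H, p, p + al - 1L))
}

# canonical = minimal total allele length, then leftmost position
spelling_canonical <- function(spellings) {
  sp <- as.data.table(spellings)
  sp[order(nchar(ref) + nchar(alt), pos)][1L]
}

#' Split a multiallelic site into biallelic records
#'
#' GWAS-VCF stores each variant in its own row: a locus observed with k
#' alternative alleles becomes k records sharing `chrom`, `pos` and `ref`,
#' each carrying the statistics of its own alternative allele. The
#' site-level rsid (a locus identifier) is copied to every record.
#'
#' @param chrom,pos,ref_allele the shared locus.
#' @param alt_alleles character vector of k alternative alleles.
#' @param stats data.frame with k rows of per-alt statistics (any of
#'   `es, se, lp, af, eaf, ss, trait`).
#' @param rsid site rsid or `NA`.
#' @return data.table of k records (normalise each afterwards; different
#'   alts of one site may canonicalise to different positions).
#' @export
split_multiallelic <- function(chrom, pos, ref_allele, alt_alleles, stats,
                               rsid = NA_character_) {
  k <- length(alt_alleles)
  stats <- as.data.table(stats)
  if (nrow(stats) != k) {
    stop(sprintf("site %s:%d has %d alt alleles but %d statistics rows",
                 chrom, pos, k, nrow(stats)), call. = FALSE)
  }
  base <- data.table(chrom = chrom, pos = as.integer(pos),
                     id = NA_character_, ref = ref_allele,
                     alt = alt_alleles, qual = NA_real_,
                     filter = NA_character_, af = NA_real_,
                     rsid = rsid)
  for (cl in c("es", "se", "lp", "eaf", "ss", "af", "trait")) {
    if (cl %in% names(stats)) base[, (cl) := stats[[cl]]]
  }
  if (!"trait" %in% names(stats)) base[, trait := "trait_1"]
  base[]
}

#' Sort records karyotypically
#'
#' Orders records by header contig order, then ascending position, then
#' `ref`, `alt` as deterministic tiebreak; the sort is stable for fully
#' equal keys. This is the order required before writing and tabix-indexing.
#'
#' @param records record table.
#' @param contigs data.frame `name`, `length`; row order defines contig rank.
#' @return the sorted table (attributes preserved).
#' @export
sort_karyotypic <- function(records, contigs = attr(records, "contigs", exact = TRUE)) {
  if (is.null(contigs)) stop("sort_karyotypic: no contig list supplied", call. = FALSE)
  ct <- as.data.table(contigs)
  dt <- as.data.table(records)
  rank <- match(dt$chrom, ct$name)
  if (anyNA(rank)) {
    stop("undeclared contig(s): ",
         paste(unique(dt$chrom[is.na(rank)]), collapse = ", "), call. = FALSE)
  }
  dt[, rank__ := rank]
  setorderv(dt, c("rank__", "pos", "ref", "alt"))
  dt[, rank__ := NULL]
  for (at in c("traits", "contigs", "assembly")) {
    a <- attr(records, at, exact = TRUE)
    if (!is.null(a)) setattr(dt, at, a)
  }
  if (inherits(records, "gwas_records")) {
    setattr(dt, "class", c("gwas_records", class(dt)))
  }
  dt[]
}

#' Annotate records with rsids from a lookup table
#'
#' Fills missing `rsid` values by joining on `(chrom, pos)` against a
#' dbSNP-style mapping: either a 3-column TSV (`rsid`, `chrom`, `pos`) or a
#' VCF whose ID column carries rsids.
#'
#' @param records record table.
#' @param mapping path to the mapping file, or a data.frame with columns
#'   `rsid`, `chrom`, `pos`.
#' @return the table with `rsid` filled where the mapping has the locus.
#' @export
annotate_rsids <- function(records, mapping) {
  if (is.character(mapping)) {
    if (grepl("\\.vcf(\\.gz)?$", mapping)) {
      lines <- readLines(gzfile(mapping))
      lines <- lines[!startsWith(lines, "#")]
      parts <- data.table::tstrsplit(lines, "\t", fixed = TRUE, keep = 1:3)
      mapping <- data.table(chrom = parts[[1]],
                            pos = as.integer(parts[[2]]),
                            rsid = parts[[3]])
    } else {
      mapping <- fread(mapping, header = TRUE)
    }
  }
  map <- as.data.table(mapping)[, .(chrom = as.character(chrom),
                                    pos = as.integer(pos),
                                    rsid_new = rsid)]
  map <- map[grepl("^rs[0-9]+$", rsid_new)]
  dt <- as.data.table(records)
  dt[map, on = c("chrom", "pos"),
     rsid := ifelse(is.na(rsid), i.rsid_new, rsid)]
  dt[]
}
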