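# Reading tabular summary statistics under a user-defined schema.
#
# Contract: every input row yields exactly one of {candidate emitted, issue
# logged}; rows are never silently dropped and never reordered (sorting is
# the writer's job). Only structural failures reject a row -- unparseable
# numbers, invalid alleles, out-of-range P or AF; a declared missing token in
# an optional field passes through as NA.

#' Read summary statistics into harmonisation candidates
#'
#' Parses a delimited text file (plain or GZIP-compressed) under a
#' [load_schema()] mapping and returns one candidate per parseable row.
#' Candidates keep the input's effect/other allele orientation; matching the
#' non-effect allele to the reference genome is [harmonize_records()]'s job.
#' P values are converted to `lp = -log10(P)` at ingest ([lp_from_p()]);
#' odds ratios, if mapped instead of effect sizes, are stored as `log(OR)`.
#'
#' @param path input file (TSV/CSV, optionally `.gz`).
#' @param schema a `gwas_schema` from [load_schema()], or anything
#'   [load_schema()] accepts (a JSON path or a list).
#' @param trait_id trait identifier attached to every candidate.
#' @return list with elements
#'   \describe{
#'     \item{candidates}{data.table: `chrom, pos, other, effect, es, se, lp,
#'       af, ss, rsid, ident, line` (line = input line number).}
#'     \item{issues}{data.table of rejected rows: `line, reason`.}
#'     \item{counts}{list `read`, `emitted`, `rejected`, `p_underflow`,
#'       `rsid_dropped`.}
#'   }
#' @export
read_sumstats <- function(path, schema, trait_id = "trait_1") {
  if (!inherits(schema, "gwas_schema")) schema <- load_schema(schema)
  con <- gzfile(path, "rt")
  on.exit(close(con), add = TRUE)
  lines <- tryCatch(readLines(con), error = function(e) {
    stop("cannot decode input stream: ", conditionMessage(e), call. = FALSE)
  })
  if (!length(lines)) stop("input file is empty: ", path, call. = FALSE)

  raw <- fread(text = lines, sep = schema$delimiter,
               header = schema$header_row, colClasses = "character",
               na.strings = NULL, quote = "", fill = TRUE,
               blank.lines.skip = FALSE, showProgress = FALSE)
  n <- nrow(raw)
  first_line <- if (schema$header_row) 2L else 1L
  line_no <- seq_len(n) + first_line - 1L

  getcol <- function(field) {
    src <- schema$columns[[field]]
    if (is.null(src)) return(NULL)
    if (is.numeric(src)) {
      src <- as.integer(src)
      if (src < 1L || src > ncol(raw)) {
        stop(sprintf("schema maps '%s' to column %d but input has %d columns",
                     field, src, ncol(raw)), call. = FALSE)
      }
      return(raw[[src]])
    }
    if (!schema$header_row) {
      stop(sprintf("schema maps '%s' by header name '%s' but header_row is false",
                   field, src), call. = FALSE)
    }
    if (!src %in% names(raw)) {
      stop(sprintf("schema maps '%s' to column '%s', absent from the header (%s)",
                   field, src, paste(names(raw), collapse = ", ")),
           call. = FALSE)
    }
    raw[[src]]
  }

  miss <- schema$missing_values
  as_missing <- function(v) {
    if (is.null(v)) return(NULL)
    v[v %in% miss] <- NA_character_
    v
  }
  num <- function(v) suppressWarnings(as.numeric(v))

  chrom  <- as_missing(getcol("chrom"))
  pos_c  <- as_missing(getcol("pos"))
  eff    <- toupper(as_missing(getcol("effect_allele")))
  oth    <- toupper(as_missing(getcol("other_allele")))
  es_c   <- as_missing(getcol("es"))
  or_c   <- as_missing(getcol("or"))
  se_c   <- as_missing(getcol("se"))
  p_c    <- as_missing(getcol("p"))
  lp_c   <- as_missing(getcol("lp"))
  af_c   <- as_missing(getcol("af"))
  ss_c   <- as_missing(getcol("ss"))
  rsid   <- as_missing(getcol("rsid"))
  ident  <- as_missing(getcol("ident"))

  reason <- rep(NA_character_, n)
  flag <- function(cond, msg) {
    hit <- which(is.na(reason) & cond)
    reason[hit] <<- msg
    invisible()
  }

  pos <- suppressWarnings(as.integer(pos_c))
  flag(is.na(chrom), "CHROM_MISSING")
  flag(is.na(pos_c), "POS_MISSING")
  flag(!is.na(pos_c) & (is.na(pos) | as.character(pos) != sub("^\\+", "", pos_c)),
       "POS_NOT_INTEGER")
  if (schema$position_base == 0L) pos <- pos + 1L
  flag(!is.na(pos) & pos < 1L, "POSITION_NOT_ONE_BASED")

  flag(is.na(eff) | is.na(oth), "ALLELE_MISSING")
  flag(!is.na(eff) & !allele_ok(eff), "ALLELE_INVALID_CHARS")
  flag(!is.na(oth) & !allele_ok(oth), "ALLELE_INVALID_CHARS")
  flag(!is.na(eff) & !is.na(oth) & eff == oth, "ALLELES_IDENTICAL")

  es <- num(es_c)
  flag(!is.na(es_c) & is.na(es), "ES_NOT_NUMERIC")
  if (!is.null(or_c)) {
    or <- num(or_c)
    flag(!is.na(or_c) & is.na(or), "OR_NOT_NUMERIC")
    flag(!is.na(or) & or <= 0, "OR_NOT_POSITIVE")
    es <- suppressWarnings(log(or))
    es[!is.na(or) & or <= 0] <- NA_real_
  }

  se <- num(se_c)
  flag(!is.na(se_c) & is.na(se), "SE_NOT_NUMERIC")
  flag(!is.na(se) & se <= 0, "SE_NOT_POSITIVE")

  p <- num(p_c)
  flag(!is.na(p_c) & is.na(p), "P_NOT_NUMERIC")
  flag(!is.na(p) & (p < 0 | p > 1), "P_OUT_OF_RANGE")
  p_underflow <- sum(!is.na(p) & p == 0 & is.na(reason))
  lp <- rep(NA_real_, n)
  ok_p <- !is.na(p) & p >= 0 & p <= 1
  if (any(ok_p)) {
    lp[ok_p] <- suppressWarnings(lp_from_p(p[ok_p]))
  }
  if (!is.null(lp_c)) {
    lp_in <- num(lp_c)
    flag(!is.na(lp_c) & is.na(lp_in), "LP_NOT_NUMERIC")
    flag(!is.na(lp_in) & lp_in < 0, "LP_NEGATIVE")
    both <- !is.na(lp) & !is.na(lp_in)
    # p and lp are mutually convertible; reject rows where the two disagree
    flag(both & abs(lp - lp_in) > 1e-4 * pmax(1, abs(lp_in)),
         "P_LP_INCONSISTENT")
    lp[is.na(lp)] <- lp_in[is.na(lp)]
  }

  af <- num(af_c)
  flag(!is.na(af_c) & is.na(af), "AF_NOT_NUMERIC")
  flag(!is.na(af) & (af < 0 | af > 1), "AF_OUT_OF_RANGE")
  ss <- suppressWarnings(as.integer(num(ss_c)))
  flag(!is.na(ss_c) & is.na(ss), "SS_NOT_NUMERIC")
  flag(!is.na(ss) & ss < 1L, "SS_NOT_POSITIVE")

  rsid_dropped <- 0L
  if (!is.null(rsid)) {
    bad_rs <- !is.na(rsid) & !grepl("^rs[0-9]+$", rsid)
    rsid_dropped <- sum(bad_rs & is.na(reason))
    rsid[bad_rs] <- NA_character_
  }

  keep <- is.na(reason)
  candidates <- data.table(
    chrom = chrom[keep], pos = pos[keep],
    other = oth[keep], effect = eff[keep],
    es = es[keep], se = se[keep], lp = lp[keep],
    af = af[keep],
    ss = if (is.null(ss_c)) rep(NA_integer_, sum(keep)) else ss[keep],
    rsid = if (is.null(rsid)) rep(NA_character_, sum(keep)) else rsid[keep],
    ident = if (is.null(ident)) rep(NA_character_, sum(keep)) else ident[keep],
    trait = trait_id,
    line = line_no[keep]
  )
  issues <- data.table(line = line_no[!keep], reason = reason[!keep])
  list(
    candidates = candidates,
    issues = issues,
    counts = list(read = n, emitted = nrow(candidates),
                  rejected = nrow(issues), p_underflow = p_underflow,
                  rsid_dropped = rsid_dropped)
  )
}
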