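# Deterministic synthetic data: reference genomes with repeat tracts, and
# summary-statistics tables with a ground-truth ledger, so every pipeline
# stage is testable without downloads. Same config + seed => identical bytes.

#' Configuration for the synthetic-data generator
#'
#' The generator emulates a dense, biobank-style summary-statistics table
#' (chromosome, position, two alleles, beta, SE, P, allele frequency, sample
#' size) with the real-world heterogeneity the converter must handle
#' injected at known rows: effect/other allele swaps (with the effect size
#' pre-negated and frequency complemented, so harmonisation must undo them),
#' non-left-aligned indel spellings, multiallelic sites, deliberately
#' incompatible alleles, malformed rows and missing values.
#'
#' Statistics are Wald-consistent: per row `se = |N(0, se_scale)| + se_min`,
#' `es = b + se * z` with `z ~ N(0,1)` and `b ~ N(0, es_sd)` for the
#' `signal_fraction` of rows carrying a true effect (default 0, the null
#' model), and `P = 2 * pnorm(-|es/se|)`. Under the default null, P values
#' are Uniform(0,1) and `lp` recomputation is internally consistent.
#'
#' @param seed integer seed; every random draw derives from it.
#' @param contig_lengths named integer vector of contig lengths (bases).
#' @param n_variants total number of variant sites, split across contigs in
#'   proportion to length.
#' @param n_traits number of traits (one summary-statistics table each, over
#'   the same variants).
#' @param indel_fraction fraction of sites that are 1-3 bp indels.
#' @param multiallelic_fraction fraction of SNV sites emitted with a second
#'   alternative allele (an extra table row sharing the locus and rsid).
#' @param swap_fraction fraction of SNV rows emitted with effect/other
#'   alleles exchanged and the effect size pre-negated (indels are never
#'   swap-injected: an indel's swapped orientation can coincide with a valid
#'   reference-matching variant, making recovery ill-defined).
#' @param respell_fraction fraction of indel rows emitted in a random
#'   non-canonical (right-shifted / padded) spelling.
#' @param corrupt_fraction fraction of rows made structurally malformed
#'   (invalid allele codes, non-numeric or zero positions, P > 1,
#'   non-numeric beta).
#' @param n_incompatible number of rows whose alleles both mismatch the
#'   reference (harmonisation must exclude or flag them).
#' @param missing_fraction named list of per-field missingness rates for the
#'   optional fields `p`, `se`, `af`, `ss`.
#' @param rsid_fraction fraction of sites assigned an rsid.
#' @param signal_fraction fraction of rows with a true nonzero effect.
#' @param es_sd standard deviation of true effects (trait units).
#' @param se_scale,se_min scale and floor of the standard-error distribution.
#' @param sample_size per-trait sample size reported in the N column.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              contig_lengths = c(`1` = 400000L, `2` = 250000L),
                              n_variants = 10000L,
                              n_traits = 1L,
                              indel_fraction = 0.1,
                              multiallelic_fraction = 0.02,
                              swap_fraction = 0.15,
                              respell_fraction = 0.5,
                              corrupt_fraction = 0.01,
                              n_incompatible = 0L,
                              missing_fraction = list(p = 0.01, se = 0.01,
                                                      af = 0.02, ss = 0.02),
                              rsid_fraction = 0.95,
                              signal_fraction = 0,
                              es_sd = 0.05,
                              se_scale = 0.02,
                              se_min = 0.005,
                              sample_size = 50000L) {
  fr <- c(indel_fraction, multiallelic_fraction, swap_fraction,
          respell_fraction, corrupt_fraction, rsid_fraction, signal_fraction,
          unlist(missing_fraction))
  stopifnot(all(fr >= 0 & fr <= 1), all(contig_lengths >= 50),
            n_variants >= 1, n_traits >= 1, n_incompatible >= 0)
  if (is.null(names(contig_lengths))) {
    names(contig_lengths) <- as.character(seq_along(contig_lengths))
  }
  structure(list(
    seed = as.integer(seed), contig_lengths = contig_lengths,
    n_variants = as.integer(n_variants), n_traits = as.integer(n_traits),
    indel_fraction = indel_fraction,
    multiallelic_fraction = multiallelic_fraction,
    swap_fraction = swap_fraction, respell_fraction = respell_fraction,
    corrupt_fraction = corrupt_fraction,
    n_incompatible = as.integer(n_incompatible),
    missing_fraction = missing_fraction, rsid_fraction = rsid_fraction,
    signal_fraction = signal_fraction, es_sd = es_sd,
    se_scale = se_scale, se_min = se_min,
    sample_size = as.integer(sample_size)
  ), class = "simulation_config")
}

BASES <- c("A", "C", "G", "T")

#' Generate a synthetic reference genome
#'
#' Random uppercase sequence per contig with planted repeat tracts
#' (homopolymers and dinucleotide repeats of 8-14 bases, roughly one per
#' 500 bp) that give indel normalisation real work to do. The tract
#' positions are returned so tests can assert against them.
#'
#' @param config a [simulation_config()].
#' @param dir optional directory; when given, `ref.fa` (+ `.fai`) is written
#'   there and a [ref_fasta()] handle returned alongside the in-memory one.
#' @return list: `ref` ([ref_memory()] object), `tracts` (data.table
#'   `chrom`, `start`, `end`, `motif`), `contigs`, and -- when `dir` is given
#'   -- `fasta` (path) and `ref_fa` ([ref_fasta()] handle).
#' @export
make_reference <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  seqs <- character(length(config$contig_lengths))
  names(seqs) <- names(config$contig_lengths)
  tracts <- list()
  for (ci in seq_along(config$contig_lengths)) {
    L <- as.integer(config$contig_lengths[ci])
    s <- sample(BASES, L, replace = TRUE)
    n_tracts <- max(1L, L %/% 500L)
    starts <- sort(sample.int(L - 20L, n_tracts))
    # drop overlapping tracts so each planted motif survives intact
    keep <- c(TRUE, diff(starts) > 20L)
    starts <- starts[keep]
    motifs <- character(length(starts))
    for (k in seq_along(starts)) {
      if (stats::runif(1) < 0.5) {
        motif <- sample(BASES, 1L)
        len <- sample(8:14, 1L)
        tract <- strsplit(strrep(motif, len), "")[[1]]
      } else {
        motif <- paste(sample(BASES, 2L), collapse = "")
        len <- 2L * sample(4:7, 1L)
        tract <- strsplit(strrep(motif, len %/% 2L), "")[[1]]
      }
      s[starts[k]:(starts[k] + length(tract) - 1L)] <- tract
      motifs[k] <- motif
    }
    tracts[[ci]] <- data.table(chrom = names(seqs)[ci], start = starts,
                               end = starts + 19L, motif = motifs)
    seqs[ci] <- paste(s, collapse = "")
  }
  out <- list(ref = ref_memory(seqs), tracts = rbindlist(tracts),
              contigs = data.table(name = names(seqs),
                                   length = nchar(seqs)))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fa <- file.path(dir, "ref.fa")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fa, width = 70L)
    Rsamtools::indexFa(fa)
    out$fasta <- fa
    out$ref_fa <- ref_fasta(fa)
  }
  out
}

#' Simulate summary-statistics tables with a ground-truth ledger
#'
#' Emits one biobank-style table per trait (columns `CHR BP A1 A2 BETA SE P AF
#' N RSID`; `A1` is the effect allele) over a shared set of variants, plus a
#' ledger recording, for every emitted row and trait, its perturbation class
#' (`clean`, `swapped`, `respelled_indel`, `multiallelic_member`,
#' `incompatible`, `corrupt`) and its true harmonised form (canonical
#' chromosome, position, REF, ALT, effect size, frequency), enabling exact
#' downstream assertions. Rows are emitted in shuffled order so sorting is
#' exercised.
#'
#' @param config a [simulation_config()].
#' @param reference result of [make_reference()] (same config).
#' @return list: `tables` (list of data.tables, one per trait), `ledger`
#'   (long data.table keyed by `trait`, `row`), `schema`
#'   ([load_schema()] object matching the tables), `rsid_map` (data.table
#'   `rsid`, `chrom`, `pos` over the true loci).
#' @export
simulate_sumstats <- function(config, reference) {
  stopifnot(inherits(config, "simulation_config"))
  ref <- reference$ref
  set.seed(config$seed + 1L)

  ## --- site positions -------------------------------------------------
  lens <- as.integer(config$contig_lengths)
  n_per <- pmax(1L, as.integer(round(config$n_variants *
                                       as.numeric(lens) / sum(as.numeric(lens)))))
  n_per[1L] <- n_per[1L] + (config$n_variants - sum(n_per))
  min_gap <- if (config$indel_fraction > 0) 30L else 2L
  sites <- list()
  for (ci in seq_along(lens)) {
    L <- lens[ci]; n <- n_per[ci]
    if (config$indel_fraction > 0) {
      cap <- (L - 60L) %/% min_gap
      if (n > cap) {
        stop(sprintf("variant density exceeds contig capacity (%d > %d on %s)",
                     n, cap, names(config$contig_lengths)[ci]), call. = FALSE)
      }
      gaps <- min_gap + sample.int(10L, n, replace = TRUE)
      extra <- L - 60L - sum(gaps)
      pos <- 20L + cumsum(gaps)
      if (extra > 0) pos <- pos + sort(sample.int(extra + 1L, n, replace = TRUE)) - 1L
    } else {
      pos <- sort(sample(2:(L - 5L), n))
    }
    sites[[ci]] <- data.table(chrom = names(config$contig_lengths)[ci],
                              raw_pos = as.integer(pos))
  }
  st <- rbindlist(sites)
  ns <- nrow(st)

  ## --- variant alleles: truth in canonical spelling -------------------
  st[, is_indel := stats::runif(ns) < config$indel_fraction]
  ref_base <- ref_fetch(ref, st$chrom, st$raw_pos, st$raw_pos)
  # SNV alt: one of the three non-reference bases, drawn vectorized
  other3 <- t(vapply(BASES, function(b) setdiff(BASES, b), character(3)))
  alt_snv <- other3[cbind(match(ref_base, BASES),
                          sample.int(3L, ns, replace = TRUE))]
  st[, `:=`(pos = raw_pos, ref = ref_base, alt = alt_snv)]
  idl <- which(st$is_indel)
  if (length(idl)) {
    npos <- integer(length(idl)); nref <- character(length(idl))
    nalt <- character(length(idl))
    for (k in seq_along(idl)) {
      i <- idl[k]
      len <- sample(1:3, 1L)
      if (stats::runif(1) < 0.5) {  # deletion: anchor base + deleted run
        r <- ref_fetch(ref, st$chrom[i], st$raw_pos[i], st$raw_pos[i] + len)
        a <- substr(r, 1L, 1L)
      } else {                      # insertion after the anchor base
        r <- ref_base[i]
        a <- paste0(r, paste(sample(BASES, len, replace = TRUE), collapse = ""))
      }
      can <- spelling_canonical(
        enumerate_spellings(ref, st$chrom[i], st$raw_pos[i], r, a))
      npos[k] <- can$pos; nref[k] <- can$ref; nalt[k] <- can$alt
    }
    st[idl, `:=`(pos = npos, ref = nref, alt = nalt)]
  }

  ## --- multiallelic second alts (SNV sites only) ----------------------
  snv_sites <- which(!st$is_indel)
  n_multi <- round(config$multiallelic_fraction * ns)
  multi_at <- sort(resample(snv_sites, min(n_multi, length(snv_sites))))
  st[, site_id := .I]
  extra <- st[multi_at]
  if (nrow(extra)) {
    extra[, alt := vapply(seq_len(.N), function(k)
      sample(setdiff(BASES, c(ref[k], alt[k])), 1L), "")]
  }
  st[, multiallelic := site_id %in% multi_at]
  extra[, multiallelic := TRUE]
  vt <- rbindlist(list(st, extra))
  setorderv(vt, c("chrom", "pos", "site_id"))
  nv <- nrow(vt)

  ## --- rsids: one per locus, shared by multiallelic members ----------
  has_rs <- stats::runif(ns) < config$rsid_fraction
  rs_of_site <- rep(NA_character_, ns)
  rs_of_site[has_rs] <- paste0("rs", 10000L + which(has_rs))
  vt[, rsid := rs_of_site[site_id]]

  ## --- perturbation classes (exclusive; shared across traits) --------
  vt[, class := ifelse(multiallelic, "multiallelic_member", "clean")]
  plain <- which(vt$class == "clean")
  if (config$n_incompatible > 0L) {
    pool <- plain[!vt$is_indel[plain]]
    inc <- resample(pool, min(config$n_incompatible, length(pool)))
    vt$class[inc] <- "incompatible"
    plain <- setdiff(plain, inc)
  }
  n_corrupt <- round(config$corrupt_fraction * nv)
  if (n_corrupt > 0L) {
    cor <- resample(plain, min(n_corrupt, length(plain)))
    vt$class[cor] <- "corrupt"
    plain <- setdiff(plain, cor)
  }
  idx_indel <- plain[vt$is_indel[plain]]
  resp <- idx_indel[stats::runif(length(idx_indel)) < config$respell_fraction]
  vt$class[resp] <- "respelled_indel"
  plain <- setdiff(plain, resp)
  # swaps are injected at SNVs only: swapping an indel's alleles can produce
  # a spelling that is itself a valid reference-matching variant (an
  # insertion's swap reads as a deletion at the same anchor), making the
  # injected orientation unrecoverable in principle
  snv_plain <- plain[!vt$is_indel[plain]]
  swp <- snv_plain[stats::runif(length(snv_plain)) < config$swap_fraction]
  vt$class[swp] <- "swapped"

  ## --- emitted spelling / orientation per row -------------------------
  vt[, `:=`(em_pos = pos, em_other = ref, em_effect = alt)]
  if (length(resp)) {
    rpos <- integer(length(resp)); rref <- character(length(resp))
    ralt <- character(length(resp))
    for (k in seq_along(resp)) {
      i <- resp[k]
      sp <- enumerate_spellings(ref, vt$chrom[i], vt$pos[i], vt$ref[i], vt$alt[i])
      sp <- sp[!(pos == vt$pos[i] & ref == vt$ref[i] & alt == vt$alt[i])]
      pick <- sp[sample.int(nrow(sp), 1L)]
      rpos[k] <- pick$pos; rref[k] <- pick$ref; ralt[k] <- pick$alt
    }
    vt[resp, `:=`(em_pos = rpos, em_other = rref, em_effect = ralt)]
  }
  vt[class == "swapped", `:=`(em_other = alt, em_effect = ref)]
  inc_rows <- which(vt$class == "incompatible")
  if (length(inc_rows)) {
    io <- character(length(inc_rows)); ie <- character(length(inc_rows))
    for (k in seq_along(inc_rows)) {
      two <- resample(setdiff(BASES, vt$ref[inc_rows[k]]), 2L)
      io[k] <- two[1L]; ie[k] <- two[2L]
    }
    vt[inc_rows, `:=`(em_other = io, em_effect = ie)]
  }

  ## --- shuffle emission order -----------------------------------------
  perm <- sample.int(nv)
  vt <- vt[perm]
  vt[, row := .I]

  ## --- per-trait statistics and tables --------------------------------
  miss <- config$missing_fraction
  mf <- function(k) if (!is.null(miss[[k]])) miss[[k]] else 0
  tables <- vector("list", config$n_traits)
  ledgers <- vector("list", config$n_traits)
  trait_ids <- sprintf("trait_%d", seq_len(config$n_traits))
  for (t in seq_len(config$n_traits)) {
    se <- abs(stats::rnorm(nv, 0, config$se_scale)) + config$se_min
    b <- ifelse(stats::runif(nv) < config$signal_fraction,
                stats::rnorm(nv, 0, config$es_sd), 0)
    es <- b + se * stats::rnorm(nv)
    # the ledger's truth is what survives the table's text emission: snap es
    # to its decimal spelling, and draw af on a dyadic grid so the swap
    # complement 1 - af is exact in double arithmetic
    es <- as.numeric(as.character(es))
    p <- 2 * stats::pnorm(-abs(es / se))
    af <- sample.int(1023L, nv, replace = TRUE) / 1024
    ss <- rep(config$sample_size, nv)

    na_p <- stats::runif(nv) < mf("p")
    na_se <- stats::runif(nv) < mf("se")
    na_af <- stats::runif(nv) < mf("af")
    na_ss <- stats::runif(nv) < mf("ss")

    swapped <- vt$class == "swapped"
    beta_em <- ifelse(swapped, -es, es)
    af_em <- ifelse(swapped, 1 - af, af)

    tab <- data.table(
      CHR = vt$chrom, BP = vt$em_pos, A1 = vt$em_effect, A2 = vt$em_other,
      BETA = as.character(beta_em), SE = as.character(se),
      P = as.character(p), AF = as.character(af_em),
      N = as.character(ss), RSID = vt$rsid
    )
    tab[na_p, P := "NA"]; tab[na_se, SE := "NA"]
    tab[na_af, AF := "NA"]; tab[na_ss, N := "NA"]
    tab[is.na(RSID), RSID := "NA"]

    # corruption applied to the emitted text, cycling over failure modes
    cor_rows <- which(vt$class == "corrupt")
    for (j in seq_along(cor_rows)) {
      i <- cor_rows[j]
      mode <- j %% 5L
      if (mode == 0L) tab[i, A1 := "I"]
      else if (mode == 1L) tab[i, A2 := "D"]
      else if (mode == 2L) tab[i, BP := NA_integer_]  # becomes "NA" on write
      else if (mode == 3L) tab[i, P := "1.5"]
      else tab[i, BETA := "not_a_number"]
    }
    tab[, BP := as.character(BP)]
    tab[cor_rows[seq_along(cor_rows) %% 5L == 2L], BP := "0"]

    led <- data.table(
      trait = trait_ids[t], row = vt$row, class = vt$class,
      chrom = vt$chrom, pos = vt$pos, ref = vt$ref, alt = vt$alt,
      es = es, se = ifelse(na_se, NA_real_, se),
      lp = ifelse(na_p, NA_real_, lp_from_p(as.numeric(as.character(p)))),
      af = ifelse(na_af, NA_real_, af),
      ss = ifelse(na_ss, NA_integer_, as.integer(ss)),
      rsid = vt$rsid
    )
    led[class %in% c("corrupt", "incompatible"),
        c("pos", "ref", "alt", "es", "se", "lp", "af") :=
          list(NA_integer_, NA_character_, NA_character_, NA_real_,
               NA_real_, NA_real_, NA_real_)]
    tables[[t]] <- tab
    ledgers[[t]] <- led
  }

  schema <- load_schema(list(columns = list(
    chrom = "CHR", pos = "BP", effect_allele = "A1", other_allele = "A2",
    es = "BETA", se = "SE", p = "P", af = "AF", ss = "N", rsid = "RSID"
  )))
  rsid_map <- unique(vt[!is.na(rsid), .(rsid, chrom, pos)])
  setorderv(rsid_map, c("chrom", "pos"))
  names(tables) <- trait_ids
  list(tables = tables, ledger = rbindlist(ledgers), schema = schema,
       rsid_map = rsid_map)
}

#' Write a full synthetic study to a directory
#'
#' Convenience wrapper: writes the reference FASTA (+ index), one
#' summary-statistics TSV per trait (optionally gzipped), the ground-truth
#' ledger, the matching schema JSON and the rsid map.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed).
#' @param gzip gzip the summary-statistics tables.
#' @return (invisibly) list of written paths plus the simulation objects.
#' @export
simulate_to_dir <- function(config, dir, gzip = FALSE) {
  reference <- make_reference(config, dir = dir)
  sim <- simulate_sumstats(config, reference)
  paths <- list(fasta = reference$fasta)
  for (tid in names(sim$tables)) {
    f <- file.path(dir, paste0("sumstats_", tid, ".tsv",
                               if (gzip) ".gz" else ""))
    if (gzip) {
      con <- gzfile(f, "wt")
      write.table(sim$tables[[tid]], con, sep = "\t", quote = FALSE,
                  row.names = FALSE, na = "NA")
      close(con)
    } else {
      fwrite(sim$tables[[tid]], f, sep = "\t", na = "NA", quote = FALSE)
    }
    paths[[paste0("sumstats_", tid)]] <- f
  }
  fwrite(sim$ledger, file.path(dir, "ledger.tsv"), sep = "\t", na = "NA",
         quote = FALSE)
  write_schema(sim$schema, file.path(dir, "schema.json"))
  fwrite(sim$rsid_map, file.path(dir, "rsid_map.tsv"), sep = "\t", quote = FALSE)
  paths$ledger <- file.path(dir, "ledger.tsv")
  paths$schema <- file.path(dir, "schema.json")
  paths$rsid_map <- file.path(dir, "rsid_map.tsv")
  invisible(c(paths, list(config = config, reference = reference, sim = sim)))
}
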