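# Shared fixture builders. Everything is generated in code at test time.

library(data.table)

# the 6-base contig used throughout the indel-normalisation examples
tiny_ref <- function() ref_memory(c(`1` = "ATTTTC"))

# a longer two-contig in-memory reference with a homopolymer and a
# dinucleotide tract at known offsets
demo_ref <- function() {
  ref_memory(c(
    `1` = paste0("ACGTACGTGG", "TTTTTTTT", "ACGTACGTAC", "ATATATATAT",
                 "GGCCAAGGTT", "ACGTTGCAAC"),
    `2` = "ACGTACGTACGTACGTACGTACGTACGTACGT"
  ))
}

basic_schema <- function(...) {
  load_schema(list(columns = utils::modifyList(list(
    chrom = "CHR", pos = "BP", effect_allele = "A1", other_allele = "A2",
    es = "BETA", se = "SE", p = "P"
  ), list(...))))
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv"),
                              gz = FALSE) {
  if (gz) {
    con <- gzfile(path, "wt")
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    close(con)
  } else {
    data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  }
  path
}

# simulate a study and convert every trait to its own GWAS-VCF; returns the
# simulation objects plus per-trait VCF paths
sim_and_convert <- function(cfg, dir = NULL, keep_incompatible = FALSE,
                            .local_envir = parent.frame()) {
  if (is.null(dir)) dir <- withr::local_tempdir(.local_envir = .local_envir)
  res <- simulate_to_dir(cfg, dir)
  vcfs <- character(cfg$n_traits)
  reports <- vector("list", cfg$n_traits)
  for (t in seq_len(cfg$n_traits)) {
    tid <- sprintf("trait_%d", t)
    vcfs[t] <- file.path(dir, paste0(tid, ".vcf.gz"))
    reports[[t]] <- convert_sumstats(
      res[[paste0("sumstats_", tid)]], res$schema, res$reference$ref,
      vcfs[t],
      metadata = study_metadata(trait_id = tid,
                                sample_size = cfg$sample_size),
      assembly = "synth1", keep_incompatible = keep_incompatible
    )
  }
  c(res, list(vcfs = vcfs, reports = reports, dir = dir))
}

# brute-force record filter used as the query oracle: full read + subset
naive_scan <- function(path) as.data.table(read_gwasvcf(path))

record_key <- function(dt) {
  k <- as.data.table(dt)[, .(chrom = as.character(chrom), pos, ref, alt, trait)]
  data.table::setorderv(k, c("chrom", "pos", "ref", "alt", "trait"))
  unique(k)
}

expect_same_records <- function(a, b) {
  expect_equal(record_key(a), record_key(b))
}
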