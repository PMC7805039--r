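contigs2 <- data.table(name = c("1", "2"), length = c(100000L, 100000L))

one_trait <- function(id = "bmi") {
  setNames(list(study_metadata(id, trait_label = "Body mass index",
                               study_id = "PMID:1", sample_size = 1000L,
                               units = "SD")), id)
}

small_records <- function(trait = "bmi") {
  gwas_records(data.table(
    chrom = c("1", "1", "2"), pos = c(100L, 200L, 50L),
    ref = c("A", "C", "G"), alt = c("G", "T", "GA"),
    af = c(0.25, NA, 0.5), rsid = c("rs1", NA, "rs2"),
    trait = trait, es = c(0.1, -0.2, 0.05), se = c(0.02, 0.04, 0.01),
    lp = c(2, 7.30103, 0.5), eaf = c(0.25, NA, 0.5),
    ss = c(1000L, 1000L, NA)
  ), traits = one_trait(trait), contigs = contigs2, assembly = "synth1")
}

test_that("the #CHROM line has 9 fixed columns plus one per trait", {
  h1 <- build_header(one_trait(), contigs2, "synth1")
  cols1 <- strsplit(tail(h1, 1), "\t")[[1]]
  expect_length(cols1, 10L)

  five <- lapply(sprintf("t%d", 1:5), study_metadata)
  names(five) <- sprintf("t%d", 1:5)
  h5 <- build_header(five, contigs2, "synth1")
  cols5 <- strsplit(tail(h5, 1), "\t")[[1]]
  expect_length(cols5, 14L)
  expect_identical(cols5[9], "FORMAT")

  expect_error(build_header(c(one_trait(), one_trait()), contigs2),
               "duplicate trait_id")
})

test_that("write -> read is a fixpoint at serialization precision", {
  recs <- small_records()
  f <- tempfile(fileext = ".vcf.gz")
  rep <- write_gwasvcf(recs, f)
  expect_identical(rep$n_records, 3L)
  back <- read_gwasvcf(f)
  expect_identical(back$chrom, recs$chrom)
  expect_identical(back$pos, recs$pos)
  expect_identical(back$ref, recs$ref)
  expect_identical(back$alt, recs$alt)
  expect_identical(back$rsid, recs$rsid)
  expect_equal(back$es, recs$es, tolerance = 1e-12)
  expect_equal(back$se, recs$se, tolerance = 1e-12)
  expect_equal(back$lp, recs$lp, tolerance = 1e-6)   # LP: 6 significant digits
  expect_equal(back$eaf, recs$eaf, tolerance = 1e-6)
  expect_identical(back$ss, recs$ss)
  expect_identical(is.na(back$af), is.na(recs$af))
  md <- attr(back, "traits", exact = TRUE)$bmi
  expect_identical(md$trait_label, "Body mass index")
  expect_identical(md$sample_size, 1000L)
  expect_equal(attr(back, "contigs", exact = TRUE)$name, contigs2$name)
  expect_identical(attr(back, "assembly", exact = TRUE), "synth1")
})

test_that("unsorted bodies and duplicate IDs are refused at write", {
  recs <- small_records()
  bad <- as.data.table(recs)[c(2, 1, 3)]
  f <- tempfile(fileext = ".vcf.gz")
  expect_error(
    write_gwasvcf(gwas_records(bad, traits = one_trait(), contigs = contigs2),
                  f), "not karyotypically sorted")
  dup <- as.data.table(recs)[, id := c("v1", "v1", "v2")]
  expect_error(
    write_gwasvcf(gwas_records(dup, traits = one_trait(), contigs = contigs2),
                  f), "duplicate variant ID")
})

test_that("a trait missing at a variant serializes as all-null FORMAT fields", {
  two <- rbind(
    as.data.table(small_records("t1")),
    as.data.table(small_records("t2"))[pos != 200L]
  )
  traits <- setNames(list(study_metadata("t1"), study_metadata("t2")),
                     c("t1", "t2"))
  recs <- gwas_records(two, traits = traits, contigs = contigs2,
                       assembly = "s")
  recs <- sort_karyotypic(recs)
  f <- tempfile(fileext = ".vcf.gz")
  write_gwasvcf(recs, f)
  lines <- readLines(gzfile(f))
  body <- lines[!startsWith(lines, "#")]
  miss <- body[grepl("\t200\t", body)]
  cells <- strsplit(miss, "\t")[[1]]
  expect_identical(cells[11], ".:.:.:.:.")   # ES:SE:LP:AF:SS all null for t2
  back <- read_gwasvcf(f)
  expect_identical(nrow(records_for_trait(back, "t2")), 2L)
  expect_identical(nrow(records_for_trait(back, "t1")), 3L)
})

test_that("written files parse under an independent VCF parser with fields intact", {
  skip_if_not_installed("VariantAnnotation")
  recs <- small_records()
  f <- tempfile(fileext = ".vcf.gz")
  write_gwasvcf(recs, f)
  v <- VariantAnnotation::readVcf(f, genome = "synth1")
  expect_identical(nrow(v), 3L)
  hd <- VariantAnnotation::header(v)
  expect_setequal(rownames(VariantAnnotation::geno(hd)),
                  c("ES", "SE", "LP", "AF", "SS"))
  expect_setequal(rownames(VariantAnnotation::info(hd)), c("AF", "RSID"))
  expect_identical(VariantAnnotation::samples(hd), "bmi")
  es <- unlist(VariantAnnotation::geno(v)$ES[, 1])
  expect_equal(unname(es), c(0.1, -0.2, 0.05), tolerance = 1e-12)
  # positions and alleles survive the independent parse
  rr <- SummarizedExperiment::rowRanges(v)
  expect_identical(unname(BiocGenerics::start(rr)), c(100L, 200L, 50L))
})

test_that("positional index supports identity and vacuous queries", {
  recs <- small_records()
  f <- tempfile(fileext = ".vcf.gz")
  write_gwasvcf(recs, f)
  index_positions(f)
  hit <- query_position(f, "1", 100L)
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$alt, "G")
  expect_identical(nrow(query_interval(f, "2", 51L, 99999L)), 0L)
  all1 <- query_interval(f, "1", 1L, 100000L)
  expect_identical(nrow(all1), 2L)
})

test_that("rsid index maps loci and distinguishes not-found from empty", {
  recs <- small_records()
  f <- tempfile(fileext = ".vcf.gz")
  write_gwasvcf(recs, f)
  index_positions(f)
  info <- index_rsids(f)
  expect_identical(info$n_indexed, 2L)
  expect_identical(info$n_without_rsid, 1L)
  loc <- lookup_rsid(info$path, "rs1")
  expect_true(attr(loc, "found", exact = TRUE))
  expect_identical(loc$pos, 100L)
  absent <- lookup_rsid(info$path, "rs999")
  expect_false(attr(absent, "found", exact = TRUE))
  expect_identical(nrow(absent), 0L)
  r <- query_rsid(f, "rs2")
  expect_identical(r$alt, "GA")
})

test_that("a split multiallelic site shares one rsid and both records return", {
  dt <- data.table(
    chrom = "1", pos = 1000L, ref = "A", alt = c("G", "T"),
    rsid = "rs555", trait = "t1", es = c(0.1, -0.2), se = 0.02, lp = 2
  )
  recs <- gwas_records(dt, contigs = contigs2, assembly = "s")
  f <- tempfile(fileext = ".vcf.gz")
  write_gwasvcf(recs, f)
  index_positions(f)
  index_rsids(f)
  loc <- lookup_rsid(rsid_index_path(f), "rs555")
  expect_identical(nrow(loc), 1L)          # one locus entry, not two
  sib <- query_rsid(f, "rs555")
  expect_identical(nrow(sib), 2L)
  expect_setequal(sib$alt, c("G", "T"))
  # caller-side allele filter retains the target substitution
  expect_identical(query_rsid(f, "rs555", alt = "T")$alt, "T")
})

test_that("export projects onto GWAS-Catalog-style headings with P recomputed", {
  recs <- small_records()
  out <- export_tsv(recs)
  expect_identical(names(out),
                   c("chromosome", "base_pair_location", "effect_allele",
                     "other_allele", "beta", "standard_error", "p_value",
                     "effect_allele_frequency", "rsid"))
  expect_identical(out$p_value[1], 0.01)   # lp = 2 back-transforms exactly
  expect_identical(out$effect_allele[3], "GA")
  expect_error(export_tsv(recs, spec = c("chromosome", "flavour")),
               "unknown export field")
})

test_that("merging disjoint single-trait files gives the union with nulls", {
  d <- withr::local_tempdir()
  r1 <- small_records("t1")
  r2dt <- as.data.table(small_records("t2"))
  r2dt[, pos := pos + 10L]
  r2 <- gwas_records(r2dt, traits = setNames(list(study_metadata("t2")), "t2"),
                     contigs = contigs2, assembly = "synth1")
  f1 <- file.path(d, "a.vcf.gz"); f2 <- file.path(d, "b.vcf.gz")
  write_gwasvcf(r1, f1); write_gwasvcf(r2, f2)
  fm <- file.path(d, "m.vcf.gz")
  m <- merge_traits(c(f1, f2), out = fm)
  expect_identical(length(unique(m$trait)), 2L)
  back <- read_gwasvcf(fm)
  expect_identical(nrow(unique(as.data.table(back)[, .(chrom, pos, ref, alt)])),
                   6L)
  # every variant has data for exactly one of the two traits
  expect_identical(nrow(records_for_trait(back, "t1")), 3L)
  expect_identical(nrow(records_for_trait(back, "t2")), 3L)
  expect_true(file.exists(paste0(fm, ".tbi")))

  # merging a file with itself under a distinct trait id duplicates stats
  r1b <- gwas_records(as.data.table(r1)[, trait := "t9"],
                      traits = setNames(list(study_metadata("t9")), "t9"),
                      contigs = contigs2, assembly = "synth1")
  f3 <- file.path(d, "c.vcf.gz")
  write_gwasvcf(r1b, f3)
  m2 <- merge_traits(c(f1, f3))
  wide <- data.table::dcast(as.data.table(m2), chrom + pos + ref + alt ~ trait,
                            value.var = "es")
  expect_equal(wide$t1, wide$t9, tolerance = 1e-12)

  # trait collision and assembly mismatch are fatal
  expect_error(merge_traits(c(f1, f1)), "collision")
})
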