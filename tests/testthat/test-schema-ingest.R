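test_that("a minimal complete mapping loads; gaps and unknown keys fail loudly", {
  sc <- basic_schema()
  expect_s3_class(sc, "gwas_schema")
  expect_identical(sc$position_base, 1L)
  expect_true(all(c("NA", "", ".") %in% sc$missing_values))

  expect_error(load_schema(list(columns = list(
    chrom = "CHR", pos = "BP", effect_allele = "A1",
    es = "BETA", p = "P"))), "OTHER_ALLELE_UNMAPPED")
  expect_error(load_schema(list(columns = list(
    chrom = "CHR", pos = "BP", effect_allele = "A1", other_allele = "A2",
    p = "P"))), "ES_UNMAPPED")
  expect_error(load_schema(list(columns = list(
    chrom = "CHR", pos = "BP", effect_allele = "A1", other_allele = "A2",
    es = "BETA"))), "P_UNMAPPED")
  expect_error(load_schema(list(columns = list(
    chrom = "CHR", pos = "BP", effect_allele = "A1", other_allele = "A2",
    es = "BETA", p = "P", banana = "X"))), "unknown schema column")
  expect_error(load_schema(list(frobnicate = TRUE, columns = list())),
               "unknown schema key")
})

test_that("schema documents round-trip through JSON", {
  sc <- basic_schema(af = "FREQ")
  f <- tempfile(fileext = ".json")
  write_schema(sc, f)
  sc2 <- load_schema(f)
  expect_identical(sc2$columns$af, "FREQ")
  expect_identical(sc2$position_base, sc$position_base)
})

test_that("rows map directly onto candidates, with P converted to LP", {
  f <- write_tsv_fixture(data.table(
    CHR = "1", BP = 1000L, A1 = "G", A2 = "a",   # lowercase must be uppercased
    BETA = 0.12, SE = 0.03, P = 0.01
  ))
  out <- read_sumstats(f, basic_schema())
  expect_identical(out$counts, list(read = 1L, emitted = 1L, rejected = 0L,
                                    p_underflow = 0L, rsid_dropped = 0L))
  cand <- out$candidates
  expect_identical(cand$chrom, "1")
  expect_identical(cand$pos, 1000L)
  expect_identical(cand$other, "A")
  expect_identical(cand$effect, "G")
  expect_identical(cand$es, 0.12)
  expect_identical(cand$lp, 2)
})

test_that("declared missing tokens pass through as NA without rejection", {
  f <- write_tsv_fixture(data.table(
    CHR = c("1", "1"), BP = c(10L, 20L), A1 = c("G", "T"), A2 = c("A", "C"),
    BETA = c(0.1, 0.2), SE = c("NA", "0.05"), P = c("NA", "0.5")
  ))
  out <- read_sumstats(f, basic_schema())
  expect_identical(out$counts$emitted, 2L)
  expect_true(is.na(out$candidates$lp[1]))
  expect_true(is.na(out$candidates$se[1]))
  expect_identical(out$candidates$lp[2], -log10(0.5))
})

test_that("a 0-based schema shifts every position up by one at ingest", {
  f <- write_tsv_fixture(data.table(
    CHR = "1", BP = c(0L, 99L, 4L), A1 = c("G", "T", "C"),
    A2 = c("A", "C", "G"), BETA = 0.1, SE = 0.02, P = 0.5
  ))
  sc0 <- load_schema(list(position_base = 0, columns = list(
    chrom = "CHR", pos = "BP", effect_allele = "A1", other_allele = "A2",
    es = "BETA", se = "SE", p = "P")))
  out <- read_sumstats(f, sc0)
  expect_identical(out$candidates$pos, c(1L, 100L, 5L))
})

test_that("odds ratios are stored as log(OR); non-positive ORs are rejected", {
  f <- write_tsv_fixture(data.table(
    CHR = "1", BP = c(10L, 20L), A1 = c("G", "T"), A2 = c("A", "C"),
    OR = c(1.5, -2), SE = 0.05, P = 0.5
  ))
  sc <- load_schema(list(columns = list(
    chrom = "CHR", pos = "BP", effect_allele = "A1", other_allele = "A2",
    or = "OR", se = "SE", p = "P")))
  out <- read_sumstats(f, sc)
  expect_equal(out$candidates$es, log(1.5))
  expect_identical(out$issues$reason, "OR_NOT_POSITIVE")
})

test_that("gzip-compressed input reads identically to plain text", {
  df <- data.table(CHR = "1", BP = 1:5 * 10L, A1 = "G", A2 = "A",
                   BETA = 0.1, SE = 0.02, P = 0.5)
  plain <- read_sumstats(write_tsv_fixture(df), basic_schema())
  gz <- read_sumstats(write_tsv_fixture(df, tempfile(fileext = ".tsv.gz"),
                                        gz = TRUE), basic_schema())
  expect_equal(plain$candidates, gz$candidates)
})

test_that("every row yields exactly one candidate or one issue, in order", {
  cfg <- simulation_config(seed = 31, n_variants = 2000,
                           contig_lengths = c(`1` = 120000L),
                           corrupt_fraction = 0.02)
  ref <- make_reference(cfg)
  sim <- simulate_sumstats(cfg, ref)
  f <- write_tsv_fixture(sim$tables[[1]])
  out <- read_sumstats(f, sim$schema)
  n <- nrow(sim$tables[[1]])
  expect_identical(out$counts$read, n)
  expect_identical(out$counts$emitted + out$counts$rejected, n)
  expect_identical(out$counts$rejected,
                   sum(sim$ledger[trait == "trait_1"]$class == "corrupt"))
  # rejected lines are exactly the corrupted rows (header is line 1)
  expect_setequal(out$issues$line,
                  sim$ledger[trait == "trait_1"][class == "corrupt"]$row + 1L)
  # ingest never reorders: candidate line numbers are strictly increasing
  expect_true(!is.unsorted(out$candidates$line, strictly = TRUE))
})

test_that("P/LP disagreement and unmappable columns are caught", {
  f <- write_tsv_fixture(data.table(
    CHR = "1", BP = c(10L, 20L), A1 = c("G", "T"), A2 = c("A", "C"),
    BETA = 0.1, SE = 0.05, P = c(0.01, 0.01), LP10 = c(2.0, 3.5)
  ))
  sc <- load_schema(list(columns = list(
    chrom = "CHR", pos = "BP", effect_allele = "A1", other_allele = "A2",
    es = "BETA", se = "SE", p = "P", lp = "LP10")))
  out <- read_sumstats(f, sc)
  expect_identical(out$counts$emitted, 1L)
  expect_identical(out$issues$reason, "P_LP_INCONSISTENT")

  sc_bad <- basic_schema(p = "PVALUE_MISSING_COL")
  expect_error(read_sumstats(f, sc_bad), "absent from the header")
})
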