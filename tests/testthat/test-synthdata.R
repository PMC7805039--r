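test_that("the generator is byte-identical under a fixed config and seed", {
  cfg <- simulation_config(seed = 51, n_variants = 800,
                           contig_lengths = c(`1` = 60000L),
                           n_incompatible = 5)
  r1 <- make_reference(cfg); s1 <- simulate_sumstats(cfg, r1)
  r2 <- make_reference(cfg); s2 <- simulate_sumstats(cfg, r2)
  expect_identical(r1$ref$seqs, r2$ref$seqs)
  expect_identical(s1$tables, s2$tables)
  expect_identical(s1$ledger, s2$ledger)

  # a different seed changes the data
  cfg3 <- simulation_config(seed = 52, n_variants = 800,
                            contig_lengths = c(`1` = 60000L))
  r3 <- make_reference(cfg3)
  expect_false(identical(r1$ref$seqs, r3$ref$seqs))
})

test_that("contigs have the requested lengths and planted repeat tracts", {
  cfg <- simulation_config(seed = 53, contig_lengths = c(`1` = 5000L,
                                                         `2` = 3000L))
  r <- make_reference(cfg)
  expect_identical(unname(nchar(r$ref$seqs)), c(5000L, 3000L))
  expect_gt(nrow(r$tracts), 0L)
  for (i in seq_len(min(nrow(r$tracts), 20L))) {
    tr <- r$tracts[i]
    seg <- ref_fetch(r$ref, tr$chrom, tr$start, tr$start + 7L)
    # the planted motif tiles the recorded offset
    expect_identical(seg, substr(strrep(tr$motif, 8L), 1L, 8L))
  }
})

test_that("FASTA output is faidx-indexable and matches the in-memory sequences", {
  d <- withr::local_tempdir()
  cfg <- simulation_config(seed = 54, contig_lengths = c(`1` = 2000L))
  r <- make_reference(cfg, dir = d)
  expect_true(file.exists(paste0(r$fasta, ".fai")))
  expect_identical(ref_fetch(r$ref_fa, "1", 101L, 160L),
                   ref_fetch(r$ref, "1", 101L, 160L))
})

test_that("every emitted row has exactly one ledger entry; classes partition", {
  cfg <- simulation_config(seed = 55, n_variants = 3000, n_traits = 2,
                           n_incompatible = 20,
                           contig_lengths = c(`1` = 200000L))
  sim <- simulate_sumstats(cfg, make_reference(cfg))
  for (tid in names(sim$tables)) {
    led <- sim$ledger[trait == tid]
    expect_identical(nrow(led), nrow(sim$tables[[tid]]))
    expect_identical(sort(led$row), seq_len(nrow(led)))
    expect_true(all(led$class %in% c("clean", "swapped", "respelled_indel",
                                     "multiallelic_member", "incompatible",
                                     "corrupt")))
  }
  expect_identical(sum(sim$ledger$class == "incompatible"), 40L)  # 20 x 2 traits
})

test_that("the clean limit harmonises 100% unchanged; the swap limit recovers exactly", {
  d <- withr::local_tempdir()
  cfg0 <- simulation_config(seed = 56, n_variants = 600,
                            contig_lengths = c(`1` = 60000L),
                            swap_fraction = 0, respell_fraction = 0,
                            corrupt_fraction = 0, multiallelic_fraction = 0,
                            indel_fraction = 0)
  fx0 <- sim_and_convert(cfg0, dir = file.path(d, "clean"))
  expect_identical(fx0$reports[[1]]$status_counts,
                   list(unchanged = nrow(fx0$sim$tables[[1]])))

  cfg1 <- simulation_config(seed = 57, n_variants = 600,
                            contig_lengths = c(`1` = 60000L),
                            swap_fraction = 1, respell_fraction = 0,
                            corrupt_fraction = 0, multiallelic_fraction = 0,
                            indel_fraction = 0)
  fx1 <- sim_and_convert(cfg1, dir = file.path(d, "swapped"))
  n <- nrow(fx1$sim$tables[[1]])
  expect_identical(fx1$reports[[1]]$status_counts, list(swapped = n))
  back <- as.data.table(read_gwasvcf(fx1$vcfs[1]))
  led <- fx1$sim$ledger
  m <- merge(led, back, by = c("chrom", "pos", "ref", "alt"))
  expect_identical(nrow(m), n)
  expect_lt(max(abs(m$es.x - m$es.y)), 1e-13)
})

test_that("injected perturbation counts equal the pipeline's observed counts", {
  cfg <- simulation_config(seed = 58, n_variants = 2500, n_incompatible = 25,
                           contig_lengths = c(`1` = 200000L))
  fx <- sim_and_convert(cfg)
  led <- fx$sim$ledger[trait == "trait_1"]
  rep <- fx$reports[[1]]
  expect_identical(rep$counts$rejected, sum(led$class == "corrupt"))
  expect_identical(rep$status_counts$swapped, sum(led$class == "swapped"))
  expect_identical(rep$status_counts$incompatible,
                   sum(led$class == "incompatible"))
  expect_identical(rep$status_counts$unchanged,
                   sum(led$class %in% c("clean", "respelled_indel",
                                        "multiallelic_member")))
})

test_that("clean-fraction P values are Uniform(0,1) under the null", {
  cfg <- simulation_config(seed = 59, n_variants = 10000,
                           missing_fraction = list(),
                           corrupt_fraction = 0)
  sim <- simulate_sumstats(cfg, make_reference(cfg))
  led <- sim$ledger[trait == "trait_1"][class != "incompatible"]
  p <- p_from_lp(led$lp)
  ks <- stats::ks.test(p, "punif")
  expect_gt(ks$p.value, 0.001)
})
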