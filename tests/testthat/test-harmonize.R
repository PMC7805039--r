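# reference base at 1:100 is fetched from demo_ref(); candidates are built
# around explicit bases so each branch is pinned

cand <- function(chrom = "1", pos = 1L, other, effect, es = 0.12, af = 0.25,
                 trait = "t1") {
  data.table(chrom = chrom, pos = as.integer(pos), other = other,
             effect = effect, es = es, se = 0.03, lp = 2, af = af,
             ss = NA_integer_, rsid = NA_character_, ident = NA_character_,
             trait = trait)
}

test_that("a record whose non-effect allele matches the reference is unchanged", {
  ref <- tiny_ref()                      # contig 1 = "ATTTTC"
  out <- harmonize_records(cand(pos = 1, other = "A", effect = "G"), ref)
  expect_identical(out$status, "unchanged")
  expect_identical(out$ref, "A")
  expect_identical(out$alt, "G")
  expect_identical(out$es, 0.12)
  expect_identical(out$eaf, 0.25)
})

test_that("a swapped record is relabelled with ES negated and AF complemented", {
  ref <- tiny_ref()
  out <- harmonize_records(cand(pos = 1, other = "G", effect = "A"), ref)
  expect_identical(out$status, "swapped")
  expect_identical(out$ref, "A")
  expect_identical(out$alt, "G")
  expect_identical(out$es, -0.12)
  expect_identical(out$af, 0.75)
  expect_identical(out$eaf, 0.75)
})

test_that("records matching neither allele are incompatible; off-reference ones distinct", {
  ref <- tiny_ref()
  out <- harmonize_records(rbind(
    cand(pos = 1, other = "T", effect = "C"),    # ref base is A
    cand(pos = 5000, other = "A", effect = "G"), # beyond contig end
    cand(chrom = "9", pos = 1, other = "A", effect = "G")  # unknown contig
  ), ref)
  expect_identical(out$status,
                   c("incompatible", "not_in_reference", "not_in_reference"))
})

test_that("reverse-complement-only matches are reported, never flipped", {
  ref <- tiny_ref()                      # base at pos 2 is T
  out <- harmonize_records(cand(pos = 2, other = "A", effect = "C"), ref)
  expect_identical(out$status, "incompatible")
  expect_match(out$detail, "reverse-complement")
})

test_that("harmonisation is idempotent and an involution on swapped input", {
  ref <- demo_ref()
  set.seed(5)
  pos <- sample(5:30, 10)
  base <- ref_fetch(ref, rep("1", 10), pos, pos)
  alt <- vapply(base, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  es <- rnorm(10); af <- runif(10)
  clean <- data.table(chrom = "1", pos = as.integer(pos), other = base,
                      effect = alt, es = es, se = 0.1, lp = 1, af = af,
                      ss = NA_integer_, rsid = NA_character_,
                      ident = NA_character_, trait = "t1")
  h1 <- harmonize_records(clean, ref)
  expect_true(all(h1$status == "unchanged"))

  # deliberately swapped emission: exchange alleles, pre-negate es, flip af
  swapped <- copy(clean)
  swapped[, c("other", "effect", "es", "af") :=
            list(clean$effect, clean$other, -clean$es, 1 - clean$af)]
  h2 <- harmonize_records(swapped, ref)
  expect_true(all(h2$status == "swapped"))
  expect_identical(h2$es, es)            # exact recovery, full float precision
  expect_identical(h2$eaf, af)
  expect_identical(h2$ref, base)
  expect_identical(h2$alt, unname(alt))

  # applying harmonisation to its own output is a no-op
  again <- data.table(chrom = h2$chrom, pos = h2$pos, other = h2$ref,
                      effect = h2$alt, es = h2$es, se = h2$se, lp = h2$lp,
                      af = h2$eaf, ss = NA_integer_, rsid = NA_character_,
                      ident = NA_character_, trait = "t1")
  h3 <- harmonize_records(again, ref)
  expect_true(all(h3$status == "unchanged"))
  expect_identical(h3$es, h2$es)
})

test_that("rsid annotation fills only missing rsids by locus", {
  recs <- data.table(chrom = c("1", "1", "2"), pos = c(10L, 20L, 10L),
                     rsid = c(NA, "rs1", NA))
  map <- data.table(rsid = c("rs7", "rs8", "bad_id"),
                    chrom = c("1", "1", "2"), pos = c(10L, 20L, 10L))
  out <- annotate_rsids(recs, map)
  expect_identical(out$rsid, c("rs7", "rs1", NA))
})
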