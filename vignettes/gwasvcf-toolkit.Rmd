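---
title: "Storing GWAS summary statistics as GWAS-VCF: model, harmonisation and design notes"
author: "gwasvcfkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Storing GWAS summary statistics as GWAS-VCF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasvcfkit)
library(data.table)
```

## The data model

A GWAS summary-statistics record couples a sequence variant with per-trait
association statistics. gwasvcfkit maps this onto VCF 4.2:

* the eight mandatory columns CHROM, POS, ID, REF, ALT, QUAL, FILTER, INFO
  describe the variant. **REF is the non-effect allele and must match the
  reference genome; ALT is the effect allele**, so the sign of the effect
  size is unambiguous across studies. Each variant occupies its own row —
  multiallelic sites are split before writing.
* per-trait statistics are FORMAT fields in the sample columns, one sample
  column per trait: `ES` (effect size on ALT), `SE` (its standard error),
  `LP` (`-log10` P), and optionally `AF` (effect-allele frequency) and `SS`
  (sample size). Storing `LP` instead of `P` keeps strong signals
  representable: P values far below double-precision underflow still have
  finite `LP`.
* the ID column holds a caller-supplied unique identifier or `.`. rsids
  deliberately live in INFO (`RSID`), not ID: an rsid names a *locus*, not
  an allelic substitution, so two records produced by splitting one
  multiallelic site legitimately share an rsid and would violate ID
  uniqueness. Retrieval by rsid therefore returns every sibling record and
  callers filter to their target substitution.
* study metadata (label, study ID, ontology, sample size, ancestry, units,
  test, provenance, date) is serialized into one structured `##SAMPLE` header
  line per trait; contig names, lengths and the assembly name are declared in
  the header and define the karyotypic sort order of the body.
* QUAL is always null: no per-variant quality model is defined for summary
  statistics.

Missing values are VCF-native: `.` in any FORMAT field, and a trait absent
at a variant has every FORMAT field null. A missing `LP` is distinguishable
from `LP = 0` (P = 1).

## Harmonisation

Input tables declare an effect and an other allele, but tools disagree
about orientation. Harmonisation compares both alleles to the reference
sequence at the record's position:

* other allele matches → `unchanged`;
* effect allele matches → `swapped`: alleles exchanged, `ES := -ES`, and
  both the site-level and per-trait frequencies `:= 1 - AF`. Swapping is an
  involution — a record swapped on input is recovered bit-exactly;
* neither matches → `incompatible`; chromosome/position absent from the
  reference → `not_in_reference`. Both are excluded from output by default
  (with logged counts) or written with FILTER `HARMONISATION_FAILED` when
  `keep_incompatible = TRUE`.

Alleles are taken to be reported on the forward strand. Records whose
alleles match only after reverse-complement are reported `incompatible`
with a distinguishing message and never silently flipped: palindromic (A/T,
C/G) variants make strand inference from alleles alone unsafe, and a wrong
flip corrupts effect directions undetectably. The same rule covers
palindromic variants where both orientations are conceivable — the direct
match decides.

## Indel normalisation

One insertion or deletion inside a repeat tract has many equivalent
spellings. The canonical form is the unique leftmost, minimal
representation, computed by iterating: while both alleles end with the same
base, drop it — first extending both alleles leftward with the reference
base at `pos - 1` whenever a drop would empty an allele; then trim shared
leading bases (keeping length ≥ 1 each), advancing `pos`. SNVs are fixed
points; a variant whose left-extension reaches the contig start cannot be
anchored and is flagged rather than guessed at.

The package also ships `enumerate_spellings()`, a brute-force enumerator of
*all* spellings of an edit within a window (default flank 16 bases, which
exceeds the longest repeat tract the synthetic genomes plant). The
enumeration is deliberately a different algorithm — prefix/suffix matching
against the edited haplotype — so tests can require that the iterative
normaliser lands on the enumeration's minimal-length, leftmost spelling for
every case, and that applying either spelling to the reference yields the
identical edited haplotype. For pathological repeats beyond the window the
enumeration is not exhaustive; the iterative algorithm itself has no such
bound.

## Queries and indexing

Files are BGZF-compressed and tabix-indexed, so interval and
single-position queries decompress only the blocks overlapping the region.
Interval semantics are pos-anchored, 1-based, inclusive: a record belongs
to a region iff its POS lies inside it; a deletion whose REF spans into a
region from the left is not returned. This matches how tabix keys records
and keeps query results bit-identical to a naive full scan, which the test
suite asserts for every query class.

The rsid index is a sorted three-column table (`rsid` integer, `chrom`,
`pos`) stored next to the file as `<file>.rsidx` and searched by keyed
binary search after a single read. P-value queries are linear scans by
design — no index assists a statistics-value predicate — and the benchmark
harness makes the consequence visible: at million-variant scale, indexed
position/rsid/interval queries beat a flat-file scan while the P-value
class does not. Benchmark timings are informational; only those orderings
are asserted, and only at dense scale (at a few hundred thousand variants,
the fixed costs of decompression and index loading can favour flat text for
point lookups).

## The synthetic-data generator

`simulate_sumstats()` emulates the kind of dense single-trait association
table distributed by large biobank analyses: columns
`CHR BP A1 A2 BETA SE P AF N RSID` with `A1` the effect allele. Reference
genomes are random sequence with planted homopolymer and dinucleotide
tracts (8–14 bases, about one per 500 bp) so indel normalisation has real
work. Injected heterogeneity, each class recorded per row in a
ground-truth ledger:

* **swapped** rows: alleles exchanged with `BETA` pre-negated and `AF`
  complemented — harmonisation must undo them exactly. Swaps are injected
  only at SNVs: an indel's swapped orientation can coincide with a valid
  reference-matching variant at the same anchor (an insertion's swap reads
  as a deletion), making the injected orientation unrecoverable in
  principle, not merely hard.
* **respelled indels**: emitted in a random non-canonical spelling drawn
  from the enumeration oracle, so normalisation is guaranteed non-trivial
  work.
* **multiallelic members**: SNV sites emitted with a second alternative
  allele sharing locus and rsid.
* **incompatible** rows: both alleles deliberately mismatching the
  reference.
* **corrupt** rows: structurally malformed (non-ACGT allele codes such as
  `I`/`D`, zero positions, P > 1, non-numeric effect sizes), cycling the
  failure modes deterministically.
* per-field missingness (`NA` tokens) at configurable rates (defaults ~1–2%
  on SE, P, AF, N).

Statistics are Wald-consistent: `se = |N(0, 0.02)| + 0.005` (a plausible
standard-error scale for a biobank-sized quantitative-trait GWAS),
`es = b + se·z` with `z ~ N(0,1)`, and `P = 2Φ(−|es/se|)`. The default is
the null model (`signal_fraction = 0`, so `b = 0`): P values are then
exactly Uniform(0,1), which the suite verifies by Kolmogorov–Smirnov test,
and `P ↔ LP` conversions are internally consistent under round trips. A
nonzero `signal_fraction` adds effects `b ~ N(0, es_sd)`. The ledger's
ground truth is defined as what survives the table's own text emission:
effect sizes are snapped to their decimal spelling and frequencies drawn on
a 1/1024 grid (whose complement `1 - af` is exact in double arithmetic), so
"recovered equals truth" assertions can be bit-exact rather than
tolerance-based. Default study
conditions: 10⁴ variant sites over two contigs (400 kb + 250 kb), 10%
indels, 2% multiallelic sites, 15% swapped rows, 50% of indels respelled,
1% corrupt rows, 95% of sites carrying an rsid, N = 50 000.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: linkage disequilibrium between variants,
realistic allele-frequency spectra, genotype-level data, strand errors
(deliberately out of scope, see harmonisation), or genome-build mismatches
(no liftover; the declared assembly must match the supplied reference).

## Numerical and design choices

* **P = 0 inputs** (upstream underflow) are stored as `LP = 999` with a
  warning: preserves the "most significant" ranking without inventing
  precision.
* **Serialization precision**: `ES`/`SE` at full double precision (15
  significant digits); `LP` and frequencies at 6 significant digits, which
  exceeds the precision of any upstream P value while keeping files
  compact. The tabular export guarantees 4-significant-figure agreement.
* **FORMAT order** is fixed (`ES:SE:LP[:AF][:SS]`) and optional fields are
  declared only when used, so identical inputs give byte-identical files.
* **Sorting** is an in-memory stable radix sort by (contig rank, POS, REF,
  ALT). The toolkit targets desk-scale files — up to a few million records,
  far below memory on ordinary hardware; an external merge would buy
  nothing at these sizes.
* **Chromosome naming** is stored exactly as the reference declares it; a
  converter flag (`chrom_style`) strips or adds a `chr` prefix explicitly,
  never silently.
* **Indels without an anchor base** (e.g. `REF = "-"` conventions) are
  rejected at ingest; re-anchoring heuristics depend on knowing the source
  tool's convention and are unsafe without it.
* **Data-quality failures do not fail a conversion** unless `--strict`:
  real summary statistics are messy, and the report carries exact counts
  and per-line reasons.
* **rsid index format**: a plain-text keyed table rather than a database
  file — human-readable, trivially diffable, and binary-search-fast after a
  single `fread`; the integer-rsid/locus schema mirrors the layout used by
  rsid-indexing tools so migration is mechanical.
* **Problem sizes in the shipped tests** were chosen to exercise each
  guarantee at the scale where it binds while keeping a full run on one CPU
  comfortable: 10⁴ variants × 2 traits for round-trip fidelity, 10⁴ with
  30% swaps + 50 incompatibles for harmonisation recovery, 10³ respelled
  indels for the normalisation oracle, 10⁵ × 5 traits for query
  correctness, and 10⁶ single-trait SNVs for the benchmark direction
  checks.

## Known limitations

* No liftover between genome assemblies; assembly equality is enforced at
  merge time.
* No BCF (binary) writer; htslib-family tools convert on the read side.
* The reserved header key names used here (`##SAMPLE` fields,
  `##genome_assembly`) are this package's documented vocabulary; other
  GWAS-VCF implementations may spell some keys differently, so a renaming
  pass may be needed for byte-level compatibility with files from other
  tools.
* P-value queries scan the whole file. Precomputing significance tiers as
  INFO flags would accelerate them but is not implemented.
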