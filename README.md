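# gwasvcfkit

Store, harmonise, index and query GWAS summary statistics as **GWAS-VCF**.

## The problem

Genome-wide association studies are shared as summary statistics — one row
per variant with an effect size, its standard error, a P value, and
usually an allele frequency and sample size. Because every analysis tool
(plink, BOLT-LMM, GCTA, METAL, ...) emits its own tabular layout, secondary
analyses constantly trip over the same hazards: ambiguity about *which*
allele the effect size refers to, inconsistent indel spellings, absent
metadata, and slow ad-hoc text scans over multi-million-row files.

gwasvcfkit implements the GWAS-VCF convention in R: summary statistics are
stored in VCF 4.2 with one variant per row, the **alternative allele is
always the effect allele**, per-trait statistics live in the sample columns
as FORMAT fields, and study metadata lives in the header. Files are
BGZF-compressed, karyotypically sorted, tabix-indexed for positional
queries and carry a secondary rsid→locus index.

## What the toolkit does

- **Ingest** any tabular summary-statistics file under an explicit JSON
  column schema (`load_schema()`, `read_sumstats()`); positions may be
  declared 0-based, odds ratios are stored as `log(OR)`, P values as
  `LP = -log10(P)`.
- **Harmonise** each record against a reference genome
  (`harmonize_records()`): if the input's effect allele is the one matching
  the reference sequence, the alleles are swapped, `ES := -ES` and every
  allele frequency `:= 1 - AF`; records matching neither allele (including
  reverse-complement-only matches, which are never silently strand-flipped)
  are excluded or FILTER-flagged.
- **Normalise indels** to the unique leftmost, minimal spelling
  (`normalize_variant()`), with a brute-force spelling enumerator
  (`enumerate_spellings()`) as an independent cross-check.
- **Split multiallelic sites** into one record per alternative allele and
  **sort karyotypically** (`split_multiallelic()`, `sort_karyotypic()`).
- **Write / index / read** GWAS-VCF (`write_gwasvcf()`, `index_positions()`,
  `index_rsids()`, `read_gwasvcf()`), **query** by interval, position, rsid
  or P-value threshold (`query_*()`), **export** to GWAS-Catalog-style TSV
  (`export_tsv()`), **merge** single-trait files into multi-trait files
  (`merge_traits()`), and **benchmark** query classes against flat TSV
  (`run_benchmark()`).
- **Simulate** reference genomes and summary-statistics tables with a
  ground-truth ledger (`simulation_config()`, `make_reference()`,
  `simulate_sumstats()`), so the full pipeline is testable offline.

A command-line interface wraps it all: `inst/exec/gwasvcf` with subcommands
`convert`, `validate`, `index`, `query`, `export`, `merge`, `simulate`,
`bench`.

## Worked example

```r
library(gwasvcfkit)

# a synthetic study: reference FASTA + biobank-style sumstats + known truth
cfg <- simulation_config(seed = 7, n_variants = 500,
                         contig_lengths = c(`1` = 60000L, `2` = 40000L),
                         n_incompatible = 5)
d <- tempfile(); dir.create(d)
res <- simulate_to_dir(cfg, d)

rep <- convert_sumstats(res$sumstats_trait_1, res$schema, res$fasta,
                        file.path(d, "out.vcf.gz"),
                        metadata = study_metadata("trait_1",
                                                  sample_size = 50000L),
                        assembly = "synthA")
rep
#> GWAS-VCF conversion report
#>   output: .../out.vcf.gz
#>   rows read 510 | emitted 505 | rejected at ingest 5
#>   harmonisation: incompatible=5, swapped=68, unchanged=432
#>   written 500 record(s) at 500 variant(s); excluded 5
```

Reading the report: 510 table rows were read; 5 were structurally malformed
and rejected with per-line reasons; 68 rows arrived with effect/other
alleles exchanged and were swapped back (effect sizes negated, frequencies
complemented); 5 rows matched neither reference allele and were excluded.
The output is BGZF-compressed, sorted, and indexed (`.tbi` + `.rsidx`).

```r
validate_gwasvcf(file.path(d, "out.vcf.gz"))
#>            check  pass                         detail
#> 1:        header  TRUE 2 contig(s), 1 trait column(s)
#> 2:       records  TRUE            500 record(s) valid
#> 3: id_uniqueness  TRUE        all non-null IDs unique
#> 4:    sort_order  TRUE          karyotypically sorted

query_interval(file.path(d, "out.vcf.gz"), "1", 1, 60000)   # 299 records
query_rsid(file.path(d, "out.vcf.gz"), "rs10002")           # 1 record
export_tsv(file.path(d, "out.vcf.gz"))                      # GWAS Catalog headings
```

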