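# Desk-scale query benchmark: indexed GWAS-VCF vs unindexed TSV.
#
# Timings are informational only -- they depend on hardware and file size.
# The one stable qualitative pattern at dense (million-variant) scale is that
# index-assisted classes (single position, rsid, interval) beat a full TSV
# scan, while the P-value class, which no index assists, does not.

tsv_scan <- function(path) {
  fread(path, sep = "\t", header = TRUE, showProgress = FALSE)
}

#' Benchmark query classes on GWAS-VCF vs tabular storage
#'
#' Times four query classes (single chromosome position, rsid, 1-Mb
#' interval, P-value threshold) on two media holding identical records: an
#' indexed BGZF GWAS-VCF and an unindexed TSV (as written by
#' [export_tsv()], long layout, with `rsid` and `p_value` columns). All
#' operations are single-threaded. Query targets are chosen
#' deterministically from the file (the median variant, its rsid, the 1-Mb
#' window starting at it, P < 5e-8).
#'
#' @param path_vcf indexed GWAS-VCF.
#' @param path_tsv TSV with the same records.
#' @param repetitions number of timed repetitions per cell (>= 1).
#' @param p_threshold threshold for the P-value class.
#' @param interval_width interval width in bases (default 1 Mb).
#' @return data.table: `query_class`, `medium`, `reps`, `mean_s`, `ci_lower`,
#'   `ci_upper` (mean elapsed seconds with a 95 percent t-interval), plus
#'   `n_hits` from the verification pass.
#' @export
run_benchmark <- function(path_vcf, path_tsv, repetitions = 3L,
                          p_threshold = 5e-8, interval_width = 1000000L) {
  stopifnot(repetitions >= 1L)
  old_threads <- data.table::getDTthreads()
  setDTthreads(1L)
  on.exit(setDTthreads(old_threads), add = TRUE)

  vcf_recs <- read_gwasvcf(path_vcf)
  tsv <- tsv_scan(path_tsv)
  need <- c("chromosome", "base_pair_location", "effect_allele",
            "other_allele", "rsid", "p_value")
  if (!all(need %in% names(tsv))) {
    stop("TSV lacks required columns: ",
         paste(setdiff(need, names(tsv)), collapse = ", "), call. = FALSE)
  }
  kv <- unique(as.data.table(vcf_recs)[, .(chrom = as.character(chrom), pos,
                                           ref, alt)])
  kt <- unique(tsv[, .(chrom = as.character(chromosome),
                       pos = base_pair_location,
                       ref = other_allele, alt = effect_allele)])
  if (!identical(nrow(kv), nrow(kt)) ||
      nrow(data.table::fsetdiff(kv, kt)) || nrow(data.table::fsetdiff(kt, kv))) {
    stop("record sets differ between '", path_vcf, "' and '", path_tsv,
         "'; benchmark would be meaningless", call. = FALSE)
  }

  key <- kv[order(match(chrom, unique(chrom)), pos)]
  mid <- key[ceiling(nrow(key) / 2L)]
  rs_pool <- as.data.table(vcf_recs)[!is.na(rsid) & chrom == mid$chrom]
  target_rs <- if (nrow(rs_pool)) rs_pool$rsid[ceiling(nrow(rs_pool) / 2L)] else NA
  iv_start <- mid$pos
  iv_end <- iv_start + interval_width - 1L

  tasks <- list(
    position = list(
      vcf = function() query_position(path_vcf, mid$chrom, mid$pos),
      tsv = function() {
        d <- tsv_scan(path_tsv)
        d[chromosome == mid$chrom & base_pair_location == mid$pos]
      }),
    rsid = list(
      vcf = function() query_rsid(path_vcf, target_rs),
      tsv = function() {
        d <- tsv_scan(path_tsv)
        d[rsid == target_rs]
      }),
    interval = list(
      vcf = function() query_interval(path_vcf, mid$chrom, iv_start, iv_end),
      tsv = function() {
        d <- tsv_scan(path_tsv)
        d[chromosome == mid$chrom & base_pair_location >= iv_start &
            base_pair_location <= iv_end]
      }),
    pvalue = list(
      vcf = function() query_pvalue(path_vcf, p_threshold),
      tsv = function() {
        d <- tsv_scan(path_tsv)
        d[!is.na(p_value) & p_value < p_threshold]
      })
  )

  out <- list()
  for (cls in names(tasks)) {
    for (med in c("vcf", "tsv")) {
      f <- tasks[[cls]][[med]]
      hits <- nrow(f())   # verification / warm-up pass
      times <- vapply(seq_len(repetitions), function(i)
        unname(system.time(f())[["elapsed"]]), numeric(1))
      m <- mean(times)
      ci <- if (repetitions > 1L && stats::sd(times) > 0) {
        stats::qt(0.975, repetitions - 1L) * stats::sd(times) / sqrt(repetitions)
      } else 0
      out[[length(out) + 1L]] <- data.table(
        query_class = cls, medium = med, reps = repetitions,
        mean_s = m, ci_lower = m - ci, ci_upper = m + ci, n_hits = hits)
    }
  }
  rbindlist(out)
}
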