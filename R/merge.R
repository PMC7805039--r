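#' Merge single-trait GWAS-VCF files into one multi-trait file
#'
#' Takes the union of loci across the inputs: every trait becomes a sample
#' column, and a trait missing a variant gets null statistics there. All
#' inputs must declare the identical genome assembly and contig list (no
#' liftover is performed), and trait ids must not collide.
#'
#' @param paths character vector of GWAS-VCF files (each may hold one or
#'   more traits).
#' @param out optional output path; when given the merged file is written,
#'   BGZF-compressed, and positionally and rsid-indexed.
#' @return merged [gwas_records()] (invisibly when `out` is given).
#' @export
merge_traits <- function(paths, out = NULL) {
  stopifnot(length(paths) >= 2L)
  inputs <- lapply(paths, read_gwasvcf)

  contigs0 <- attr(inputs[[1L]], "contigs", exact = TRUE)
  assembly0 <- attr(inputs[[1L]], "assembly", exact = TRUE)
  for (i in seq_along(inputs)[-1L]) {
    ci <- attr(inputs[[i]], "contigs", exact = TRUE)
    if (!identical(as.data.frame(ci), as.data.frame(contigs0))) {
      stop("contig lists differ between '", paths[1L], "' and '", paths[i],
           "'", call. = FALSE)
    }
    ai <- attr(inputs[[i]], "assembly", exact = TRUE)
    if (!identical(ai, assembly0)) {
      stop("genome assembly mismatch: '", assembly0, "' vs '", ai, "'",
           call. = FALSE)
    }
  }
  all_traits <- unlist(lapply(inputs, function(x)
    names(attr(x, "traits", exact = TRUE))))
  if (anyDuplicated(all_traits)) {
    stop("trait_id collision across inputs: ",
         paste(unique(all_traits[duplicated(all_traits)]), collapse = ", "),
         call. = FALSE)
  }
  traits <- do.call(c, lapply(inputs, attr, "traits", exact = TRUE))

  long <- rbindlist(lapply(inputs, function(x) {
    dt <- as.data.table(x)
    dt[!(is.na(es) & is.na(se) & is.na(lp) & is.na(eaf) & is.na(ss))]
  }))
  merged <- gwas_records(long, traits = traits, contigs = contigs0,
                         assembly = assembly0)
  merged <- sort_karyotypic(merged)
  if (!is.null(out)) {
    write_gwasvcf(merged, out)
    index_positions(out)
    index_rsids(out)
    return(invisible(merged))
  }
  merged
}
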