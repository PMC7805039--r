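#' Reference genome accessors
#'
#' Harmonisation and indel normalisation need random access to reference
#' bases. Two backends implement the same contract: an indexed FASTA on disk
#' (`ref_fasta()`, backed by [Rsamtools::FaFile]) and an in-memory named
#' character vector (`ref_memory()`, used by the synthetic-data generator and
#' in tests). `ref_fetch()` uses 1-based inclusive coordinates and returns
#' exactly `end - start + 1` bases per request; out-of-range requests are
#' errors, never silent truncations.
#'
#' @param path path to a FASTA file; a `.fai` index is created if absent.
#' @param seqs named character vector of uppercase contig sequences.
#' @return a reference-genome object with methods for [ref_fetch()] and
#'   [ref_contigs()].
#' @name reference_genome
NULL

#' @rdname reference_genome
#' @export
ref_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  if (!file.exists(paste0(path, ".fai"))) Rsamtools::indexFa(path)
  fa <- Rsamtools::FaFile(path)
  si <- Rsamtools::seqinfo(fa)
  contigs <- data.table(name = as.character(GenomeInfoDb::seqnames(si)),
                        length = as.integer(GenomeInfoDb::seqlengths(si)))
  structure(list(fa = fa, contigs = contigs, path = path),
            class = c("fasta_reference", "reference_genome"))
}

#' @rdname reference_genome
#' @export
ref_memory <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  seqs <- toupper(seqs)
  contigs <- data.table(name = names(seqs), length = nchar(seqs))
  structure(list(seqs = seqs, contigs = contigs),
            class = c("mem_reference", "reference_genome"))
}

#' Declared contigs of a reference genome
#' @param ref a reference-genome object.
#' @return data.table with columns `name`, `length` in declaration order.
#' @export
ref_contigs <- function(ref) UseMethod("ref_contigs")

#' @export
ref_contigs.reference_genome <- function(ref) copy(ref$contigs)

#' Fetch reference bases (1-based inclusive)
#'
#' Vectorized over `chrom`, `start`, `end`.
#'
#' @param ref a reference-genome object.
#' @param chrom chromosome names.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @return character vector of uppercase base strings, one per request.
#' @export
ref_fetch <- function(ref, chrom, start, end) UseMethod("ref_fetch")

check_ranges <- function(ref, chrom, start, end) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (!length(chrom)) return(invisible())
  if (any(start < 1L | end < start)) {
    stop("invalid range: need 1 <= start <= end", call. = FALSE)
  }
  idx <- match(chrom, ref$contigs$name)
  if (anyNA(idx)) {
    stop("unknown contig: ", paste(unique(chrom[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(end > ref$contigs$length[idx])) {
    stop("range exceeds contig length", call. = FALSE)
  }
  invisible()
}

#' @export
ref_fetch.mem_reference <- function(ref, chrom, start, end) {
  check_ranges(ref, chrom, start, end)
  if (!length(chrom)) return(character())
  unname(substring(ref$seqs[chrom], start, end))
}

#' @export
ref_fetch.fasta_reference <- function(ref, chrom, start, end) {
  check_ranges(ref, chrom, start, end)
  if (!length(chrom)) return(character())
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  unname(as.character(Rsamtools::scanFa(ref$fa, param = gr)))
}

# fetch that reports NA instead of erroring for ranges off the reference
# (harmonisation maps these to status "not_in_reference")
ref_fetch_safe <- function(ref, chrom, start, end) {
  n <- length(chrom)
  out <- rep(NA_character_, n)
  if (!n) return(out)
  idx <- match(chrom, ref$contigs$name)
  ok <- !is.na(idx) & start >= 1L & end >= start & end <= ref$contigs$length[idx]
  if (any(ok)) out[ok] <- ref_fetch(ref, chrom[ok], start[ok], end[ok])
  out
}

#' Apply a variant to a contig sequence
#'
#' Replaces the bases at `pos .. pos + nchar(ref_allele) - 1` with
#' `alt_allele` and returns the edited haplotype. Used to check that two
#' spellings of one indel describe the same edit (haplotype conservation).
#'
#' @param seq contig sequence (character scalar).
#' @param pos 1-based position of the first replaced base.
#' @param ref_allele bases being replaced (must match `seq` at `pos`).
#' @param alt_allele replacement bases.
#' @return edited sequence (character scalar).
#' @export
apply_variant <- function(seq, pos, ref_allele, alt_allele) {
  stopifnot(length(seq) == 1L, pos >= 1L,
            pos + nchar(ref_allele) - 1L <= nchar(seq))
  if (substring(seq, pos, pos + nchar(ref_allele) - 1L) != ref_allele) {
    stop("ref allele does not match sequence at pos ", pos, call. = FALSE)
  }
  paste0(substring(seq, 1L, pos - 1L), alt_allele,
         substring(seq, pos + nchar(ref_allele), nchar(seq)))
}
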