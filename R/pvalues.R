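#' Convert P values to -log10 scale (LP)
#'
#' GWAS-VCF stores association significance per trait as LP = -log10(P)
#' rather than P itself, which keeps genome-wide significant values
#' (P < 5e-8 and far below) representable without floating-point underflow.
#'
#' A P value of exactly 0 -- produced by upstream tools whose own arithmetic
#' underflowed -- cannot be mapped to a finite LP. It is stored as `lp_cap`
#' (default 999) with a warning, which preserves the "most significant"
#' ranking without inventing precision.
#'
#' @param p numeric vector of P values in \[0, 1\]. `NA` passes through.
#' @param lp_cap value substituted for p = 0.
#' @return numeric vector of LP values (>= 0).
#' @examples
#' lp_from_p(c(1, 0.01, 5e-8))
#' @seealso [p_from_lp()]
#' @export
lp_from_p <- function(p, lp_cap = 999) {
  stopifnot(is.numeric(p))
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    stop(sprintf(
      "P value outside [0,1] at position(s) %s (first offending value: %g)",
      paste(utils::head(which(bad), 5L), collapse = ", "), p[which(bad)[1L]]
    ), call. = FALSE)
  }
  zero <- !is.na(p) & p == 0
  if (any(zero)) {
    warning(sprintf(
      "%d P value(s) equal to 0 (upstream underflow); storing LP = %g",
      sum(zero), lp_cap
    ), call. = FALSE)
  }
  out <- -log10(p)
  out[zero] <- lp_cap
  out
}

#' Convert LP (-log10 P) back to a P value
#'
#' @param lp numeric vector of -log10 P values (>= 0). `NA` passes through.
#' @return numeric vector of P values.
#' @examples
#' p_from_lp(2)    # 0.01
#' @seealso [lp_from_p()]
#' @export
p_from_lp <- function(lp) {
  stopifnot(is.numeric(lp))
  bad <- !is.na(lp) & lp < 0
  if (any(bad)) stop("LP values must be >= 0", call. = FALSE)
  10^(-lp)
}
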