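# Small shared helpers.

#' Round half away from zero
#'
#' Rounds to the nearest integer with exact halves moving away from zero
#' (so 0.5 -> 1, -0.5 -> -1), unlike [round()]'s round-half-even rule.
#' This is the rounding used for every reported percentage.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
#' @examples
#' round_half_away(c(2.5, -2.5, 2.4))
round_half_away <- function(x) {
  trunc(x + 0.5 * sign(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rs_msg <- function(...) message("[rodsig] ", ...)

stop_input <- function(...) stop(..., call. = FALSE)

# GRanges from 0-based half-open coordinates (BED convention).
gr0 <- function(chrom, start0, end0, ..., seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0), ...)
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

# 0-based start / half-open end of a GRanges.
start0 <- function(gr) GenomicRanges::start(gr) - 1L
end0 <- function(gr) GenomicRanges::end(gr)

# Deterministic (chrom, start) order.
order_gr <- function(gr) {
  order(as.character(GenomicRanges::seqnames(gr)), GenomicRanges::start(gr),
        GenomicRanges::end(gr))
}
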