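## Internal helpers shared across modules.

#' Convert internal 0-based half-open intervals to a GRanges
#'
#' @param df data.frame with columns chrom, start, end and optionally strand.
#' @return A `GenomicRanges::GRanges` (1-based closed, as GRanges requires).
#' @keywords internal
#' @noRd
as_granges0 <- function(df) {
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  strand[!strand %in% c("+", "-")] <- "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

## Reverse complement for plain character vectors of A/C/G/T/N.
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Benjamini-Hochberg adjustment; single choke point so every module uses
## the same correction.
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

## Clamp a numeric vector into [lo, hi].
clamp01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

stop_mc <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
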