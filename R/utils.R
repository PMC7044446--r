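#' Round half away from zero
#'
#' Unlike [round()] (banker's rounding), ties are rounded away from zero:
#' 0.5 -> 1, 2.5 -> 3, -0.5 -> -1. Used when averaged fractional counts must
#' become integer 2x2 tables for the exact test.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# 0-based half-open (chrom,start,end) -> GRanges (1-based closed)
bed_to_granges <- function(chrom, start, end, ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end), ...)
}

# 0-based point positions -> width-1 GRanges
points_to_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, width = 1L))
}
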