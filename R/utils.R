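# Internal helpers shared across modules.
#
# Coordinate convention: every interval inside the package is 0-based,
# half-open [start, end). GenomicRanges is 1-based closed, so conversion
# happens only inside .as_granges()/.from_granges().

#' @importFrom GenomicRanges GRanges reduce findOverlaps
#' @importFrom IRanges IRanges
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Accept either a path to a file or a character vector of raw lines.
.read_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    return(readLines(x))
  }
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

# 0-based half-open data.frame (chrom, start, end) -> GRanges (1-based closed)
.as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

.from_granges <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

.bin_key <- function(chrom, start) paste0(chrom, ":", start)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assert <- function(cond, fmt, ...) if (!cond) .stopf(fmt, ...)
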