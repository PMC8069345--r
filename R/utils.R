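#' Methylated variant of CpG-context 6-mers
#'
#' Replaces every \code{CG} dinucleotide with \code{MG} (all CpGs within one
#' 6-mer share a methylation state; 6-mers mixing methylated and unmethylated
#' CpGs do not exist in the model).
#'
#' @param kmers character vector of 6-mers over {A,C,G,T}.
#' @return character vector of the methylated-context 6-mers.
#' @export
#' @examples
#' methylVariant(c("AACGTT", "CGACGT"))
methylVariant <- function(kmers) gsub("CG", "MG", kmers, fixed = TRUE)

#' Unmethylated variant of a 6-mer (inverse of [methylVariant()])
#' @param kmers character vector of 6-mers possibly containing \code{M}.
#' @return character vector over {A,C,G,T}.
#' @export
unmethylVariant <- function(kmers) gsub("MG", "CG", kmers, fixed = TRUE)

#' Largest-remainder apportionment of n items across classes
#'
#' Splits `n` into integer counts proportional to `fractions`: each class
#' first gets the floor of its quota, remaining items go to the largest
#' fractional remainders (ties broken in class order).
#'
#' @param n integer total.
#' @param fractions numeric vector summing to 1.
#' @return integer vector of counts summing to `n`.
#' @export
#' @examples
#' largestRemainderCounts(100, c(0.3, 0.5, 0.2))
largestRemainderCounts <- function(n, fractions) {
  stopifnot(n >= 0, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must sum to 1")
  quota <- n * fractions
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  counts <- as.integer(base)
  names(counts) <- names(fractions)
  counts
}

# Gene symbols are matched across platforms and species (mouse regeneration
# data vs human sets) by upper-casing and whitespace stripping only.
normalizeSymbols <- function(x) toupper(trimws(as.character(x)))

# Derived sub-seed, kept below 2^31 so it stays a valid R integer.
subSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% 2147483647)
}

# 0-based CpG record positions from a width-1 GRanges
pos0 <- function(gr) GenomicRanges::start(gr) - 1L

newRecords <- function(chrom, pos, platform, coverage, methylated,
                       frequency, n_reads = coverage) {
  gr <- GRanges(chrom, IRanges(pos + 1L, width = 1L), strand = "+")
  mcols(gr)$platform <- platform
  mcols(gr)$n_reads <- as.integer(n_reads)
  mcols(gr)$coverage <- as.integer(coverage)
  mcols(gr)$methylated <- as.integer(methylated)
  mcols(gr)$frequency <- frequency
  gr
}
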