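#' Build a synthetic Gaussian 6-mer current model
#'
#' Enumerates all 4096 6-mers over {A,C,G,T}, draws each mean current
#' uniformly from `meanRange`, and adds for every CpG-containing 6-mer a
#' methylated variant (every \code{CG} replaced by \code{MG}) whose mean is
#' shifted by `delta` pA. With the default `delta = 2 * sigma` each
#' CpG-overlapping event separates the methylated and unmethylated
#' hypotheses by two standard deviations, a realistic per-event signal for
#' pore current models.
#'
#' @param sigma current standard deviation (pA), shared by all 6-mers.
#' @param delta mean-current shift of the methylated variant (pA).
#' @param meanRange range (pA) of the unmethylated 6-mer means.
#' @param seed integer RNG seed.
#' @return A [SixMerModel-class].
#' @export
buildSixMerModel <- function(sigma = 2, delta = 2 * sigma,
                             meanRange = c(60, 120), seed = 1) {
  stopifnot(sigma > 0, length(meanRange) == 2)
  b <- c("A", "C", "G", "T")
  kmers <- do.call(paste0, expand.grid(b, b, b, b, b, b,
                                       stringsAsFactors = FALSE))
  kmers <- sort(kmers)
  withr::with_seed(seed, {
    mu <- stats::runif(length(kmers), meanRange[1], meanRange[2])
  })
  cg <- grepl("CG", kmers, fixed = TRUE)
  params <- data.frame(
    kmer = c(kmers, methylVariant(kmers[cg])),
    level_mean = c(mu, mu[cg] + delta),
    level_stdv = sigma, stringsAsFactors = FALSE)
  methods::new("SixMerModel", params = params)
}

modelLookup <- function(model, kmers, what = c("mean", "sd")) {
  what <- match.arg(what)
  col <- if (what == "mean") "level_mean" else "level_stdv"
  idx <- match(kmers, model@params$kmer)
  if (anyNA(idx))
    stop("6-mer(s) missing from model: ",
         paste(utils::head(unique(kmers[is.na(idx)]), 3), collapse = ", "))
  model@params[[col]][idx]
}

#' Per-read per-site 5mC log-likelihood ratio
#'
#' Sums, over the current events of one CpG site on one read, the natural-log
#' Gaussian density under the methylated (M-context) model minus the density
#' under the unmethylated (C-context) model; events are treated as
#' independent. Positive values favour methylation.
#'
#' @param events data.frame with columns `kmer` (C-context 6-mer) and
#'   `current` (pA); must be non-empty.
#' @param model a [SixMerModel-class] containing both variants of every
#'   event's 6-mer.
#' @return numeric scalar, the log-likelihood ratio (natural log).
#' @export
#' @examples
#' m <- buildSixMerModel(sigma = 1, delta = 2, seed = 1)
#' mu <- modelParams(m)
#' x <- mu$level_mean[mu$kmer == "AACGTT"]
#' scoreSiteLLR(data.frame(kmer = "AACGTT", current = x), m)
scoreSiteLLR <- function(events, model) {
  stopifnot(is(model, "SixMerModel"))
  if (is.null(events) || nrow(events) == 0)
    stop("empty event list: a site observation needs at least one event")
  if (!all(c("kmer", "current") %in% names(events)))
    stop("events need columns kmer and current")
  if (any(!is.finite(events$current)))
    stop("currents must be finite")
  kc <- unmethylVariant(events$kmer)
  km <- methylVariant(kc)
  muC <- modelLookup(model, kc, "mean"); sdC <- modelLookup(model, kc, "sd")
  muM <- modelLookup(model, km, "mean"); sdM <- modelLookup(model, km, "sd")
  sum(stats::dnorm(events$current, muM, sdM, log = TRUE) -
        stats::dnorm(events$current, muC, sdC, log = TRUE))
}

#' Three-way methylation call from a log-likelihood ratio
#'
#' Confident-call extraction: `methylated` when llr >= +threshold,
#' `unmethylated` when llr <= -threshold, else `ambiguous`. The boundary is
#' inclusive (the threshold is the minimum acceptable confidence); the
#' default 2.5 is applied on the natural-log scale.
#'
#' @param llr numeric vector of log-likelihood ratios.
#' @param threshold positive calling threshold (default 2.5).
#' @return character vector of calls.
#' @export
#' @examples
#' callSite(c(2.5, -3, 0.4))
callSite <- function(llr, threshold = 2.5) {
  stopifnot(threshold > 0)
  ifelse(llr >= threshold, "methylated",
         ifelse(llr <= -threshold, "unmethylated", "ambiguous"))
}

#' Call 5mC per read and site from a nanopore event set
#'
#' Groups events by read and site, scores the summed log-likelihood ratio of
#' each group against `model`, and applies the three-way call of
#' [callSite()].
#'
#' @param events data.frame as returned by [simulateNanoporeEvents()]
#'   (columns read_id, chrom, pos, kmer, current).
#' @param model a [SixMerModel-class].
#' @param threshold calling threshold (default 2.5, natural log).
#' @return data.frame with columns read_id, chrom, pos, llr, call.
#' @export
callMethylation <- function(events, model, threshold = 2.5) {
  stopifnot(is(model, "SixMerModel"), threshold > 0)
  if (nrow(events) == 0)
    return(data.frame(read_id = character(0), chrom = character(0),
                      pos = integer(0), llr = numeric(0), call = character(0),
                      stringsAsFactors = FALSE))
  kc <- unmethylVariant(events$kmer)
  km <- methylVariant(kc)
  muC <- modelLookup(model, kc, "mean"); sdC <- modelLookup(model, kc, "sd")
  muM <- modelLookup(model, km, "mean"); sdM <- modelLookup(model, km, "sd")
  contrib <- stats::dnorm(events$current, muM, sdM, log = TRUE) -
    stats::dnorm(events$current, muC, sdC, log = TRUE)
  key <- paste(events$read_id, events$chrom, events$pos, sep = "\r")
  llr <- rowsum(contrib, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- data.frame(read_id = events$read_id[first],
                    chrom = events$chrom[first],
                    pos = events$pos[first],
                    llr = llr[match(key[first], rownames(llr)), 1],
                    stringsAsFactors = FALSE)
  out$call <- callSite(out$llr, threshold)
  rownames(out) <- NULL
  out[order(out$chrom, out$pos, out$read_id), , drop = FALSE]
}

#' Aggregate per-read calls into per-site nanopore methylation records
#'
#' Ambiguous calls are excluded from both numerator and denominator:
#' coverage is the number of confident (non-ambiguous) calls and frequency is
#' methylated / coverage. Sites whose calls are all ambiguous are kept with
#' coverage 0 and NA frequency, so promoter read-depth accounting stays
#' explicit; `n_reads` carries the raw read count including ambiguous calls.
#'
#' @param calls data.frame from [callMethylation()].
#' @return GRanges of per-site records with mcols platform ("nanopore"),
#'   n_reads, coverage, methylated, frequency.
#' @export
aggregateNanoporeFrequency <- function(calls) {
  if (nrow(calls) == 0)
    return(newRecords(character(0), integer(0), "nanopore", integer(0),
                      integer(0), numeric(0)))
  key <- paste(calls$chrom, calls$pos, sep = "\r")
  first <- !duplicated(key)
  nReads <- as.vector(rowsum(rep(1L, nrow(calls)), key, reorder = FALSE))
  cov <- as.vector(rowsum((calls$call != "ambiguous") + 0L, key,
                          reorder = FALSE))
  meth <- as.vector(rowsum((calls$call == "methylated") + 0L, key,
                           reorder = FALSE))
  newRecords(calls$chrom[first], calls$pos[first], "nanopore",
             cov, meth, ifelse(cov > 0, meth / cov, NA_real_),
             n_reads = nReads)
}

#' Per-site methylation records from a bisulfite count table
#'
#' Applies the minimum-coverage rule: methylation is only called for sites
#' covered by at least `minCoverage` reads (default 5); shallower sites are
#' dropped. Frequency is methylated_count / total_count.
#'
#' @param table data.frame with columns chrom, pos (0-based), strand,
#'   methylated_count, total_count, platform.
#' @param minCoverage minimum read coverage (default 5).
#' @return GRanges of per-site records with mcols platform, n_reads,
#'   coverage, methylated, frequency.
#' @export
bisulfiteFrequency <- function(table, minCoverage = 5) {
  stopifnot(all(c("chrom", "pos", "methylated_count", "total_count") %in%
                  names(table)))
  if (any(table$methylated_count > table$total_count) ||
      any(table$methylated_count < 0) || any(table$total_count <= 0))
    stop("invalid counts: need 0 <= methylated_count <= total_count")
  keep <- table$total_count >= minCoverage
  t2 <- table[keep, , drop = FALSE]
  platform <- if (nrow(t2)) t2$platform[1] else "wgbs"
  newRecords(t2$chrom, t2$pos, platform, t2$total_count, t2$methylated_count,
             ifelse(t2$total_count > 0,
                    t2$methylated_count / t2$total_count, NA_real_))
}

#' Spearman correlation of per-site frequencies between two platforms
#'
#' Restricts both record sets to sites covered by at least `minCoverage`
#' confident reads, matches sites present in both platforms, and computes the
#' Spearman rank correlation (average ranks for ties) of their methylation
#' frequencies.
#'
#' @param a,b GRanges of per-site records (mcols coverage, frequency).
#' @param minCoverage minimum coverage in each platform (default 5).
#' @return numeric scalar rho.
#' @export
platformSpearman <- function(a, b, minCoverage = 5) {
  a <- a[!is.na(mcols(a)$frequency) & mcols(a)$coverage >= minCoverage]
  b <- b[!is.na(mcols(b)$frequency) & mcols(b)$coverage >= minCoverage]
  hits <- suppressWarnings(findOverlaps(a, b, type = "equal"))
  if (length(hits) < 3)
    stop("need at least 3 shared sites after coverage filtering, got ",
         length(hits))
  fa <- mcols(a)$frequency[S4Vectors::queryHits(hits)]
  fb <- mcols(b)$frequency[S4Vectors::subjectHits(hits)]
  stats::cor(fa, fb, method = "spearman")
}
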