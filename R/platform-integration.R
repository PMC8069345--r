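#' Compare hypermethylated gene sets between nanopore and WGBS
#'
#' Exact set algebra on normalized gene symbols. The overlap percent is
#' denominated on the nanopore set (100 * |shared| / |nanopore|), reported to
#' the nearest integer percent; it is NA (with a warning) when the nanopore
#' set is empty.
#'
#' @param nanopore,wgbs character vectors of hypermethylated gene symbols.
#' @return A [GeneSetComparison-class].
#' @export
#' @examples
#' compareGeneSets(c("A", "B", "C"), c("B", "C", "D"))
compareGeneSets <- function(nanopore, wgbs) {
  nano <- unique(normalizeSymbols(nanopore))
  wg <- unique(normalizeSymbols(wgbs))
  shared <- intersect(nano, wg)
  ov <- if (length(nano) == 0) {
    warning("empty nanopore gene set: overlap percent undefined")
    NA_real_
  } else round(100 * length(shared) / length(nano))
  methods::new("GeneSetComparison",
               nanopore = sort(nano), wgbs = sort(wg), shared = sort(shared),
               nanoporeOnly = sort(setdiff(nano, wg)),
               wgbsOnly = sort(setdiff(wg, nano)),
               overlapPercent = ov)
}

#' Confirm shared hypermethylated genes with targeted EPIC calls
#'
#' Intersects the nanopore-and-WGBS shared gene set with the EPIC-derived
#' hypermethylated gene set; genes whose promoters fall outside the EPIC
#' capture target can never be confirmed.
#'
#' @param shared character gene vector (or a [GeneSetComparison-class], whose
#'   shared slot is used).
#' @param epic character vector of EPIC hypermethylated genes.
#' @return sorted character vector of confirmed genes.
#' @export
confirmWithEpic <- function(shared, epic) {
  if (is(shared, "GeneSetComparison")) shared <- shared@shared
  sort(intersect(unique(normalizeSymbols(shared)),
                 unique(normalizeSymbols(epic))))
}

#' Flag putative hydroxymethylated (5hmC) genes among WGBS-only calls
#'
#' A WGBS-only hypermethylated gene is flagged as putatively
#' hydroxymethylated when its best-covered promoter has at least `minReads`
#' nanopore reads yet a mean nanopore 5mC frequency of at most `lowFreq`:
#' bisulfite reads 5hmC as methylated while the nanopore 5mC caller does
#' not, so adequately covered promoters with no or low 5mC signal point to
#' 5hmC. Genes below the read threshold are reported as "insufficient
#' coverage" rather than "not 5hmC". A gene's depth and frequency are those
#' of its maximally covered promoter; a covered promoter with no confident
#' calls counts as zero observed 5mC frequency.
#'
#' @param genes character, the WGBS-only hypermethylated genes.
#' @param promoterStats data.frame with columns gene, promoter_id,
#'   read_depth, mean_frequency (nanopore; e.g. `profileInfo()` of the
#'   nanopore [PromoterProfiles-class]).
#' @param minReads minimum nanopore reads (default 5).
#' @param lowFreq maximum mean 5mC frequency (default 0.1).
#' @return data.frame with gene, read_depth, mean_frequency, flagged,
#'   reason (flagged_5hmC / methylation_detected / insufficient_coverage).
#' @export
flagPutative5hmC <- function(genes, promoterStats, minReads = 5,
                             lowFreq = 0.1) {
  stopifnot(minReads >= 0, lowFreq >= 0,
            all(c("gene", "read_depth", "mean_frequency") %in%
                  names(promoterStats)))
  genes <- unique(normalizeSymbols(genes))
  ps <- promoterStats
  ps$gene <- normalizeSymbols(ps$gene)
  out <- data.frame(gene = genes, read_depth = 0L,
                    mean_frequency = NA_real_, flagged = FALSE,
                    reason = "insufficient_coverage",
                    stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    rows <- which(ps$gene == genes[i])
    if (!length(rows)) next
    best <- rows[which.max(ps$read_depth[rows])]
    depth <- ps$read_depth[best]
    freq <- ps$mean_frequency[best]
    obsFreq <- if (is.na(freq)) 0 else freq  # no confident 5mC calls at all
    out$read_depth[i] <- depth
    out$mean_frequency[i] <- freq
    if (depth < minReads) {
      out$reason[i] <- "insufficient_coverage"
    } else if (obsFreq <= lowFreq) {
      out$flagged[i] <- TRUE
      out$reason[i] <- "flagged_5hmC"
    } else {
      out$reason[i] <- "methylation_detected"
    }
  }
  out
}
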