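#' Strand-aware promoter windows around TSSs
#'
#' Builds promoter ranges covering, in 0-based coordinates, positions
#' `[tss - upstream, tss + downstream)` on the plus strand and the mirrored
#' half-open window `(tss - downstream, tss + upstream]` on the minus strand
#' (upstream always means 5' of the TSS on the annotated strand).
#'
#' @param chrom character chromosome names.
#' @param tss0 integer 0-based TSS positions.
#' @param strand "+" or "-".
#' @param upstream,downstream window extent in bp (defaults 1000 / 500).
#' @param promoterId,gene identifiers stored as mcols.
#' @return GRanges with mcols promoter_id, gene, tss0.
#' @export
promoterWindows <- function(chrom, tss0, strand, upstream = 1000,
                            downstream = 500,
                            promoterId = sprintf("P%04d", seq_along(tss0)),
                            gene = promoterId) {
  stopifnot(length(tss0) == length(strand), all(strand %in% c("+", "-")))
  start1 <- ifelse(strand == "+", tss0 - upstream + 1L,
                   tss0 - downstream + 2L)
  end1 <- ifelse(strand == "+", tss0 + downstream, tss0 + upstream + 1L)
  gr <- GRanges(chrom, IRanges(start1, end1), strand = strand)
  mcols(gr)$promoter_id <- promoterId
  mcols(gr)$gene <- gene
  mcols(gr)$tss0 <- as.integer(tss0)
  gr
}

#' Assign CpG methylation records to promoter windows
#'
#' A site belongs to a promoter iff its position falls in the half-open,
#' strand-mirrored window (see [promoterWindows()]). A site may belong to
#' more than one promoter when windows overlap. Records on chromosomes
#' unknown to the promoter annotation are skipped with a warning.
#'
#' @param records GRanges of per-site records.
#' @param promoters GRanges of promoter windows (mcol promoter_id).
#' @return data.frame with columns promoter_id and site (index into
#'   `records`).
#' @export
assignSitesToPromoters <- function(records, promoters) {
  recChrom <- unique(as.character(seqnames(records)))
  promChrom <- unique(as.character(seqnames(promoters)))
  unknown <- setdiff(recChrom, promChrom)
  if (length(unknown))
    warning("records on chromosome(s) unknown to the promoter annotation ",
            "skipped: ", paste(unknown, collapse = ", "))
  hits <- suppressWarnings(findOverlaps(records, promoters,
                                        ignore.strand = TRUE))
  data.frame(
    promoter_id = mcols(promoters)$promoter_id[S4Vectors::subjectHits(hits)],
    site = S4Vectors::queryHits(hits), stringsAsFactors = FALSE)
}

#' Select hypermethylated CpG sites
#'
#' Keeps sites with a methylation frequency of more than `freqThreshold`
#' (strictly greater than; a site at exactly 50% is excluded).
#'
#' @param records GRanges of per-site records (mcol frequency).
#' @param freqThreshold frequency cutoff (default 0.5).
#' @return GRanges subset of hypermethylated sites.
#' @export
selectHypermethylatedSites <- function(records, freqThreshold = 0.5) {
  f <- mcols(records)$frequency
  records[!is.na(f) & f > freqThreshold]
}

#' Binned hypermethylation profiles per promoter
#'
#' For each promoter window (split into `nBins` strand-oriented bins, bin 1
#' most upstream) the feature is the fraction of covered CpG sites in the bin
#' that are hypermethylated (frequency > `freqThreshold`). Bins without
#' covered sites are imputed with the promoter-wide hypermethylated
#' fraction. Promoters with fewer than `minSites` covered sites are flagged
#' unclassifiable (NA feature rows). `read_depth` is the maximum raw read
#' count over the promoter's covered sites and `mean_frequency` the mean
#' site frequency.
#'
#' @param records GRanges of per-site records.
#' @param promoters GRanges of promoter windows (mcols promoter_id, gene,
#'   tss0).
#' @param nBins number of window bins (default 20).
#' @param minSites minimum covered sites for classifiability (default 3).
#' @param freqThreshold hypermethylated-site cutoff (default 0.5).
#' @return A [PromoterProfiles-class].
#' @export
buildProfiles <- function(records, promoters, nBins = 20, minSites = 3,
                          freqThreshold = 0.5) {
  stopifnot(nBins >= 1, minSites >= 1)
  nP <- length(promoters)
  pid <- mcols(promoters)$promoter_id
  gene <- mcols(promoters)$gene
  w <- GenomicRanges::width(promoters)
  features <- matrix(NA_real_, nrow = nP, ncol = nBins,
                     dimnames = list(pid, NULL))
  nSites <- integer(nP); meanFreq <- rep(NA_real_, nP); depth <- integer(nP)
  map <- assignSitesToPromoters(records, promoters)
  if (nrow(map)) {
    pidx <- match(map$promoter_id, pid)
    freq <- mcols(records)$frequency[map$site]
    nr <- mcols(records)$n_reads
    if (is.null(nr)) nr <- mcols(records)$coverage
    nr <- nr[map$site]
    covered <- !is.na(freq)
    p0 <- pos0(records)[map$site]
    str <- as.character(strand(promoters))[pidx]
    st0 <- start(promoters)[pidx] - 1L
    en0 <- end(promoters)[pidx]            # 0-based exclusive end
    off <- ifelse(str == "+", p0 - st0, (en0 - 1L) - p0)
    bin <- pmin(floor(off * nBins / w[pidx]), nBins - 1L) + 1L
    for (i in seq_len(nP)) {
      sel <- which(pidx == i)
      depth[i] <- if (length(sel)) max(nr[sel], 0L) else 0L
      selc <- sel[covered[sel]]
      nSites[i] <- length(selc)
      if (length(selc) == 0) next
      meanFreq[i] <- mean(freq[selc])
      hyper <- freq[selc] > freqThreshold
      nb <- tabulate(bin[selc], nBins)
      hb <- rowsum(hyper + 0, bin[selc])
      hcount <- numeric(nBins)
      hcount[as.integer(rownames(hb))] <- hb[, 1]
      feat <- ifelse(nb > 0, hcount / pmax(nb, 1), mean(hyper))
      features[i, ] <- feat
    }
  }
  classifiable <- nSites >= minSites
  features[!classifiable, ] <- NA_real_
  info <- data.frame(promoter_id = pid, gene = gene, n_sites = nSites,
                     mean_frequency = meanFreq, read_depth = depth,
                     classifiable = classifiable, stringsAsFactors = FALSE)
  methods::new("PromoterProfiles", features = features, info = info)
}

#' Two-class k-means of promoter hypermethylation profiles
#'
#' Clusters the classifiable profiles into hyper- and hypomethylated classes
#' with Lloyd's algorithm (Euclidean distance), seeded by farthest-point
#' initialisation (a random first centre, then the profile farthest from
#' it); the best of `nRestarts` restarts by within-cluster sum of squares is
#' kept and the run is deterministic for a fixed seed. The cluster with the
#' larger centroid mean is labelled hyper. If all profiles are identical a
#' single-cluster warning is emitted and every promoter is labelled by its
#' mean feature versus 0.5.
#'
#' @param profiles a [PromoterProfiles-class].
#' @param k number of clusters; only 2 is supported.
#' @param nRestarts number of seeded restarts (default 10).
#' @param seed integer RNG seed.
#' @return A [PromoterClassification-class]; unclassifiable promoters get NA
#'   labels.
#' @export
kmeansClassify <- function(profiles, k = 2, nRestarts = 10, seed = 1) {
  stopifnot(is(profiles, "PromoterProfiles"), k == 2, nRestarts >= 1)
  info <- profiles@info
  x <- profiles@features[info$classifiable, , drop = FALSE]
  if (nrow(x) < 2)
    stop("need at least 2 classifiable profiles, got ", nrow(x))
  labels <- rep(NA_character_, nrow(info))
  if (max(stats::dist(x)) == 0) {
    warning("all profiles identical: single-cluster degenerate case, ",
            "labelling by mean feature vs 0.5")
    lab <- ifelse(rowMeans(x) > 0.5, "hyper", "hypo")
    labels[info$classifiable] <- lab
    cen <- rbind(colMeans(x), colMeans(x))
    return(methods::new("PromoterClassification",
                        labels = data.frame(promoter_id = info$promoter_id,
                                            gene = info$gene, label = labels,
                                            stringsAsFactors = FALSE),
                        centroids = cen, centroidMeans = rowMeans(cen)))
  }
  best <- NULL
  for (r in seq_len(nRestarts)) {
    centers <- withr::with_seed(subSeed(seed, r), {
      i1 <- sample.int(nrow(x), 1)
      d <- rowSums(sweep(x, 2, x[i1, ])^2)
      rbind(x[i1, ], x[which.max(d), ])
    })
    km <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = centers, iter.max = 100,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss))
      best <- km
  }
  if (is.null(best)) stop("k-means failed in all restarts")
  hyperCluster <- which.max(rowMeans(best$centers))
  lab <- ifelse(best$cluster == hyperCluster, "hyper", "hypo")
  labels[info$classifiable] <- lab
  cen <- best$centers[c(hyperCluster, 3 - hyperCluster), , drop = FALSE]
  methods::new("PromoterClassification",
               labels = data.frame(promoter_id = info$promoter_id,
                                   gene = info$gene, label = labels,
                                   stringsAsFactors = FALSE),
               centroids = cen, centroidMeans = rowMeans(cen))
}

#' Collapse promoter labels to a hypermethylated gene set
#'
#' A gene is hypermethylated iff at least one of its promoters is labelled
#' hyper (OR-logic over alternative promoters), so the gene count is at most
#' the hyper promoter count.
#'
#' @param classification a [PromoterClassification-class].
#' @return list with `genes` (sorted character), `nHyperPromoters` and
#'   `nGenes`.
#' @export
collapseToGenes <- function(classification) {
  lab <- classification@labels
  hyper <- lab$label == "hyper" & !is.na(lab$label)
  genes <- sort(unique(normalizeSymbols(lab$gene[hyper])))
  list(genes = genes, nHyperPromoters = sum(hyper), nGenes = length(genes))
}

#' Average methylation metaplot around TSSs
#'
#' Bins the strand-oriented distance of every covered CpG record to every
#' TSS within `span` bp and averages the site frequencies per bin; the
#' genome-wide dip of methylation at transcription start sites shows up as
#' central bins below the flanks.
#'
#' @param records GRanges of per-site records.
#' @param promoters GRanges with mcols tss0 and strand.
#' @param span half-width of the metaplot window in bp (default 2000).
#' @param nBins number of distance bins (default 80).
#' @return data.frame with bin, center (oriented bp relative to the TSS),
#'   mean_frequency (NA for empty bins) and n_sites.
#' @export
tssMetaplot <- function(records, promoters, span = 2000, nBins = 80) {
  stopifnot(span > 0, nBins >= 2)
  tss0 <- mcols(promoters)$tss0
  win <- GRanges(seqnames(promoters),
                 IRanges(pmax(tss0 - span + 1L, 1L), tss0 + span + 1L))
  binw <- 2 * span / nBins
  centers <- -span + (seq_len(nBins) - 0.5) * binw
  out <- data.frame(bin = seq_len(nBins), center = centers,
                    mean_frequency = NA_real_, n_sites = 0L)
  if (length(records) == 0 || length(promoters) == 0) return(out)
  hits <- suppressWarnings(findOverlaps(records, win, ignore.strand = TRUE))
  if (length(hits) == 0) return(out)
  ri <- S4Vectors::queryHits(hits); pi <- S4Vectors::subjectHits(hits)
  freq <- mcols(records)$frequency[ri]
  ok <- !is.na(freq)
  ri <- ri[ok]; pi <- pi[ok]; freq <- freq[ok]
  d <- pos0(records)[ri] - tss0[pi]
  neg <- as.character(strand(promoters))[pi] == "-"
  d[neg] <- -d[neg]
  keep <- d >= -span & d < span
  d <- d[keep]; freq <- freq[keep]
  if (length(d) == 0) return(out)
  bin <- floor((d + span) / binw) + 1L
  out$n_sites <- tabulate(bin, nBins)
  sums <- rowsum(freq, bin)
  out$mean_frequency[as.integer(rownames(sums))] <-
    sums[, 1] / out$n_sites[as.integer(rownames(sums))]
  out
}
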