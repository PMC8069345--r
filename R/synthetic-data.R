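#' Generate a toy genome with CpG islands and non-overlapping promoters
#'
#' Builds a small random genome in which CpG dinucleotides occur only at the
#' annotated sites: the background sequence is sampled over {A,C,G,T} with
#' accidental \code{CG} dinucleotides removed, then \code{CG} is planted at
#' every drawn site. CpG sites arise per-position with probability
#' `cpgDensity`, elevated `islandFactor`-fold inside promoter windows to mimic
#' CpG islands (capped at 0.3/bp); consecutive sites keep >= 2 bp spacing so
#' planted dinucleotides never overlap. Promoter windows of
#' `windowUp + windowDown` bp are placed uniformly without overlap, with a
#' random strand; the TSS sits `windowUp` bp into the window on the annotated
#' strand.
#'
#' @param nChrom number of chromosomes.
#' @param chromLength length (bp) of each chromosome.
#' @param nGenes total number of genes (one promoter each), split across
#'   chromosomes.
#' @param cpgDensity per-bp CpG probability outside promoters.
#' @param islandFactor CpG enrichment inside promoter windows (default 10).
#' @param windowUp,windowDown promoter window extent (bp) upstream/downstream
#'   of the TSS.
#' @param seed integer RNG seed; identical seeds give identical genomes.
#' @return A [ToyGenome-class].
#' @export
#' @examples
#' g <- generateToyGenome(1, 50000, 5, 0.01, seed = 1)
#' g
generateToyGenome <- function(nChrom = 1, chromLength = 2e5, nGenes = 40,
                              cpgDensity = 0.005, islandFactor = 10,
                              windowUp = 1000, windowDown = 500, seed = 1) {
  stopifnot(nChrom >= 1, chromLength >= 10, nGenes >= 0,
            cpgDensity >= 0, cpgDensity <= 0.3, islandFactor >= 1)
  w <- windowUp + windowDown
  geneChrom <- if (nGenes > 0) rep(seq_len(nChrom), length.out = nGenes) else
    integer(0)
  withr::with_seed(seed, {
    seqs <- character(nChrom)
    siteChrom <- character(0); sitePos <- integer(0)
    promChrom <- character(0); promStart0 <- integer(0)
    promStrand <- character(0); promTss0 <- integer(0); promGene <- integer(0)
    for (ci in seq_len(nChrom)) {
      L <- as.integer(chromLength)
      cname <- paste0("chr", ci)
      genesHere <- which(geneChrom == ci)
      k <- length(genesHere)
      starts <- integer(0); strands <- character(0)
      if (k > 0) {
        slack <- L - k * w
        if (slack < 0)
          stop("cannot place ", k, " non-overlapping promoters of ", w,
               " bp on a ", L, " bp chromosome")
        cuts <- sort(stats::runif(k, 0, slack))
        starts <- as.integer(floor(cuts) + (seq_len(k) - 1L) * w)
        strands <- sample(c("+", "-"), k, replace = TRUE)
      }
      tss0 <- ifelse(strands == "+", starts + windowUp,
                     starts + w - 1L - windowUp)
      # per-position CpG rate, island-elevated inside promoter windows
      rate <- rep(cpgDensity, L)
      for (s in starts)
        rate[(s + 1L):(s + w)] <- min(cpgDensity * islandFactor, 0.3)
      pos <- which(stats::runif(L) < rate) - 1L
      pos <- pos[pos <= L - 2L]
      if (length(pos) > 1) {           # enforce >= 2 bp spacing
        keep <- logical(length(pos)); last <- -10L
        for (i in seq_along(pos)) {
          if (pos[i] - last >= 2L) { keep[i] <- TRUE; last <- pos[i] }
        }
        pos <- pos[keep]
      }
      # sequence without accidental CpGs, then plant the annotated ones
      s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      acc <- which(s[-L] == "C" & s[-1] == "G")
      if (length(acc)) s[acc + 1L] <- "A"
      if (length(pos)) { s[pos + 1L] <- "C"; s[pos + 2L] <- "G" }
      seqs[ci] <- paste(s, collapse = "")
      siteChrom <- c(siteChrom, rep(cname, length(pos)))
      sitePos <- c(sitePos, pos)
      promChrom <- c(promChrom, rep(cname, k))
      promStart0 <- c(promStart0, starts)
      promStrand <- c(promStrand, strands)
      promTss0 <- c(promTss0, as.integer(tss0))
      promGene <- c(promGene, genesHere)
    }
    genes <- if (nGenes > 0) sprintf("TG%04d", seq_len(nGenes)) else
      character(0)
    lens <- stats::setNames(rep(as.integer(chromLength), nChrom),
                            paste0("chr", seq_len(nChrom)))
    sites <- GRanges(siteChrom, IRanges(sitePos + 1L, width = 1L),
                     strand = rep("+", length(sitePos)), seqlengths = lens)
    mcols(sites)$pos0 <- sitePos
    proms <- GRanges(promChrom, IRanges(promStart0 + 1L, width = w),
                     strand = promStrand, seqlengths = lens)
    mcols(proms)$promoter_id <- sprintf("P%04d", seq_along(proms))
    mcols(proms)$gene <- genes[promGene]
    mcols(proms)$tss0 <- promTss0
    dna <- DNAStringSet(seqs)
    names(dna) <- names(lens)
    methods::new("ToyGenome", chromLengths = lens, sequence = dna,
                 sites = sites, promoters = proms, genes = genes,
                 windowUp = windowUp, windowDown = windowDown)
  })
}

#' Assign a ground-truth methylation landscape to a toy genome
#'
#' Promoters are apportioned to the three classes by largest-remainder
#' rounding of `fractions` and assigned in random order. CpG sites inside a
#' hyper5mC promoter are methylated with probability `pIn`; inside hypo
#' promoters with probability `pOut`; inside hyper5hmC promoters they are
#' hydroxymethylated with probability `pIn` (otherwise unmethylated).
#' Background sites outside promoters are methylated with probability
#' `bgMeth`, emulating the broadly methylated genomic background against
#' which promoters stand out.
#'
#' @param genome a [ToyGenome-class].
#' @param fractions length-3 numeric (hyper5mC, hypo, hyper5hmC) summing to 1.
#' @param pIn,pOut in-class / out-of-class per-site state probabilities.
#' @param bgMeth methylation probability of non-promoter background sites.
#' @param seed integer RNG seed.
#' @return A [MethylationLandscape-class].
#' @export
assignLandscape <- function(genome,
                            fractions = c(hyper5mC = 0.3, hypo = 0.5,
                                          hyper5hmC = 0.2),
                            pIn = 0.9, pOut = 0.05, bgMeth = 0.8, seed = 1) {
  stopifnot(is(genome, "ToyGenome"), length(fractions) == 3)
  probs <- c(pIn, pOut, bgMeth)
  if (any(probs < 0) || any(probs > 1) || any(fractions < 0) ||
      any(fractions > 1))
    stop("probabilities must lie in [0, 1]")
  proms <- genome@promoters
  sites <- genome@sites
  nP <- length(proms)
  counts <- largestRemainderCounts(nP, fractions)
  withr::with_seed(seed, {
    cls <- rep(PROMOTER_CLASSES, counts)[sample.int(max(nP, 1))[seq_len(nP)]]
    promClass <- factor(cls, levels = PROMOTER_CLASSES)
    names(promClass) <- mcols(proms)$promoter_id
    hits <- findOverlaps(sites, proms, select = "first",
                         ignore.strand = TRUE)
    state <- character(length(sites))
    u <- stats::runif(length(sites))
    bg <- is.na(hits)
    state[bg] <- ifelse(u[bg] < bgMeth, "methylated_5mC", "unmethylated")
    inP <- which(!is.na(hits))
    pcls <- as.character(promClass[hits[inP]])
    state[inP] <- ifelse(
      pcls == "hyper5mC",
      ifelse(u[inP] < pIn, "methylated_5mC", "unmethylated"),
      ifelse(pcls == "hypo",
             ifelse(u[inP] < pOut, "methylated_5mC", "unmethylated"),
             ifelse(u[inP] < pIn, "hydroxymethylated_5hmC", "unmethylated")))
    methods::new("MethylationLandscape",
                 siteState = factor(state, levels = SITE_STATES),
                 promoterClass = promClass,
                 fractions = fractions,
                 params = list(p_in = pIn, p_out = pOut, bg_meth = bgMeth))
  })
}

# 6-mers (start offsets, 0-based) containing the full CpG dinucleotide,
# clipped at chromosome ends: starts in [pos-4, pos] n [0, L-6]. A 6-mer
# holding only the terminal C of the CpG carries no representable
# methylation state, so the event window is the 5 dinucleotide-spanning
# frames.
siteKmerTable <- function(genome, siteIdx = seq_along(genome@sites)) {
  sites <- genome@sites[siteIdx]
  chrom <- as.character(seqnames(sites))
  pos <- mcols(sites)$pos0
  L <- genome@chromLengths[chrom]
  off <- rep(0:4, each = length(sites))
  si <- rep(seq_along(sites), times = 5)
  s0 <- pos[si] - 4L + off
  ok <- s0 >= 0L & (s0 + 6L) <= L[si]
  si <- si[ok]; s0 <- s0[ok]
  seqstr <- as.character(genome@sequence)
  kmer <- substring(seqstr[chrom[si]], s0 + 1L, s0 + 6L)
  data.frame(site = siteIdx[si], kmer = kmer, stringsAsFactors = FALSE)
}

#' Simulate per-read nanopore current events at CpG sites
#'
#' Read depth is Poisson(`meanCoverage`) per site; sites within one promoter
#' share a single per-promoter Poisson draw (so promoter read depth is
#' well-defined), background sites draw independently. Each read of a site
#' yields one current event per 6-mer spanning the CpG dinucleotide (up to
#' 5, fewer at chromosome ends). Events at truly methylated (5mC) sites are
#' drawn from the M-context Gaussians of `model`; unmethylated sites from the
#' C-context Gaussians. Hydroxymethylated (5hmC) sites also emit from the
#' C-context Gaussians: the 5mC caller then sees no methylation signal there,
#' which is exactly the observable that separates 5hmC from 5mC when
#' contrasted with bisulfite counts.
#'
#' @param landscape a [MethylationLandscape-class].
#' @param genome the matching [ToyGenome-class].
#' @param model a [SixMerModel-class] covering all 6-mers of the genome.
#' @param meanCoverage mean reads per site.
#' @param seed integer RNG seed.
#' @return data.frame with columns read_id, chrom, pos (0-based), kmer
#'   (C-context 6-mer), current (pA).
#' @export
simulateNanoporeEvents <- function(landscape, genome, model,
                                   meanCoverage = 10, seed = 1) {
  stopifnot(is(landscape, "MethylationLandscape"), is(genome, "ToyGenome"),
            is(model, "SixMerModel"), meanCoverage >= 0)
  sites <- genome@sites
  empty <- data.frame(read_id = character(0), chrom = character(0),
                      pos = integer(0), kmer = character(0),
                      current = numeric(0), stringsAsFactors = FALSE)
  if (length(sites) == 0 || meanCoverage == 0) return(empty)
  state <- as.character(landscape@siteState)
  stopifnot(length(state) == length(sites))
  prom <- findOverlaps(sites, genome@promoters, select = "first",
                       ignore.strand = TRUE)
  mu <- stats::setNames(model@params$level_mean, model@params$kmer)
  sdv <- stats::setNames(model@params$level_stdv, model@params$kmer)
  withr::with_seed(seed, {
    promDepth <- stats::rpois(length(genome@promoters), meanCoverage)
    depth <- ifelse(is.na(prom), stats::rpois(length(sites), meanCoverage),
                    promDepth[prom])
    kt <- siteKmerTable(genome)
    missing <- setdiff(unique(c(kt$kmer, methylVariant(kt$kmer))),
                       model@params$kmer)
    if (length(missing))
      stop("6-mer(s) missing from model: ",
           paste(utils::head(missing, 3), collapse = ", "))
    reads <- data.frame(site = rep(seq_along(sites), depth),
                        read = sequence(depth))
    ev <- merge(reads, kt, by = "site", sort = FALSE)
    if (nrow(ev) == 0) return(empty)
    obsKmer <- ifelse(state[ev$site] == "methylated_5mC",
                      methylVariant(ev$kmer), ev$kmer)
    current <- stats::rnorm(nrow(ev), mu[obsKmer], sdv[obsKmer])
    chrom <- as.character(seqnames(sites))[ev$site]
    pos <- mcols(sites)$pos0[ev$site]
    out <- data.frame(
      read_id = sprintf("%s:%d/r%d", chrom, pos, ev$read),
      chrom = chrom, pos = pos, kmer = ev$kmer, current = current,
      stringsAsFactors = FALSE)
    out[order(out$chrom, out$pos, out$read_id), , drop = FALSE]
  })
}

#' Simulate bisulfite count tables (WGBS and targeted EPIC)
#'
#' Bisulfite conversion reads both 5mC and 5hmC as methylated: methylated
#' counts are Binomial(total, 1 - `conversionError`) for 5mC and 5hmC sites
#' and Binomial(total, `conversionError`) for unmethylated sites. Per-site
#' totals are Poisson(`meanCoverage`) for WGBS and Poisson(`epicCoverage`)
#' for EPIC; the EPIC table is restricted to a random fraction
#' `epicFraction` of sites (the capture target mask, returned for
#' inspection). Sites with zero sampled reads are omitted.
#'
#' @param landscape a [MethylationLandscape-class].
#' @param genome the matching [ToyGenome-class].
#' @param meanCoverage mean WGBS reads per site.
#' @param conversionError conversion/sequencing error probability (<= 0.05).
#' @param epicFraction fraction of CpG sites on the EPIC capture target.
#' @param epicCoverage mean EPIC reads per targeted site (targeted capture is
#'   sequenced deeper; default 3x the WGBS coverage).
#' @param seed integer RNG seed.
#' @return list with elements `wgbs` and `epic` (data.frames with columns
#'   chrom, pos, strand, methylated_count, total_count, platform) and
#'   `epic_mask` (integer indices of targeted sites in `cpgSites(genome)`).
#' @export
simulateBisulfiteCounts <- function(landscape, genome, meanCoverage = 15,
                                    conversionError = 0.01,
                                    epicFraction = 0.11,
                                    epicCoverage = 3 * meanCoverage,
                                    seed = 1) {
  stopifnot(is(landscape, "MethylationLandscape"), is(genome, "ToyGenome"))
  if (conversionError < 0 || conversionError > 0.05)
    stop("conversionError must lie in [0, 0.05]")
  if (epicFraction < 0 || epicFraction > 1)
    stop("epicFraction must lie in [0, 1]")
  sites <- genome@sites
  state <- as.character(landscape@siteState)
  q <- ifelse(state == "unmethylated", conversionError, 1 - conversionError)
  chrom <- as.character(seqnames(sites))
  pos <- mcols(sites)$pos0
  mk <- function(idx, total, meth, platform) {
    keep <- which(total > 0)
    data.frame(chrom = chrom[idx[keep]], pos = pos[idx[keep]], strand = "+",
               methylated_count = meth[keep], total_count = total[keep],
               platform = platform, stringsAsFactors = FALSE)
  }
  withr::with_seed(seed, {
    n <- length(sites)
    totW <- stats::rpois(n, meanCoverage)
    methW <- stats::rbinom(n, totW, q)
    mask <- sort(sample.int(n, size = round(epicFraction * n)))
    totE <- stats::rpois(length(mask), epicCoverage)
    methE <- stats::rbinom(length(mask), totE, q[mask])
    list(wgbs = mk(seq_len(n), totW, methW, "wgbs"),
         epic = mk(mask, totE, methE, "epic"),
         epic_mask = mask)
  })
}

#' Simulate regeneration and tumor-cohort expression tables
#'
#' Baseline per-gene expression is log-normal (TPM-like arbitrary units).
#' Planted candidate genes are downregulated `fcPh4h`-fold at 4 h
#' post-partial-hepatectomy relative to sham and (when `recovery = TRUE`)
#' return to the sham level at 1 week; in the tumor cohort their median is
#' the normal median divided by `fcTumor`. All values carry multiplicative
#' log-normal noise with coefficient of variation `noiseCv` (mean 1), so
#' non-planted genes are identically distributed across conditions.
#'
#' @param genome a [ToyGenome-class] (supplies the gene universe).
#' @param plantedCandidates character, genes with planted downregulation.
#' @param fcPh4h,fcTumor fold-change divisors (> 1 means downregulated).
#' @param recovery logical; planted genes recover at 1 week post-PH.
#' @param nTumor,nNormal cohort sample sizes (defaults 371 tumors and 50
#'   normal livers, the TCGA liver cohort layout).
#' @param noiseCv coefficient of variation of the multiplicative noise.
#' @param seed integer RNG seed.
#' @return list with `regeneration` (data.frame gene, condition in
#'   sham/ph4h/ph1wk, value) and `cohort` (data.frame gene, sample, group in
#'   normal/tumor, value).
#' @export
simulateExpression <- function(genome, plantedCandidates = character(0),
                               fcPh4h = 4, fcTumor = 4, recovery = TRUE,
                               nTumor = 371, nNormal = 50, noiseCv = 0.2,
                               seed = 1) {
  stopifnot(is(genome, "ToyGenome"), fcPh4h >= 1, fcTumor >= 1, noiseCv >= 0)
  genes <- genome@genes
  planted <- genes %in% normalizeSymbols(plantedCandidates)
  sdlog <- sqrt(log(1 + noiseCv^2))
  noise <- function(n) {
    if (noiseCv == 0) rep(1, n) else
      stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  withr::with_seed(seed, {
    base <- stats::rlnorm(length(genes), meanlog = log(100), sdlog = 0.5)
    sham <- base * noise(length(genes))
    ph4 <- base / ifelse(planted, fcPh4h, 1) * noise(length(genes))
    wk1true <- if (recovery) base else base / ifelse(planted, fcPh4h, 1)
    wk1 <- wk1true * noise(length(genes))
    regen <- data.frame(
      gene = rep(genes, 3),
      condition = rep(c("sham", "ph4h", "ph1wk"), each = length(genes)),
      value = c(sham, ph4, wk1), stringsAsFactors = FALSE)
    nS <- nNormal + nTumor
    grp <- rep(c("normal", "tumor"), c(nNormal, nTumor))
    samp <- sprintf("%s_%03d", grp, c(seq_len(nNormal), seq_len(nTumor)))
    vals <- matrix(rep(base, nS), nrow = length(genes)) *
      matrix(noise(length(genes) * nS), nrow = length(genes))
    tumorCols <- which(grp == "tumor")
    vals[planted, tumorCols] <- vals[planted, tumorCols] / fcTumor
    cohort <- data.frame(
      gene = rep(genes, nS),
      sample = rep(samp, each = length(genes)),
      group = rep(grp, each = length(genes)),
      value = as.vector(vals), stringsAsFactors = FALSE)
    list(regeneration = regen, cohort = cohort)
  })
}
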