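suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

# Minimal two-entry model: one CpG 6-mer and its methylated variant.
tinyModel <- function(muC = 8, muM = 10, sdC = 1, sdM = sdC) {
  methods::new("SixMerModel", params = data.frame(
    kmer = c("AACGTT", "AAMGTT"),
    level_mean = c(muC, muM),
    level_stdv = c(sdC, sdM),
    stringsAsFactors = FALSE))
}

# Per-site record GRanges on one chromosome.
makeRecords <- function(pos, frequency, coverage = 10, chrom = "chr1",
                        platform = "test",
                        methylated = round(frequency * coverage)) {
  n <- length(pos)
  gr <- GRanges(chrom, IRanges(pos + 1L, width = 1L), strand = "+")
  mcols(gr)$platform <- platform
  mcols(gr)$n_reads <- as.integer(rep_len(coverage, n))
  mcols(gr)$coverage <- as.integer(rep_len(coverage, n))
  mcols(gr)$methylated <- as.integer(rep_len(methylated, n))
  mcols(gr)$frequency <- frequency
  gr
}

# Feature-profile set built directly from a matrix (bypasses records).
makeProfiles <- function(features, genes = rownames(features),
                         nSites = rep(10L, nrow(features)),
                         depth = rep(10L, nrow(features))) {
  if (is.null(rownames(features)))
    rownames(features) <- sprintf("P%03d", seq_len(nrow(features)))
  if (is.null(genes)) genes <- rownames(features)
  info <- data.frame(promoter_id = rownames(features), gene = genes,
                     n_sites = nSites,
                     mean_frequency = rowMeans(features),
                     read_depth = depth,
                     classifiable = nSites >= 3, stringsAsFactors = FALSE)
  methods::new("PromoterProfiles", features = features, info = info)
}

# Independent Spearman oracle: average ranks computed by counting, then the
# Pearson product-moment formula applied to the ranks.
bruteSpearman <- function(x, y) {
  avrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2, numeric(1))
  }
  rx <- avrank(x); ry <- avrank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Expression table with planted downregulation, zero noise by default.
makeRegenTable <- function(genes, sham, ph4h, ph1wk) {
  data.frame(gene = rep(genes, 3),
             condition = rep(c("sham", "ph4h", "ph1wk"), each = length(genes)),
             value = c(sham, ph4h, ph1wk), stringsAsFactors = FALSE)
}
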