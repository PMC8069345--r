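#' @import methods
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end strand findOverlaps
#' @importFrom Biostrings DNAStringSet writeXStringSet
NULL

SITE_STATES <- c("methylated_5mC", "unmethylated", "hydroxymethylated_5hmC")
PROMOTER_CLASSES <- c("hyper5mC", "hypo", "hyper5hmC")

#' Gaussian 6-mer current model over the {A,C,G,T,M} alphabet
#'
#' Holds one Gaussian (mean, sd of the ionic current in pA) per 6-mer, with
#' 5-methylcytosine in CpG context written as \code{M}. For every 6-mer that
#' contains a CpG, both the unmethylated (\code{CG}) and the fully methylated
#' (\code{MG}) variant are present; 6-mers mixing an \code{M} with an
#' unmethylated CpG are excluded, so within one 6-mer all CpGs share a state.
#'
#' @slot params data.frame with columns \code{kmer}, \code{level_mean},
#'   \code{level_stdv}.
#' @seealso [buildSixMerModel()], [readSixMerModel()], [scoreSiteLLR()]
#' @export
setClass("SixMerModel", representation(params = "data.frame"))

setValidity("SixMerModel", function(object) {
  p <- object@params
  if (!all(c("kmer", "level_mean", "level_stdv") %in% names(p)))
    return("params needs columns kmer, level_mean, level_stdv")
  if (anyDuplicated(p$kmer)) return("duplicated 6-mer entries")
  if (any(nchar(p$kmer) != 6L)) return("all k-mers must have length 6")
  if (!all(p$level_stdv > 0)) return("level_stdv must be > 0 for every entry")
  bad <- grepl("M", p$kmer, fixed = TRUE) & grepl("CG", p$kmer, fixed = TRUE)
  if (any(bad))
    return("6-mers containing both M and an unmethylated CpG are excluded")
  cg <- p$kmer[grepl("CG", p$kmer, fixed = TRUE)]
  missing <- setdiff(methylVariant(cg), p$kmer)
  if (length(missing))
    return(paste0("missing M-variant(s): ", paste(utils::head(missing, 3),
                                                  collapse = ", ")))
  TRUE
})

#' Toy genome with annotated CpG sites and promoters
#'
#' A small synthetic genome: chromosome sequences (CpG dinucleotides occur
#' only at the annotated sites), CpG site positions, non-overlapping promoter
#' windows around each gene's TSS, and unique gene symbols.
#'
#' @slot chromLengths named numeric, bp per chromosome.
#' @slot sequence DNAStringSet, one entry per chromosome.
#' @slot sites GRanges of CpG cytosines (width 1, mcol \code{pos0} is the
#'   0-based position).
#' @slot promoters GRanges of promoter windows with mcols \code{promoter_id},
#'   \code{gene}, \code{tss0} (0-based TSS).
#' @slot genes character, unique gene symbols.
#' @slot windowUp,windowDown numeric, promoter window extent (bp) upstream /
#'   downstream of the TSS on the annotated strand.
#' @seealso [generateToyGenome()]
#' @export
setClass("ToyGenome", representation(
  chromLengths = "numeric", sequence = "DNAStringSet", sites = "GRanges",
  promoters = "GRanges", genes = "character",
  windowUp = "numeric", windowDown = "numeric"))

setValidity("ToyGenome", function(object) {
  L <- object@chromLengths
  s <- object@sites
  if (length(s)) {
    pos <- mcols(s)$pos0
    if (any(pos < 0) || any(pos >= L[as.character(seqnames(s))]))
      return("CpG positions must lie within chromosome bounds")
  }
  p <- object@promoters
  if (length(p)) {
    if (any(start(p) < 1) || any(end(p) > L[as.character(seqnames(p))]))
      return("promoter windows must lie within chromosome bounds")
  }
  if (anyDuplicated(object@genes)) return("gene symbols must be unique")
  TRUE
})

#' Ground-truth methylation landscape of a toy genome
#'
#' Per-CpG true state (5mC / unmethylated / 5hmC) and per-promoter true class
#' (hyper5mC / hypo / hyper5hmC), aligned with the sites and promoters of the
#' [ToyGenome-class] it was drawn for.
#'
#' @slot siteState factor over methylated_5mC / unmethylated /
#'   hydroxymethylated_5hmC, one per CpG site.
#' @slot promoterClass factor over hyper5mC / hypo / hyper5hmC, named by
#'   promoter id.
#' @slot fractions numeric, the requested class mix.
#' @slot params list of the drawing probabilities (p_in, p_out, bg_meth).
#' @seealso [assignLandscape()]
#' @export
setClass("MethylationLandscape", representation(
  siteState = "factor", promoterClass = "factor",
  fractions = "numeric", params = "list"))

setValidity("MethylationLandscape", function(object) {
  if (!identical(levels(object@siteState), SITE_STATES))
    return("siteState levels must be the three cytosine states")
  if (!identical(levels(object@promoterClass), PROMOTER_CLASSES))
    return("promoterClass levels must be hyper5mC/hypo/hyper5hmC")
  TRUE
})

#' Per-promoter binned hypermethylation profiles
#'
#' @slot features matrix (promoters x bins) of per-bin fractions of
#'   hypermethylated CpG sites; rows of unclassifiable promoters are NA.
#' @slot info data.frame with promoter_id, gene, n_sites, mean_frequency,
#'   read_depth, classifiable.
#' @seealso [buildProfiles()], [kmeansClassify()]
#' @export
setClass("PromoterProfiles",
         representation(features = "matrix", info = "data.frame"))

#' Two-class promoter methylation labels
#'
#' @slot labels data.frame with promoter_id, gene, label (hyper/hypo, NA for
#'   unclassifiable promoters).
#' @slot centroids matrix of the two cluster centroids (hyper row first).
#' @slot centroidMeans numeric, mean of each centroid.
#' @export
setClass("PromoterClassification", representation(
  labels = "data.frame", centroids = "matrix", centroidMeans = "numeric"))

#' Cross-platform hypermethylated gene-set comparison
#'
#' Exact set algebra between the nanopore- and WGBS-derived hypermethylated
#' gene sets: shared genes, platform-exclusive genes, and the overlap percent
#' denominated on the nanopore set.
#'
#' @slot nanopore,wgbs,shared,nanoporeOnly,wgbsOnly character gene vectors.
#' @slot overlapPercent numeric; 100 * |shared| / |nanopore| rounded to the
#'   nearest integer percent (NA when the nanopore set is empty).
#' @seealso [compareGeneSets()]
#' @export
setClass("GeneSetComparison", representation(
  nanopore = "character", wgbs = "character", shared = "character",
  nanoporeOnly = "character", wgbsOnly = "character",
  overlapPercent = "numeric"))

setValidity("GeneSetComparison", function(object) {
  if (length(object@shared) + length(object@nanoporeOnly) !=
      length(object@nanopore))
    return("nanopore partition identity violated")
  if (length(object@shared) + length(object@wgbsOnly) !=
      length(object@wgbs))
    return("wgbs partition identity violated")
  TRUE
})

#' Candidate table of the expression filter cascade
#'
#' Per-gene stage flags (hypermethylation-confirmed, regeneration pass, tumor
#' pass, known TSG) with the final candidate status and the funnel of stage
#' counts.
#'
#' @slot table data.frame, one row per confirmed gene.
#' @slot funnel named integer: confirmed, regeneration_pass, tumor_pass,
#'   candidates.
#' @seealso [runCascade()]
#' @export
setClass("CandidateTable",
         representation(table = "data.frame", funnel = "integer"))

setValidity("CandidateTable", function(object) {
  f <- object@funnel
  need <- c("confirmed", "regeneration_pass", "tumor_pass", "candidates")
  if (!all(need %in% names(f))) return("funnel must carry the four stages")
  if (any(diff(f[need]) > 0)) return("funnel counts must be non-increasing")
  TRUE
})
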