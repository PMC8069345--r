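#' Accessors for the core classes
#'
#' @param x a MethylTSG object.
#' @param ... ignored.
#' @return The slot content: a GRanges for `cpgSites`/`promoterRanges`, a
#'   character vector for `geneSymbols`, a named numeric for `chromLengths`,
#'   a data.frame for `modelParams`/`profileInfo`/`classLabels`/
#'   `candidateTable`, a matrix for `profileFeatures`, a named integer for
#'   `stageFunnel`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cpgSites", function(x, ...) standardGeneric("cpgSites"))
#' @rdname accessors
#' @export
setMethod("cpgSites", "ToyGenome", function(x, ...) x@sites)

#' @rdname accessors
#' @export
setGeneric("promoterRanges", function(x, ...) standardGeneric("promoterRanges"))
#' @rdname accessors
#' @export
setMethod("promoterRanges", "ToyGenome", function(x, ...) x@promoters)

#' @rdname accessors
#' @export
setGeneric("geneSymbols", function(x, ...) standardGeneric("geneSymbols"))
#' @rdname accessors
#' @export
setMethod("geneSymbols", "ToyGenome", function(x, ...) x@genes)

#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x, ...) standardGeneric("chromLengths"))
#' @rdname accessors
#' @export
setMethod("chromLengths", "ToyGenome", function(x, ...) x@chromLengths)

#' @rdname accessors
#' @export
setGeneric("modelParams", function(x, ...) standardGeneric("modelParams"))
#' @rdname accessors
#' @export
setMethod("modelParams", "SixMerModel", function(x, ...) x@params)

#' @rdname accessors
#' @export
setGeneric("siteStates", function(x, ...) standardGeneric("siteStates"))
#' @rdname accessors
#' @export
setMethod("siteStates", "MethylationLandscape", function(x, ...) x@siteState)

#' @rdname accessors
#' @export
setGeneric("promoterClasses", function(x, ...)
  standardGeneric("promoterClasses"))
#' @rdname accessors
#' @export
setMethod("promoterClasses", "MethylationLandscape",
          function(x, ...) x@promoterClass)

#' @rdname accessors
#' @export
setGeneric("profileFeatures", function(x, ...)
  standardGeneric("profileFeatures"))
#' @rdname accessors
#' @export
setMethod("profileFeatures", "PromoterProfiles", function(x, ...) x@features)

#' @rdname accessors
#' @export
setGeneric("profileInfo", function(x, ...) standardGeneric("profileInfo"))
#' @rdname accessors
#' @export
setMethod("profileInfo", "PromoterProfiles", function(x, ...) x@info)

#' @rdname accessors
#' @export
setGeneric("classLabels", function(x, ...) standardGeneric("classLabels"))
#' @rdname accessors
#' @export
setMethod("classLabels", "PromoterClassification", function(x, ...) x@labels)

#' @rdname accessors
#' @export
setGeneric("sharedGenes", function(x, ...) standardGeneric("sharedGenes"))
#' @rdname accessors
#' @export
setMethod("sharedGenes", "GeneSetComparison", function(x, ...) x@shared)

#' @rdname accessors
#' @export
setGeneric("overlapPercent", function(x, ...) standardGeneric("overlapPercent"))
#' @rdname accessors
#' @export
setMethod("overlapPercent", "GeneSetComparison",
          function(x, ...) x@overlapPercent)

#' @rdname accessors
#' @export
setGeneric("candidateGenes", function(x, ...) standardGeneric("candidateGenes"))
#' @rdname accessors
#' @export
setMethod("candidateGenes", "CandidateTable", function(x, ...)
  sort(x@table$gene[x@table$status == "candidate"]))

#' @rdname accessors
#' @export
setGeneric("candidateTable", function(x, ...) standardGeneric("candidateTable"))
#' @rdname accessors
#' @export
setMethod("candidateTable", "CandidateTable", function(x, ...) x@table)

#' @rdname accessors
#' @export
setGeneric("stageFunnel", function(x, ...) standardGeneric("stageFunnel"))
#' @rdname accessors
#' @export
setMethod("stageFunnel", "CandidateTable", function(x, ...) x@funnel)

setMethod("show", "SixMerModel", function(object) {
  p <- object@params
  cat("SixMerModel:", nrow(p), "6-mers (",
      sum(grepl("M", p$kmer, fixed = TRUE)), "methylated variants )\n")
  cat("  current sd range:", paste(signif(range(p$level_stdv), 3),
                                   collapse = " - "), "pA\n")
})

setMethod("show", "ToyGenome", function(object) {
  cat("ToyGenome:", length(object@chromLengths), "chromosome(s),",
      sum(object@chromLengths), "bp\n")
  cat(" ", length(object@sites), "CpG sites;", length(object@promoters),
      "promoters of", length(object@genes), "genes\n")
  cat("  promoter window: -", object@windowUp, "/+", object@windowDown,
      " bp around TSS\n", sep = "")
})

setMethod("show", "MethylationLandscape", function(object) {
  cat("MethylationLandscape:\n  sites: ")
  print(table(object@siteState))
  cat("  promoters: ")
  print(table(object@promoterClass))
})

setMethod("show", "PromoterProfiles", function(object) {
  cat("PromoterProfiles:", nrow(object@features), "promoters x",
      ncol(object@features), "bins;",
      sum(object@info$classifiable), "classifiable\n")
})

setMethod("show", "PromoterClassification", function(object) {
  lab <- object@labels$label
  cat("PromoterClassification:", sum(lab == "hyper", na.rm = TRUE), "hyper /",
      sum(lab == "hypo", na.rm = TRUE), "hypo promoters",
      sprintf("(%d unclassifiable)\n", sum(is.na(lab))))
  cat("  centroid means:", paste(signif(object@centroidMeans, 3),
                                 collapse = " / "), "\n")
})

setMethod("show", "GeneSetComparison", function(object) {
  cat("GeneSetComparison:\n")
  cat(sprintf("  nanopore %d | wgbs %d | shared %d | nanopore-only %d | wgbs-only %d\n",
              length(object@nanopore), length(object@wgbs),
              length(object@shared), length(object@nanoporeOnly),
              length(object@wgbsOnly)))
  cat("  overlap (of nanopore set):", object@overlapPercent, "%\n")
})

setMethod("show", "CandidateTable", function(object) {
  cat("CandidateTable funnel:\n")
  f <- object@funnel
  cat(sprintf("  confirmed %d -> regeneration %d -> tumor %d -> candidates %d\n",
              f["confirmed"], f["regeneration_pass"], f["tumor_pass"],
              f["candidates"]))
})
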