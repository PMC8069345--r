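#' Default pipeline configuration
#'
#' One nested list with a section per stage. Thresholds carry the method's
#' reference defaults: caller threshold 2.5 (natural log), minimum bisulfite
#' coverage 5 reads, hypermethylated-site cutoff 0.5, 5hmC rule min 5 reads
#' and max 0.1 mean frequency, fold-change thresholds 2, rank-test alpha
#' 1e-4, known TSGs AJAP1/GATA5/LRAT. The simulator block defines the study
#' conditions the synthetic validation runs under (see the package
#' vignette).
#'
#' @param seed master seed; all stage seeds derive from it.
#' @return nested configuration list.
#' @export
defaultConfig <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    genome = list(n_chrom = 1, chrom_length = 200000, n_genes = 40,
                  cpg_density = 0.005, island_factor = 10,
                  window_up = 1000, window_down = 500),
    landscape = list(fractions = c(hyper5mC = 0.3, hypo = 0.5,
                                   hyper5hmC = 0.2),
                     p_in = 0.9, p_out = 0.05, bg_meth = 0.8),
    nanopore = list(mean_coverage = 10, sigma = 2, delta = 4),
    bisulfite = list(mean_coverage = 15, conversion_error = 0.01,
                     epic_fraction = 0.11, epic_coverage = 45),
    expression = list(n_planted = 8, fc_ph4h = 4, fc_tumor = 4,
                      recovery = TRUE, n_tumor = 371, n_normal = 50,
                      noise_cv = 0.2),
    caller = list(threshold = 2.5, min_coverage = 5),
    promoter = list(n_bins = 20, min_sites = 3, freq_threshold = 0.5,
                    kmeans_restarts = 10),
    integration = list(min_reads = 5, low_freq = 0.1),
    filter = list(fc_regeneration = 2, fc_tumor = 2, alpha = 1e-4,
                  recovery_factor = 2, pseudocount = 0.1,
                  known_tsgs = c("AJAP1", "GATA5", "LRAT"), use_bh = FALSE))
}

#' Read / write a pipeline configuration (YAML)
#'
#' The configuration round-trips losslessly: `readPipelineConfig()` restores
#' what `writePipelineConfig()` wrote, filling unspecified entries from
#' [defaultConfig()].
#'
#' @param path YAML path.
#' @return [readPipelineConfig()]: configuration list;
#'   [writePipelineConfig()]: `path`, invisibly.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultConfig(if (!is.null(user$seed)) user$seed else 1)
  mergeIn <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(upd[[nm]]))
        mergeIn(base[[nm]], upd[[nm]]) else upd[[nm]]
    }
    base
  }
  cfg <- mergeIn(cfg, user)
  cfg$landscape$fractions <- unlist(cfg$landscape$fractions)
  if (is.null(names(cfg$landscape$fractions)))
    names(cfg$landscape$fractions) <- c("hyper5mC", "hypo", "hyper5hmC")
  cfg$filter$known_tsgs <- unlist(cfg$filter$known_tsgs)
  cfg
}

#' @rdname readPipelineConfig
#' @param config configuration list.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the integrated methylation-to-candidate pipeline
#'
#' Executes the six stages on simulated data: simulate (toy genome,
#' ground-truth landscape, nanopore events, bisulfite counts, expression),
#' call (per-read 5mC calls and per-site frequencies for all three
#' platforms), cluster (promoter profiles + k-means per platform, collapsed
#' to gene sets), integrate (nanopore/WGBS/EPIC set algebra and the
#' putative-5hmC flags), filter (the expression cascade), and report
#' (cross-platform Spearman, TSS metaplot, overlap counts, funnel). Each
#' stage is deterministic given the config seed; when `outdir` is given the
#' stage artifacts are written as plain-text tables and rerunning with the
#' same config reproduces them byte-identically.
#'
#' @param config configuration list (see [defaultConfig()]).
#' @param outdir optional output directory for stage artifacts.
#' @param verbose log stage parameters and record counts via message().
#' @return list with the simulated truth (`genome`, `landscape`, `planted`,
#'   `epic_mask`), per-platform records and gene sets, the
#'   [GeneSetComparison-class], confirmed genes, 5hmC flags, the
#'   [CandidateTable-class], and the report block (spearman, metaplot,
#'   overlap counts, funnel).
#' @export
runPipeline <- function(config = defaultConfig(), outdir = NULL,
                        verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed
  cg <- config$genome; cl <- config$landscape; cn <- config$nanopore
  cb <- config$bisulfite; ce <- config$expression; cc <- config$caller
  cp <- config$promoter; ci <- config$integration; cf <- config$filter

  ## stage: simulate ---------------------------------------------------
  say("simulate: genome %d chrom x %d bp, %d genes, density %.4g",
      cg$n_chrom, cg$chrom_length, cg$n_genes, cg$cpg_density)
  genome <- generateToyGenome(cg$n_chrom, cg$chrom_length, cg$n_genes,
                              cg$cpg_density, cg$island_factor,
                              cg$window_up, cg$window_down,
                              seed = subSeed(seed, 11))
  landscape <- assignLandscape(genome, cl$fractions, cl$p_in, cl$p_out,
                               cl$bg_meth, seed = subSeed(seed, 12))
  model <- buildSixMerModel(sigma = cn$sigma, delta = cn$delta,
                            seed = subSeed(seed, 13))
  events <- simulateNanoporeEvents(landscape, genome, model,
                                   cn$mean_coverage,
                                   seed = subSeed(seed, 14))
  bis <- simulateBisulfiteCounts(landscape, genome, cb$mean_coverage,
                                 cb$conversion_error, cb$epic_fraction,
                                 cb$epic_coverage, seed = subSeed(seed, 15))
  trueHyper <- names(promoterClasses(landscape))[
    promoterClasses(landscape) == "hyper5mC"]
  trueHyperGenes <- unique(mcols(genome@promoters)$gene[
    mcols(genome@promoters)$promoter_id %in% trueHyper])
  planted <- withr::with_seed(subSeed(seed, 16), {
    sample(trueHyperGenes, min(ce$n_planted, length(trueHyperGenes)))
  })
  expr <- simulateExpression(genome, planted, ce$fc_ph4h, ce$fc_tumor,
                             ce$recovery, ce$n_tumor, ce$n_normal,
                             ce$noise_cv, seed = subSeed(seed, 17))
  say("simulate: %d CpG sites, %d events, %d planted candidates",
      length(cpgSites(genome)), nrow(events), length(planted))

  ## stage: call -------------------------------------------------------
  calls <- callMethylation(events, model, cc$threshold)
  nanoRec <- aggregateNanoporeFrequency(calls)
  wgbsRec <- bisulfiteFrequency(bis$wgbs, cc$min_coverage)
  epicRec <- bisulfiteFrequency(bis$epic, cc$min_coverage)
  say("call: %d nanopore sites, %d wgbs sites, %d epic sites",
      length(nanoRec), length(wgbsRec), length(epicRec))

  ## stage: cluster ----------------------------------------------------
  proms <- promoterRanges(genome)
  clusterOne <- function(rec, tag, off) {
    prof <- buildProfiles(rec, proms, cp$n_bins, cp$min_sites,
                          cp$freq_threshold)
    cls <- kmeansClassify(prof, nRestarts = cp$kmeans_restarts,
                          seed = subSeed(seed, off))
    list(profiles = prof, classification = cls, genes = collapseToGenes(cls))
  }
  nano <- clusterOne(nanoRec, "nanopore", 21)
  wgbs <- clusterOne(wgbsRec, "wgbs", 22)
  epic <- clusterOne(epicRec, "epic", 23)
  say("cluster: hyper genes nanopore %d, wgbs %d, epic %d",
      nano$genes$nGenes, wgbs$genes$nGenes, epic$genes$nGenes)

  ## stage: integrate --------------------------------------------------
  comparison <- compareGeneSets(nano$genes$genes, wgbs$genes$genes)
  confirmed <- confirmWithEpic(comparison, epic$genes$genes)
  flags <- flagPutative5hmC(comparison@wgbsOnly, profileInfo(nano$profiles),
                            ci$min_reads, ci$low_freq)
  say("integrate: shared %d, confirmed %d, 5hmC-flagged %d",
      length(comparison@shared), length(confirmed), sum(flags$flagged))

  ## stage: filter -----------------------------------------------------
  candidates <- runCascade(confirmed, expr$regeneration, expr$cohort,
                           cf$fc_regeneration, cf$fc_tumor, cf$alpha,
                           cf$recovery_factor, cf$pseudocount,
                           cf$known_tsgs, cf$use_bh)
  say("filter: funnel %s",
      paste(stageFunnel(candidates), collapse = " -> "))

  ## stage: report -----------------------------------------------------
  spearman <- tryCatch(
    platformSpearman(nanoRec, wgbsRec, cc$min_coverage),
    error = function(e) NA_real_)
  metaplot <- tssMetaplot(nanoRec, proms)
  report <- list(
    spearman_nanopore_wgbs = spearman,
    metaplot = metaplot,
    overlap = c(nanopore = length(comparison@nanopore),
                wgbs = length(comparison@wgbs),
                shared = length(comparison@shared),
                nanopore_only = length(comparison@nanoporeOnly),
                wgbs_only = length(comparison@wgbsOnly),
                overlap_percent = comparison@overlapPercent,
                confirmed = length(confirmed),
                flagged_5hmc = sum(flags$flagged)),
    funnel = stageFunnel(candidates))

  result <- list(config = config, genome = genome, landscape = landscape,
                 model = model, planted = sort(normalizeSymbols(planted)),
                 epic_mask = bis$epic_mask, events = events, calls = calls,
                 records = list(nanopore = nanoRec, wgbs = wgbsRec,
                                epic = epicRec),
                 profiles = list(nanopore = nano$profiles,
                                 wgbs = wgbs$profiles, epic = epic$profiles),
                 geneSets = list(nanopore = nano$genes$genes,
                                 wgbs = wgbs$genes$genes,
                                 epic = epic$genes$genes),
                 comparison = comparison, confirmed = confirmed,
                 hmcFlags = flags, expression = expr,
                 candidates = candidates, report = report)
  if (!is.null(outdir)) writePipelineArtifacts(result, outdir)
  result
}

writePipelineArtifacts <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(outdir, f)
  writeGenomeFasta(result$genome, fp("genome.fa"))
  writePromoterBed(promoterRanges(result$genome), fp("promoters.bed"))
  truth <- data.frame(
    promoter_id = names(promoterClasses(result$landscape)),
    class = as.character(promoterClasses(result$landscape)))
  utils::write.table(truth, fp("truth_promoters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeBedMethyl(result$records$nanopore, fp("nanopore.bedmethyl"))
  writeBedGraph(result$records$nanopore, fp("nanopore.bedgraph"), "nanopore")
  for (p in c("wgbs", "epic")) {
    rec <- result$records[[p]]
    tab <- data.frame(chrom = as.character(seqnames(rec)), pos = pos0(rec),
                      methylated_count = mcols(rec)$methylated,
                      total_count = mcols(rec)$coverage)
    writeBismarkCoverage(tab, fp(paste0(p, ".cov")))
  }
  membership <- data.frame(gene = sort(unique(c(
    result$comparison@nanopore, result$comparison@wgbs,
    result$geneSets$epic))))
  membership$nanopore <- membership$gene %in% result$comparison@nanopore
  membership$wgbs <- membership$gene %in% result$comparison@wgbs
  membership$epic <- membership$gene %in% result$geneSets$epic
  membership$partition <- ifelse(
    membership$gene %in% result$comparison@shared, "shared",
    ifelse(membership$gene %in% result$comparison@nanoporeOnly,
           "nanopore_only",
           ifelse(membership$gene %in% result$comparison@wgbsOnly,
                  "wgbs_only", "epic_only")))
  fl <- result$hmcFlags
  membership$hmc_flag <- fl$flagged[match(membership$gene, fl$gene)]
  membership$hmc_reason <- fl$reason[match(membership$gene, fl$gene)]
  utils::write.table(membership, fp("gene_membership.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(metric = names(result$report$overlap),
                                value = unname(result$report$overlap)),
                     fp("venn_counts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(candidateTable(result$candidates),
                     fp("candidates.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(stage = names(result$report$funnel),
                                count = unname(result$report$funnel)),
                     fp("funnel.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(result$report$metaplot, fp("tss_metaplot.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("spearman_nanopore_wgbs\t%.6f",
                     result$report$spearman_nanopore_wgbs),
             fp("correlation.tsv"))
  invisible(outdir)
}

#' Recovery of planted truth by a pipeline run
#'
#' Sensitivity of the final candidate set for the planted candidate genes,
#' plus per-stage false-admission rates: for the confirmation stage the
#' fraction of confirmed genes that are not truly promoter-hypermethylated
#' (5mC), and for the regeneration/tumor/candidate stages the fraction of
#' admitted genes without planted downregulation.
#'
#' @param result a [runPipeline()] result.
#' @return list with `sensitivity`, `falseAdmission` (named numeric per
#'   stage) and the admitted gene sets per stage.
#' @export
plantedRecovery <- function(result) {
  planted <- result$planted
  pc <- promoterClasses(result$landscape)
  trueHyperGenes <- normalizeSymbols(unique(
    mcols(result$genome@promoters)$gene[
      mcols(result$genome@promoters)$promoter_id %in%
        names(pc)[pc == "hyper5mC"]]))
  tab <- candidateTable(result$candidates)
  stages <- list(
    confirmed = result$confirmed,
    regeneration_pass = tab$gene[tab$regeneration_pass],
    tumor_pass = tab$gene[tab$regeneration_pass & tab$tumor_pass],
    candidates = candidateGenes(result$candidates))
  truthFor <- list(confirmed = trueHyperGenes, regeneration_pass = planted,
                   tumor_pass = planted, candidates = planted)
  fa <- vapply(names(stages), function(s) {
    adm <- stages[[s]]
    if (!length(adm)) return(0)
    mean(!adm %in% truthFor[[s]])
  }, numeric(1))
  sens <- if (length(planted)) mean(planted %in% stages$candidates) else
    NA_real_
  list(sensitivity = sens, falseAdmission = fa, stages = stages)
}
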