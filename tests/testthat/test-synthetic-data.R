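test_that("toy genome generation is deterministic and respects bounds", {
  g1 <- generateToyGenome(2, 50000, 10, 0.005, seed = 11)
  g2 <- generateToyGenome(2, 50000, 10, 0.005, seed = 11)
  expect_identical(as.character(g1@sequence), as.character(g2@sequence))
  expect_identical(cpgSites(g1), cpgSites(g2))
  expect_identical(promoterRanges(g1), promoterRanges(g2))
  g3 <- generateToyGenome(2, 50000, 10, 0.005, seed = 12)
  expect_false(identical(as.character(g1@sequence),
                         as.character(g3@sequence)))

  sites <- cpgSites(g1)
  expect_true(all(mcols(sites)$pos0 >= 0))
  expect_true(all(mcols(sites)$pos0 <
                    chromLengths(g1)[as.character(seqnames(sites))]))
  proms <- promoterRanges(g1)
  expect_true(all(start(proms) >= 1))
  expect_true(all(end(proms) <=
                    chromLengths(g1)[as.character(seqnames(proms))]))
  # promoters do not overlap
  expect_equal(sum(countOverlaps(proms, proms, ignore.strand = TRUE)),
               length(proms))
  expect_false(anyDuplicated(geneSymbols(g1)) > 0)
})

test_that("genome sequence carries CpG dinucleotides only at annotated sites", {
  g <- generateToyGenome(1, 30000, 5, 0.01, seed = 3)
  seq <- as.character(g@sequence[["chr1"]])
  found <- gregexpr("CG", seq, fixed = TRUE)[[1]]
  expect_setequal(as.integer(found) - 1L, mcols(cpgSites(g))$pos0)
})

test_that("empty genome: zero density and zero genes give no sites/promoters", {
  g <- generateToyGenome(1, 1000, 0, 0.0, seed = 1)
  expect_length(cpgSites(g), 0)
  expect_length(promoterRanges(g), 0)
  expect_length(geneSymbols(g), 0)
})

test_that("CpG count matches the analytic island-enriched expectation", {
  # Bernoulli(rate) per bp with a >=2 bp hardcore: the kept-site rate is
  # r / (1 + r) (renewal argument), summed over background and island bp.
  g <- generateToyGenome(1, 100000, 10, 0.01, islandFactor = 10, seed = 1)
  expect_length(promoterRanges(g), 10)
  islandBp <- sum(width(promoterRanges(g)))
  bgBp <- 100000 - islandBp
  rateIn <- 0.1; rateOut <- 0.01
  mu <- bgBp * rateOut / (1 + rateOut) + islandBp * rateIn / (1 + rateIn)
  expect_lt(abs(length(cpgSites(g)) - mu), 4 * sqrt(mu))
})

test_that("promoter placement fails cleanly when windows cannot fit", {
  expect_error(generateToyGenome(1, 1000, 2, 0.01, seed = 1),
               "non-overlapping")
})

test_that("landscape class counts follow largest-remainder apportionment", {
  expect_equal(unname(largestRemainderCounts(100, c(0.3, 0.5, 0.2))),
               c(30L, 50L, 20L))
  expect_equal(unname(largestRemainderCounts(10, rep(1, 3) / 3)),
               c(4L, 3L, 3L))
  expect_equal(sum(largestRemainderCounts(17, c(0.21, 0.33, 0.46))), 17L)
  g <- generateToyGenome(1, 200000, 100, 0.004, seed = 5)
  l <- assignLandscape(g, c(hyper5mC = 0.3, hypo = 0.5, hyper5hmC = 0.2),
                       seed = 5)
  expect_equal(as.vector(table(promoterClasses(l))), c(30L, 50L, 20L))
})

test_that("landscape site states follow the per-class probabilities", {
  g <- generateToyGenome(1, 100000, 20, 0.005, seed = 6)
  proms <- promoterRanges(g)
  inProm <- overlapsAny(cpgSites(g), proms, ignore.strand = TRUE)

  # all-hypo landscape with no noise: promoter sites all unmethylated
  l0 <- assignLandscape(g, c(0, 1, 0), pIn = 1, pOut = 0, seed = 1)
  expect_true(all(siteStates(l0)[inProm] == "unmethylated"))

  # all-hyper landscape at pIn = 1: every promoter CpG methylated
  l1 <- assignLandscape(g, c(1, 0, 0), pIn = 1, seed = 1)
  expect_true(all(siteStates(l1)[inProm] == "methylated_5mC"))

  # background obeys bgMeth
  lbg <- assignLandscape(g, c(0, 1, 0), bgMeth = 1, seed = 1)
  expect_true(all(siteStates(lbg)[!inProm] == "methylated_5mC"))

  expect_error(assignLandscape(g, c(0.5, 0.5, 0), pIn = 1.4),
               "probabilities")
  expect_error(assignLandscape(g, c(0.5, 0.4, 0)), "sum to 1")
})

test_that("nanopore event simulation: empty, degenerate-sigma, Poisson depth", {
  g <- generateToyGenome(1, 50000, 5, 0.005, seed = 7)
  l <- assignLandscape(g, seed = 7)
  m <- buildSixMerModel(seed = 7)
  expect_equal(nrow(simulateNanoporeEvents(l, g, m, 0, seed = 1)), 0)

  # sigma -> 0 on a fully methylated landscape: currents sit at mu_M
  l1 <- assignLandscape(g, c(1, 0, 0), pIn = 1, bgMeth = 1, seed = 7)
  m0 <- buildSixMerModel(sigma = 1e-9, delta = 4, seed = 7)
  ev <- simulateNanoporeEvents(l1, g, m0, 2, seed = 8)
  mu <- stats::setNames(modelParams(m0)$level_mean, modelParams(m0)$kmer)
  expect_equal(ev$current, unname(mu[methylVariant(ev$kmer)]),
               tolerance = 1e-6)

  # Poisson(3) read depth over ~10000 sites: mean within 3 +/- 0.1
  gbig <- generateToyGenome(1, 2e6, 0, 0.005, seed = 9)
  lbig <- assignLandscape(gbig, seed = 9)
  m2 <- buildSixMerModel(seed = 9)
  evb <- simulateNanoporeEvents(lbig, gbig, m2, 3, seed = 10)
  meanDepth <- length(unique(evb$read_id)) / length(cpgSites(gbig))
  expect_lt(abs(meanDepth - 3), 0.1)
})

test_that("event simulation is deterministic and events are well-formed", {
  g <- generateToyGenome(1, 30000, 4, 0.01, seed = 2)
  l <- assignLandscape(g, seed = 2)
  m <- buildSixMerModel(seed = 2)
  e1 <- simulateNanoporeEvents(l, g, m, 5, seed = 3)
  e2 <- simulateNanoporeEvents(l, g, m, 5, seed = 3)
  expect_identical(e1, e2)
  expect_true(all(is.finite(e1$current)))
  expect_true(all(nchar(e1$kmer) == 6))
  expect_true(all(grepl("CG", e1$kmer, fixed = TRUE)))
  # every observed site carries at least one event per read by construction
  expect_gt(nrow(e1), 0)
})

test_that("bisulfite counts: conversion asymmetry and EPIC targeting", {
  g <- generateToyGenome(1, 60000, 10, 0.005, seed = 4)
  inProm <- overlapsAny(cpgSites(g), promoterRanges(g), ignore.strand = TRUE)
  key <- function(df) paste(df$chrom, df$pos)
  siteKey <- paste(as.character(seqnames(cpgSites(g))),
                   mcols(cpgSites(g))$pos0)

  # error-free: unmethylated sites give 0, 5hmC sites give total
  l <- assignLandscape(g, c(0, 0, 1), pIn = 1, pOut = 0, bgMeth = 0,
                       seed = 4)
  b <- simulateBisulfiteCounts(l, g, 10, conversionError = 0, seed = 5)
  st <- siteStates(l)[match(key(b$wgbs), siteKey)]
  expect_true(all(b$wgbs$methylated_count[st == "unmethylated"] == 0))
  expect_true(all((b$wgbs$methylated_count ==
                     b$wgbs$total_count)[st == "hydroxymethylated_5hmC"]))
  expect_true(all(b$wgbs$methylated_count <= b$wgbs$total_count))

  # EPIC rows restricted to the recorded capture mask
  expect_true(all(key(b$epic) %in% siteKey[b$epic_mask]))
  expect_equal(length(b$epic_mask),
               round(0.11 * length(cpgSites(g))))

  # pooled error rate of unmethylated sites ~ conversionError
  l0 <- assignLandscape(g, c(0, 1, 0), pIn = 1, pOut = 0, bgMeth = 0,
                        seed = 4)
  b2 <- simulateBisulfiteCounts(l0, g, 30, conversionError = 0.01, seed = 6)
  pooled <- sum(b2$wgbs$methylated_count) / sum(b2$wgbs$total_count)
  n <- sum(b2$wgbs$total_count)
  expect_lt(abs(pooled - 0.01), 3 * sqrt(0.01 * 0.99 / n))

  expect_error(simulateBisulfiteCounts(l, g, 10, conversionError = 0.2),
               "conversionError")
})

test_that("expression simulation plants exact fold changes at zero noise", {
  g <- generateToyGenome(1, 60000, 10, 0.005, seed = 8)
  genes <- geneSymbols(g)
  ex <- simulateExpression(g, genes[1:3], fcPh4h = 2, fcTumor = 2,
                           noiseCv = 0, nTumor = 10, nNormal = 5, seed = 9)
  wide <- reshape(ex$regeneration, idvar = "gene", timevar = "condition",
                  direction = "wide")
  planted <- wide$gene %in% genes[1:3]
  expect_equal(wide$value.ph4h[planted], wide$value.sham[planted] / 2)
  expect_equal(wide$value.ph1wk[planted], wide$value.sham[planted])
  # non-candidates identical in all conditions and all cohort samples
  expect_equal(wide$value.ph4h[!planted], wide$value.sham[!planted])
  nonc <- ex$cohort[ex$cohort$gene == genes[5], ]
  expect_equal(length(unique(nonc$value)), 1)
  expect_true(all(ex$cohort$value >= 0))
  # every gene present in every condition/sample
  expect_equal(nrow(ex$cohort), length(genes) * 15)

  # cohort median ratio recovers the planted fold under default noise
  ex2 <- simulateExpression(g, genes[1], fcTumor = 4, nTumor = 371,
                            nNormal = 50, noiseCv = 0.2, seed = 10)
  v <- ex2$cohort[ex2$cohort$gene == genes[1], ]
  ratio <- median(v$value[v$group == "normal"]) /
    median(v$value[v$group == "tumor"])
  expect_lt(abs(ratio - 4) / 4, 0.15)
})

test_that("5hmC asymmetry: bisulfite reads 5hmC high, the 5mC caller reads it low", {
  g <- generateToyGenome(1, 60000, 8, 0.005, seed = 12)
  l <- assignLandscape(g, c(0, 0, 1), pIn = 1, pOut = 0, bgMeth = 0,
                       seed = 12)
  m <- buildSixMerModel(sigma = 0.5, delta = 4, seed = 12)
  b <- simulateBisulfiteCounts(l, g, 20, conversionError = 0, seed = 13)
  wg <- bisulfiteFrequency(b$wgbs, 5)
  ev <- simulateNanoporeEvents(l, g, m, 20, seed = 13)
  np <- aggregateNanoporeFrequency(callMethylation(ev, m))
  hmc <- which(siteStates(l) == "hydroxymethylated_5hmC")
  hmcGr <- cpgSites(g)[hmc]
  wgH <- subsetByOverlaps(wg, hmcGr, type = "equal")
  npH <- subsetByOverlaps(np, hmcGr, type = "equal")
  expect_true(all(mcols(wgH)$frequency == 1))
  expect_true(all(mcols(npH)$frequency == 0, na.rm = TRUE))
})
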