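test_that("site-to-promoter assignment is strand-aware and half-open", {
  tss <- 10000L
  pPlus <- promoterWindows("chr1", tss, "+", 1000, 500, "P1", "G1")
  pMinus <- promoterWindows("chr1", tss, "-", 1000, 500, "P2", "G2")
  assigned <- function(prom, pos) {
    rec <- makeRecords(pos, 0.5)
    nrow(assignSitesToPromoters(rec, prom)) == 1
  }
  # plus strand: [tss - up, tss + down)
  expect_true(assigned(pPlus, tss))
  expect_true(assigned(pPlus, tss - 1000L))
  expect_true(assigned(pPlus, tss + 499L))
  expect_false(assigned(pPlus, tss + 500L))          # half-open boundary
  expect_false(assigned(pPlus, tss - 1001L))
  # minus strand mirror: (tss - down, tss + up]
  expect_true(assigned(pMinus, tss - 499L))
  expect_false(assigned(pMinus, tss - 500L))
  expect_true(assigned(pMinus, tss + 1000L))
  expect_false(assigned(pMinus, tss + 1001L))

  expect_warning(
    assignSitesToPromoters(makeRecords(5, 0.5, chrom = "chrUn"), pPlus),
    "chrUn")
})

test_that("shifting a site across the downstream edge removes the assignment", {
  withr::with_seed(31, {
    for (i in 1:10) {
      tss <- sample(5000:50000, 1)
      up <- sample(200:1500, 1); dn <- sample(100:800, 1)
      str <- sample(c("+", "-"), 1)
      prom <- promoterWindows("chr1", tss, str, up, dn, "P", "G")
      inside <- if (str == "+") tss + dn - 1L else tss - dn + 1L
      outside <- if (str == "+") tss + dn else tss - dn
      expect_equal(nrow(assignSitesToPromoters(makeRecords(inside, 0.5),
                                               prom)), 1)
      expect_equal(nrow(assignSitesToPromoters(makeRecords(outside, 0.5),
                                               prom)), 0)
    }
  })
})

test_that("hypermethylated-site selection is strictly greater than 50%", {
  rec <- makeRecords(c(10, 20, 30), c(0.50, 0.51, 0.49))
  sel <- selectHypermethylatedSites(rec)
  expect_length(sel, 1)
  expect_equal(mcols(sel)$frequency, 0.51)
  expect_length(selectHypermethylatedSites(rec[0]), 0)
})

test_that("profiles bin correctly and impute empty bins with the promoter mean", {
  prom <- promoterWindows("chr1", 2000L, "+", 1000, 500, "P1", "G1")
  # all-hyper and all-hypo promoters
  posIn <- c(1100L, 1600L, 2100L)
  recHi <- makeRecords(posIn, c(0.9, 0.8, 1.0))
  profHi <- buildProfiles(recHi, prom, nBins = 20, minSites = 3)
  expect_equal(unname(profileFeatures(profHi)[1, ]), rep(1, 20))
  recLo <- makeRecords(posIn, c(0.1, 0.0, 0.2))
  expect_equal(unname(profileFeatures(
    buildProfiles(recLo, prom, nBins = 20, minSites = 3))[1, ]), rep(0, 20))

  # sites confined to one bin: the 19 empty bins take that bin's value
  pos1 <- c(1000L, 1020L, 1040L)                    # all in bin 1 (75 bp)
  recBin <- makeRecords(pos1, c(0.9, 0.9, 0.1))
  featB <- profileFeatures(buildProfiles(recBin, prom, nBins = 20,
                                         minSites = 3))[1, ]
  expect_equal(unname(featB), rep(2 / 3, 20))

  # below min_sites: unclassifiable, NA features
  prof2 <- buildProfiles(makeRecords(c(1100L, 1600L), c(1, 1)), prom,
                         minSites = 3)
  expect_false(profileInfo(prof2)$classifiable)
  expect_true(all(is.na(profileFeatures(prof2)[1, ])))
})

test_that("k-means separates planted hyper/hypo profiles and is deterministic", {
  withr::with_seed(7, {
    nHyper <- 30; nHypo <- 50; nb <- 20
    feats <- rbind(
      matrix(pmin(pmax(rnorm(nHyper * nb, 0.9, 0.05), 0), 1), nHyper),
      matrix(pmin(pmax(rnorm(nHypo * nb, 0.05, 0.05), 0), 1), nHypo))
  })
  rownames(feats) <- sprintf("P%03d", seq_len(nrow(feats)))
  prof <- makeProfiles(feats)
  cls <- kmeansClassify(prof, seed = 3)
  truth <- rep(c("hyper", "hypo"), c(30, 50))
  expect_equal(classLabels(cls)$label, truth)

  # determinism and input-order invariance
  cls2 <- kmeansClassify(prof, seed = 3)
  expect_identical(classLabels(cls), classLabels(cls2))
  perm <- withr::with_seed(9, sample(nrow(feats)))
  profP <- makeProfiles(feats[perm, , drop = FALSE])
  clsP <- kmeansClassify(profP, seed = 3)
  lp <- classLabels(clsP)
  expect_equal(lp$label[match(classLabels(cls)$promoter_id,
                              lp$promoter_id)],
               classLabels(cls)$label)

  # duplicated points always share a label
  dup <- makeProfiles(feats[rep(1:40, each = 2), , drop = FALSE])
  labd <- classLabels(kmeansClassify(dup, seed = 5))$label
  expect_equal(labd[seq(1, 80, 2)], labd[seq(2, 80, 2)])
})

test_that("identical profiles trigger the degenerate single-cluster path", {
  feats <- matrix(0.8, nrow = 5, ncol = 10)
  rownames(feats) <- sprintf("P%d", 1:5)
  expect_warning(cls <- kmeansClassify(makeProfiles(feats), seed = 1),
                 "identical")
  expect_true(all(classLabels(cls)$label == "hyper"))
  expect_error(kmeansClassify(makeProfiles(feats[1, , drop = FALSE])),
               "at least 2")
})

test_that("gene collapse uses any-promoter OR-logic", {
  labels <- data.frame(
    promoter_id = c("P1", "P2", "P3", "P4"),
    gene = c("GA", "GA", "GB", "GC"),
    label = c("hyper", "hypo", "hypo", NA), stringsAsFactors = FALSE)
  cls <- methods::new("PromoterClassification", labels = labels,
                      centroids = matrix(0, 2, 2),
                      centroidMeans = c(1, 0))
  out <- collapseToGenes(cls)
  expect_equal(out$genes, "GA")
  expect_equal(out$nHyperPromoters, 1)
  expect_lte(out$nGenes, out$nHyperPromoters)
  # no hyper promoters: empty set
  labels$label <- "hypo"
  cls0 <- methods::new("PromoterClassification", labels = labels,
                       centroids = matrix(0, 2, 2), centroidMeans = c(1, 0))
  expect_length(collapseToGenes(cls0)$genes, 0)
})

test_that("TSS metaplot is flat on uniform data and dips at hypo promoters", {
  g <- generateToyGenome(1, 400000, 20, 0.005, seed = 41)
  proms <- promoterRanges(g)

  # uniform landscape: profile flat up to sampling noise
  lU <- assignLandscape(g, c(1, 0, 0), pIn = 0.8, bgMeth = 0.8, seed = 41)
  bU <- simulateBisulfiteCounts(lU, g, 30, conversionError = 0, seed = 42)
  recU <- bisulfiteFrequency(bU$wgbs, 5)
  mpU <- tssMetaplot(recU, proms, span = 2000, nBins = 40)
  mf <- mpU$mean_frequency[mpU$n_sites >= 20]
  expect_lt(max(mf) - min(mf), 0.25)

  # planted hypo promoters on a methylated background: central dip
  lD <- assignLandscape(g, c(0, 1, 0), pIn = 0.9, pOut = 0.05,
                        bgMeth = 0.9, seed = 43)
  bD <- simulateBisulfiteCounts(lD, g, 30, conversionError = 0, seed = 44)
  recD <- bisulfiteFrequency(bD$wgbs, 5)
  mpD <- tssMetaplot(recD, proms, span = 2000, nBins = 40)
  central <- mpD$mean_frequency[abs(mpD$center) <= 400]
  flank <- mpD$mean_frequency[abs(mpD$center) >= 1600]
  expect_true(all(central < min(flank, na.rm = TRUE), na.rm = TRUE))

  # empty input: all bins undefined
  mpE <- tssMetaplot(recD[0], proms)
  expect_true(all(is.na(mpE$mean_frequency)))
})
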