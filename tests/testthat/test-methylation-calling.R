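test_that("LLR scoring matches hand-computed Gaussian log-densities", {
  # identical M and C models: llr is exactly 0
  m0 <- tinyModel(muC = 9, muM = 9, sdC = 1.5)
  ev <- data.frame(kmer = "AACGTT", current = c(7.2, 9.9, 10.4))
  expect_equal(scoreSiteLLR(ev, m0), 0)

  # single event at mu_M with mu_M=10, mu_C=8, sd=1:
  # llr = 0 - (-(10-8)^2/2) = 2
  m <- tinyModel(muC = 8, muM = 10, sdC = 1)
  expect_equal(scoreSiteLLR(data.frame(kmer = "AACGTT", current = 10), m), 2)

  # general hand formula for shared sigma:
  # llr = sum over events of (x-muC)^2/2 - (x-muM)^2/2
  x <- c(8.3, 9.1, 11.0)
  hand <- sum((x - 8)^2 / 2 - (x - 10)^2 / 2)
  expect_equal(scoreSiteLLR(data.frame(kmer = "AACGTT", current = x), m),
               hand)

  expect_error(scoreSiteLLR(data.frame(kmer = character(0),
                                       current = numeric(0)), m), "empty")
  expect_error(scoreSiteLLR(data.frame(kmer = "TTTCGA", current = 1), m),
               "TTTCGA")
})

test_that("LLR is exactly antisymmetric under swapping the M and C models", {
  m <- tinyModel(muC = 8, muM = 10.5, sdC = 1, sdM = 2)
  swapped <- tinyModel(muC = 10.5, muM = 8, sdC = 2, sdM = 1)
  withr::with_seed(42, {
    for (i in 1:20) {
      ev <- data.frame(kmer = "AACGTT", current = rnorm(5, 9, 3))
      expect_identical(scoreSiteLLR(ev, m), -scoreSiteLLR(ev, swapped))
    }
  })
})

test_that("three-way calling is inclusive at the threshold boundary", {
  expect_equal(callSite(2.5, 2.5), "methylated")
  expect_equal(callSite(-2.5, 2.5), "unmethylated")
  expect_equal(callSite(-3.0), "unmethylated")
  expect_equal(callSite(0.4), "ambiguous")
  expect_equal(callSite(c(2.49, 2.51)), c("ambiguous", "methylated"))
  expect_error(callSite(1, threshold = -1))
})

test_that("raising the threshold never increases methylated calls", {
  withr::with_seed(1, llr <- rnorm(500, 0, 4))
  counts <- vapply(seq(0.5, 6, by = 0.5),
                   function(t) sum(callSite(llr, t) == "methylated"),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("per-site aggregation excludes ambiguous calls from both terms", {
  calls <- data.frame(
    read_id = sprintf("r%d", 1:17),
    chrom = "chr1",
    pos = c(rep(100L, 13), rep(200L, 4)),
    llr = 0,
    call = c(rep("methylated", 10), rep("ambiguous", 3),
             rep(c("methylated", "unmethylated"), 2)),
    stringsAsFactors = FALSE)
  rec <- aggregateNanoporeFrequency(calls)
  m <- as.data.frame(mcols(rec))
  s1 <- m[start(rec) == 101, ]
  expect_equal(s1$coverage, 10)
  expect_equal(s1$n_reads, 13)
  expect_equal(s1$frequency, 1.0)
  s2 <- m[start(rec) == 201, ]
  expect_equal(s2$frequency, 0.5)

  # a site with only ambiguous calls is kept, flagged with coverage 0
  allAmb <- data.frame(read_id = c("a", "b"), chrom = "chr1", pos = 5L,
                       llr = 0, call = "ambiguous")
  rec0 <- aggregateNanoporeFrequency(allAmb)
  expect_equal(mcols(rec0)$coverage, 0L)
  expect_equal(mcols(rec0)$n_reads, 2L)
  expect_true(is.na(mcols(rec0)$frequency))
})

test_that("bisulfite frequency applies the five-read coverage rule", {
  tab <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L), strand = "+",
                    methylated_count = c(2L, 5L, 2L),
                    total_count = c(4L, 5L, 8L), platform = "wgbs")
  rec <- bisulfiteFrequency(tab, minCoverage = 5)
  expect_length(rec, 2)                      # 4-read site dropped
  expect_false(11L %in% start(rec))
  expect_equal(mcols(rec)$frequency, c(1.0, 0.25))
  expect_error(bisulfiteFrequency(transform(tab, methylated_count = 9)),
               "invalid counts")
})

test_that("platform Spearman matches a brute-force average-rank oracle", {
  f <- c(0.1, 0.5, 0.5, 0.9, 0.3, 0.7)
  a <- makeRecords(seq(100, 600, by = 100), f)
  same <- platformSpearman(a, a)
  expect_equal(same, 1.0)
  b <- makeRecords(seq(100, 600, by = 100), c(0.95, 0.6, 0.4, 0.1, 0.8, 0.2))
  expect_equal(platformSpearman(a, b),
               bruteSpearman(f, c(0.95, 0.6, 0.4, 0.1, 0.8, 0.2)))
  # strict reversal without ties: rho = -1
  f2 <- c(0.1, 0.2, 0.4, 0.6, 0.8, 0.9)
  a2 <- makeRecords(seq(100, 600, by = 100), f2)
  b2 <- makeRecords(seq(100, 600, by = 100), 1 - f2)
  expect_equal(platformSpearman(a2, b2), -1.0)
  # too few shared sites errors
  expect_error(platformSpearman(a, makeRecords(c(100, 200), c(0.5, 0.5))),
               "at least 3")
  # low-coverage sites excluded before matching
  a3 <- makeRecords(seq(100, 600, by = 100), f, coverage = 4)
  expect_error(platformSpearman(a3, b), "at least 3")
})

test_that("caller calibration: mean LLR equals the analytic expectation", {
  # shared sigma, shift delta: E[llr per event] = delta^2 / (2 sigma^2)
  g <- generateToyGenome(1, 100000, 0, 0.004, seed = 21)
  l <- assignLandscape(g, c(1, 0, 0), pIn = 1, bgMeth = 1, seed = 21)
  m <- buildSixMerModel(sigma = 2, delta = 4, seed = 21)
  ev <- simulateNanoporeEvents(l, g, m, 4, seed = 22)
  calls <- callMethylation(ev, m)
  perRead <- table(ev$read_id)
  k <- as.numeric(perRead[calls$read_id])
  expected <- 2 * k                          # delta^2/(2 sigma^2) = 2
  resid <- calls$llr - expected
  se <- sd(resid) / sqrt(length(resid))
  expect_lt(abs(mean(resid)), 3 * se + 1e-9)
})

test_that("per-read calls recover the simulated truth with high accuracy", {
  g <- generateToyGenome(1, 150000, 20, 0.005, seed = 23)
  l <- assignLandscape(g, seed = 23)
  m <- buildSixMerModel(sigma = 2, delta = 4, seed = 23)
  ev <- simulateNanoporeEvents(l, g, m, 6, seed = 24)
  calls <- callMethylation(ev, m)
  siteKey <- paste(as.character(seqnames(cpgSites(g))),
                   mcols(cpgSites(g))$pos0)
  truth <- as.character(siteStates(l))[match(paste(calls$chrom, calls$pos),
                                             siteKey)]
  conf <- calls$call != "ambiguous"
  acc <- mean((calls$call[conf] == "methylated") ==
                (truth[conf] == "methylated_5mC"))
  expect_gt(acc, 0.99)
  # every emitted frequency is inside [0, 1]
  rec <- aggregateNanoporeFrequency(calls)
  fr <- mcols(rec)$frequency
  expect_true(all(fr >= 0 & fr <= 1, na.rm = TRUE))
})
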