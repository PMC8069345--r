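---
title: "From methylation calls to tumor suppressor candidates: methods and design"
author: "MethylTSG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From methylation calls to tumor suppressor candidates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(MethylTSG))
```

# The problem

Promoter hypermethylation silences tumor suppressor genes (TSGs), and
hepatocellular carcinoma in particular carries genome-wide methylation
changes that precede driver mutations. Two measurement families see
methylation differently: bisulfite conversion (WGBS genome-wide, or
targeted EPIC capture of a few million CpGs) reports the *sum* of
5-methylcytosine (5mC) and 5-hydroxymethylcytosine (5hmC), while nanopore
sequencing reads 5mC directly from native DNA current signal and does not
mistake 5hmC for it. MethylTSG implements the full integration path: call
5mC per read from current events, classify promoters into hyper- and
hypomethylated classes, reconcile the three platforms (using the
bisulfite/nanopore disagreement to flag putatively hydroxymethylated
promoters), and push the confirmed hypermethylated genes through an
expression filter cascade — downregulated during liver regeneration with
later recovery, and downregulated in tumors versus normal tissue — to
nominate TSG candidates.

Because the original genome-scale inputs (a ~3x nanopore run of HepG2,
ENCODE WGBS, EPIC capture, mouse regeneration RNA-Seq, a 371-tumor /
50-normal cohort) are far beyond a test suite, the package ships a
synthetic-data module that generates all of these at toy scale *with
recorded ground truth*, so every stage is validated by planted-truth
recovery rather than by eyeballing.

# The 5mC caller

## Emission model

The caller scores each CpG site on each read against a Gaussian 6-mer
current model over the five-base alphabet {A, C, G, T, M}, with M denoting
methylated cytosine in CpG context. Each 6-mer k has one Gaussian
N(mu_k, sigma_k^2) for the picoampere current it produces in the pore. For
every CpG-containing 6-mer both the unmethylated (`...CG...`) and
methylated (`...MG...`) variant exist; 6-mers mixing an M with an
unmethylated CpG are excluded, i.e. all CpGs within one 6-mer share a
state. The per-site, per-read log-likelihood ratio is

    LLR = sum over events e [ log N(x_e; mu_M(e), sigma_M(e))
                            - log N(x_e; mu_C(e), sigma_C(e)) ]

in natural log, summed over the 6-mers spanning the CpG dinucleotide. A
6-mer that contains only the terminal C of the CpG cannot represent a
methylation state in this alphabet (the `CG -> MG` substitution needs both
bases), so the event window is the five dinucleotide-spanning reading
frames, fewer at chromosome ends. With the default synthetic model the
methylated variant is shifted by `delta = 2 * sigma`, so each event
contributes `delta^2 / (2 sigma^2) = 2` nats in expectation and a truly
methylated site scores ~10 nats over its five events — comfortably above
the calling threshold, which is what the calibration tests assert.

## Calling and aggregation

Calls are three-way at threshold T = 2.5 (natural log): `methylated` when
LLR >= +T, `unmethylated` when LLR <= -T, else `ambiguous`. Design
choices, each of which was genuinely open:

* **Boundary inclusive.** The threshold is read as the minimum acceptable
  confidence, so LLR exactly 2.5 is a methylated call.
* **Threshold applied per read and site**, before aggregation, mirroring
  confident-call extraction; an alternative reading (thresholding the
  read-aggregated score) would trade per-read specificity for coverage.
* **Ambiguous calls are excluded from both numerator and denominator** of
  the per-site frequency. A site whose calls are all ambiguous is kept
  with coverage 0 rather than dropped, so promoter read-depth accounting
  (which the 5hmC rule relies on) stays explicit; the raw read count is
  carried separately as `n_reads`.

Bisulfite counts go through the matching minimum-coverage rule:
methylation is only called for sites covered by at least five reads, and
frequency is methylated/total. Cross-platform agreement is summarized as
the Spearman rank correlation (average ranks on ties) of per-site
frequencies over sites passing both coverage filters.

# Promoter classification

Promoter windows default to (-1000, +500) bp around the TSS,
strand-aware and half-open: position p belongs to a plus-strand promoter
iff `tss - up <= p < tss + down`, mirrored on the minus strand. The
promoter database behind the original analysis does not fix a window, so
the extent is configurable; (-1000, +500) covers the proximal promoter
where methylation is most repressive.

Hypermethylated CpG sites are those with frequency strictly above 0.5
("more than 50%"; a site at exactly 0.5 is excluded). The clustering
feature for each promoter is the per-bin *fraction of covered sites that
are hypermethylated* over 20 window bins — not raw frequencies — because
the promoter classes are defined by how densely hypermethylated sites
tile the window; bins without covered sites are imputed with the
promoter-wide fraction so that sparse promoters are not pushed toward
either class by the imputation. Promoters with fewer than `min_sites = 3`
covered sites are unclassifiable: one or two sites cannot support a
profile.

k-means with k = 2 uses Lloyd iterations (via `stats::kmeans`), Euclidean
distance, farthest-point seeding from a seeded RNG and the best of 10
restarts by within-cluster sum of squares, making the labels reproducible
and invariant to input order; the cluster with the larger centroid mean is
"hyper". If every profile is identical the clustering is degenerate; the
package warns and labels all promoters by mean feature versus 0.5. Genes
collapse by OR-logic — hypermethylated iff at least one promoter is hyper
— which is why hyper promoter counts exceed hyper gene counts when genes
have alternative promoters.

# Platform integration and the 5hmC flag

Set algebra between the nanopore and WGBS hypermethylated gene sets is
exact, with the overlap percent denominated on the nanopore set (the
smaller, lower-coverage platform). Confirmation intersects the shared set
with the EPIC-derived set; genes whose promoters fall outside the EPIC
capture target can never be confirmed, which the tests assert as a mask
property.

Among WGBS-only genes, a gene is flagged putatively hydroxymethylated
when its best-covered promoter has at least 5 nanopore reads yet a mean
nanopore 5mC frequency of at most 0.1. Two quantifications were open:

* "low level of 5mC" is quantified as mean promoter frequency <= 0.1
  (configurable); mean over sites is used rather than max or
  per-site-absence because it is stable at toy coverage.
* A gene's depth is the maximum over its promoters: one adequately
  covered promoter suffices to interrogate the gene.

Genes failing the depth test are reported `insufficient_coverage`, never
"not 5hmC" — absence of reads is not evidence of absence. A covered
promoter with zero confident calls counts as zero observed 5mC.

# The expression filter cascade

Stages run in order on the confirmed hypermethylated genes; each stage
count is at most the previous (funnel monotonicity is asserted).

1. **Regeneration**: fold-down `(sham + pc) / (ph4h + pc)` strictly
   greater than 2, AND recovery at one week. "Should have recovered" is
   not a quantitative criterion by itself; the package quantifies it as
   1-week expression within twofold of sham (`ph1wk >= sham / 2`,
   configurable). Replicates are averaged per condition.
2. **Tumor cohort**: fold-down of pseudocounted *medians* (cohort
   expression is right-skewed) strictly greater than 2, AND a two-sided
   Mann-Whitney rank test (normal approximation, tie-corrected) of tumor
   versus normal below alpha = 1e-4, matching the printed significance
   level. The boxplot-level comparison in the source analysis names no
   test; Mann-Whitney is the standard distribution-free choice for a
   371-vs-50 cohort. Benjamini-Hochberg q-values are always reported and
   can drive the pass rule by configuration; the default uses raw p to
   mirror the original star annotations. A gene constant across all
   samples gets p = 1 by convention.
3. **Known-TSG exclusion**: AJAP1, GATA5 and LRAT — previously reported
   methylation-silenced liver TSGs — are excluded; the remainder are
   candidates.

The pseudocount (0.1) guards zero denominators; for strictly positive
data the decisions are stable as it shrinks (a tested property). Mouse
regeneration symbols are matched to human sets by case normalization
only; resolving true orthology is out of scope and affects on the order
of a percent of genes.

# What the synthetic data emulates — and what it does not

The generator defines the study conditions under which every property is
validated:

* **Genome**: 1 chromosome of 200 kb, 40 genes, background CpG density
  0.005/bp elevated 10-fold inside promoter windows (CpG islands).
  Sequence is random ACGT with accidental CG dinucleotides removed and CG
  planted only at annotated sites, so the FASTA and the ground truth
  agree exactly; planted sites keep >= 2 bp spacing. These sizes keep a
  full pipeline run at a few seconds while leaving ~75 CpGs per promoter
  window — enough that profile classification operates in its intended
  regime.
* **Landscape**: promoters are hyper-5mC / hypo / hyper-5hmC in
  proportions 0.3 / 0.5 / 0.2 (largest-remainder rounding, so class
  counts are exact and assertable); sites follow their promoter class
  with `p_in = 0.9` in-class and `p_out = 0.05` off-class probability;
  background sites are methylated at 0.8, emulating the broadly
  methylated genomic background that produces the TSS dip.
* **Nanopore**: per-site read depth is Poisson(10); sites within one
  promoter share the promoter's draw so promoter read depth is
  well-defined (reads are not modelled as contiguous molecules
  otherwise). 5hmC sites emit from the *unmethylated* current
  distribution: the source caller's observable is "no or low 5mC at 5hmC
  sites", and emitting C-like current reproduces exactly that observable
  without inventing 5hmC current parameters — one of several defensible
  stand-ins, and the one with no new free parameters.
* **Bisulfite**: methylated counts are Binomial(total, 1 - err) for both
  5mC and 5hmC sites and Binomial(total, err) for unmethylated sites
  (err = 0.01) — the asymmetry with the nanopore simulator is the core of
  the 5hmC test. EPIC restricts to a random 11% of sites (mirroring the
  ~3.3M of ~30M CpGs on the capture) at 3x the WGBS depth.
* **Expression**: log-normal baselines with multiplicative log-normal
  noise at CV 0.2 (TPM-like values are positive and right-skewed;
  count-level negative-binomial modelling is deliberately avoided to
  keep the filter arithmetic in one unit system). Planted candidates are
  4-fold down at 4 h and in tumors — comfortably past the 2-fold
  thresholds, as a real silenced TSG would be — with full 1-week
  recovery; the cohort is 371 tumors versus 50 normals.

Not emulated: raw squiggle/FAST5 signal, event segmentation or alignment,
read-level sequence errors, bisulfite read alignment, fragment-length
structure, copy-number or tumor-purity effects, cell-to-cell
heterogeneity (a site has one true state, not a mosaic fraction), and
inter-sample designs (single-sample methylation, as in the source study).
Passing tests therefore demonstrate that the *logic* of every stage is
correct and calibrated under realistic noise — not that the pipeline is
robust to alignment artifacts or impure tumors.

# Numerical and reproducibility choices

* All randomness flows through explicit integer seeds; stage seeds derive
  from one master seed (kept below 2^31). Identical seeds give
  byte-identical generators, pipelines and written artifacts.
* Coordinates are 0-based half-open internally and in bedMethyl/bedGraph
  output; Bismark-style coverage files are written 1-based, as that
  format expects.
* The k-means degenerate case (identical profiles), all-ambiguous sites,
  empty gene sets (overlap percent undefined, with a warning), constant
  cohort genes (p = 1) and genes missing an expression condition
  (skipped, with a warning) are all defined behaviours with tests.
* Validation problem sizes (200-400 kb genomes, 20-40 genes, 20
  end-to-end replicates) were chosen once as the smallest sizes at which
  the asserted properties are statistically comfortable — e.g. >= 0.9
  planted-candidate sensitivity and <= 5% stage false admission across
  replicates.

# Known limitations

* The five-base alphabet cannot mark a CpG whose G falls outside the
  6-mer, so one of the six overlapping frames is unusable; real pore
  models handle this with wider context.
* Closely spaced CpGs (< 6 bp) share 6-mers; their methylated variants
  are jointly substituted, so a methylated site next to an unmethylated
  one is scored slightly optimistically. At the default density this
  affects a small minority of sites.
* The 5hmC flag is indirect evidence: it identifies promoters where
  bisulfite and nanopore disagree in the direction 5hmC would cause, not
  chemistry-level 5hmC (no oxBS/TAB-seq support).
* Symbol-level mouse-to-human matching misassigns genes without 1:1
  orthologues.
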