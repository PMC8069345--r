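Package: MethylTSG
Title: Promoter Methylation Integration and Tumor Suppressor Candidate
    Discovery from Nanopore and Bisulfite Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates 5-methylcytosine calls from nanopore sequencing with
    whole-genome and targeted (EPIC) bisulfite data to nominate tumor
    suppressor gene candidates silenced by promoter hypermethylation.
    Provides a per-read log-likelihood-ratio 5mC caller over a five-base
    alphabet 6-mer Gaussian current model, k-means classification of
    promoters into hyper- and hypomethylated classes, cross-platform gene-set
    integration with a putative-5-hydroxymethylcytosine flagging rule, and a
    two-stage expression filter cascade (liver-regeneration downregulation
    with recovery, tumor-versus-normal downregulation). A synthetic-data
    module simulates a toy genome, nanopore current events, bisulfite count
    tables and expression tables with recorded ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Epigenetics, DNAMethylation, Sequencing, Coverage
RoxygenNote: 7.3.3
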