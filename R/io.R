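#' Write a toy genome to FASTA
#' @param genome a [ToyGenome-class].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
  writeXStringSet(genome@sequence, path)
  invisible(path)
}

#' Write promoter windows to BED6
#'
#' 0-based half-open BED6; the name field is `promoterID|geneSymbol`.
#'
#' @param promoters GRanges with mcols promoter_id, gene, tss0.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePromoterBed <- function(promoters, path) {
  df <- data.frame(
    chrom = as.character(seqnames(promoters)),
    start = start(promoters) - 1L,
    end = end(promoters),
    name = paste(mcols(promoters)$promoter_id, mcols(promoters)$gene,
                 sep = "|"),
    score = 0L,
    strand = as.character(strand(promoters)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read promoter windows from BED6
#'
#' Expects 6 tab-separated columns with name = `promoterID|geneSymbol`; the
#' TSS is recovered from the strand and the window geometry given by
#' `upstream`. Malformed lines raise an error naming the line.
#'
#' @param path BED6 path.
#' @param upstream bp of the window upstream of the TSS (default 1000);
#'   needed to recover the TSS from the interval.
#' @return GRanges with mcols promoter_id, gene, tss0.
#' @export
readPromoterBed <- function(path, upstream = 1000) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 6)
      stop("malformed BED6 at line ", i, ": expected 6 fields, got ",
           length(f))
    if (is.na(suppressWarnings(as.integer(f[2]))) ||
        is.na(suppressWarnings(as.integer(f[3]))))
      stop("malformed BED6 at line ", i, ": non-numeric interval")
    if (!f[6] %in% c("+", "-"))
      stop("malformed BED6 at line ", i, ": bad strand '", f[6], "'")
    if (!grepl("|", f[4], fixed = TRUE))
      stop("malformed BED6 at line ", i,
           ": name must be promoterID|geneSymbol")
  }
  m <- do.call(rbind, fields)
  start0 <- as.integer(m[, 2]); end0 <- as.integer(m[, 3])
  strand <- m[, 6]
  nm <- strsplit(m[, 4], "|", fixed = TRUE)
  tss0 <- ifelse(strand == "+", start0 + upstream, end0 - 1L - upstream)
  gr <- GRanges(m[, 1], IRanges(start0 + 1L, end0), strand = strand)
  mcols(gr)$promoter_id <- vapply(nm, `[`, character(1), 1)
  mcols(gr)$gene <- vapply(nm, `[`, character(1), 2)
  mcols(gr)$tss0 <- as.integer(tss0)
  gr
}

#' Write per-site methylation records as bedMethyl-style TSV
#'
#' Columns: chrom, start (0-based), end, coverage, methylated, frequency in
#' percent. Sites without confident coverage get an empty frequency of 0 and
#' coverage 0.
#'
#' @param records GRanges of per-site records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBedMethyl <- function(records, path) {
  df <- data.frame(
    chrom = as.character(seqnames(records)),
    start = pos0(records),
    end = pos0(records) + 1L,
    coverage = mcols(records)$coverage,
    methylated = mcols(records)$methylated,
    frequency_pct = ifelse(is.na(mcols(records)$frequency), 0,
                           100 * mcols(records)$frequency))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read bedMethyl-style TSV into per-site records
#' @param path input path.
#' @param platform platform label for the records.
#' @return GRanges of per-site records.
#' @export
readBedMethyl <- function(path, platform = "nanopore") {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "coverage",
                                        "methylated", "frequency_pct"),
                          stringsAsFactors = FALSE)
  newRecords(df$chrom, df$start, platform, df$coverage, df$methylated,
             ifelse(df$coverage > 0, df$methylated / df$coverage, NA_real_))
}

#' Write a bedGraph browser track of methylation frequencies
#' @param records GRanges of per-site records.
#' @param path output path.
#' @param name track name.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(records, path, name = "methylation") {
  keep <- !is.na(mcols(records)$frequency)
  records <- records[keep]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  utils::write.table(
    data.frame(as.character(seqnames(records)), pos0(records),
               pos0(records) + 1L, mcols(records)$frequency),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a bisulfite count table as Bismark-coverage-style TSV
#'
#' Columns: chrom, start (1-based), end, methylation percent, methylated
#' count, unmethylated count.
#'
#' @param table data.frame with chrom, pos (0-based), methylated_count,
#'   total_count.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBismarkCoverage <- function(table, path) {
  df <- data.frame(
    chrom = table$chrom, start = table$pos + 1L, end = table$pos + 1L,
    pct = 100 * table$methylated_count / table$total_count,
    methylated = table$methylated_count,
    unmethylated = table$total_count - table$methylated_count)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a Bismark-coverage-style TSV into a bisulfite count table
#' @param path input path.
#' @param platform "wgbs" or "epic".
#' @return data.frame with chrom, pos (0-based), strand, methylated_count,
#'   total_count, platform.
#' @export
readBismarkCoverage <- function(path, platform = "wgbs") {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "pct",
                                        "methylated", "unmethylated"),
                          stringsAsFactors = FALSE)
  data.frame(chrom = df$chrom, pos = df$start - 1L, strand = "+",
             methylated_count = df$methylated,
             total_count = df$methylated + df$unmethylated,
             platform = platform, stringsAsFactors = FALSE)
}

#' Read / write a 6-mer current model as TSV
#'
#' Nanopolish-style three-column TSV: kmer, level_mean, level_stdv.
#'
#' @param path TSV path.
#' @return [readSixMerModel()]: a [SixMerModel-class];
#'   [writeSixMerModel()]: `path`, invisibly.
#' @export
readSixMerModel <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  methods::new("SixMerModel", params = df[c("kmer", "level_mean",
                                            "level_stdv")])
}

#' @rdname readSixMerModel
#' @param model a [SixMerModel-class].
#' @export
writeSixMerModel <- function(model, path) {
  utils::write.table(model@params, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a nanopore event set as (optionally gzipped) TSV
#' @param events event data.frame from [simulateNanoporeEvents()].
#' @param path output path; a ".gz" suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
writeEventsTsv <- function(events, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(events, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a nanopore event set written by [writeEventsTsv()]
#' @param path input path (plain or gzipped TSV).
#' @return event data.frame.
#' @export
readEventsTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
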