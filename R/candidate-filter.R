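#' Regeneration-downregulation filter with recovery criterion
#'
#' For each gene with sham, 4 h post-partial-hepatectomy (ph4h) and 1 week
#' post-PH (ph1wk) values, computes the pseudocounted fold-down
#' `(sham + pc) / (ph4h + pc)` and the recovery indicator
#' `ph1wk >= sham / recoveryFactor`. A gene passes iff it is downregulated
#' strictly more than `fcThreshold`-fold at 4 h AND has recovered at 1 week.
#' Genes missing a condition are skipped with a warning.
#'
#' @param expr data.frame with columns gene, condition (sham/ph4h/ph1wk),
#'   value; replicate rows per condition are averaged.
#' @param fcThreshold fold-change threshold (default 2, strict).
#' @param recoveryFactor recovery tolerance: 1-week expression must be
#'   within this factor of sham (default 2).
#' @param pseudocount added to numerator and denominator (default 0.1).
#' @return data.frame with gene, sham, ph4h, ph1wk, fold_down, recovered,
#'   passes.
#' @export
regenerationFilter <- function(expr, fcThreshold = 2, recoveryFactor = 2,
                               pseudocount = 0.1) {
  stopifnot(all(c("gene", "condition", "value") %in% names(expr)),
            fcThreshold > 0, recoveryFactor >= 1, pseudocount >= 0)
  if (any(expr$value < 0)) stop("expression values must be non-negative")
  expr$gene <- normalizeSymbols(expr$gene)
  wide <- lapply(c("sham", "ph4h", "ph1wk"), function(cond) {
    sub <- expr[expr$condition == cond, , drop = FALSE]
    tapply(sub$value, sub$gene, mean)
  })
  names(wide) <- c("sham", "ph4h", "ph1wk")
  genes <- sort(unique(expr$gene))
  have <- vapply(genes, function(g)
    all(vapply(wide, function(w) g %in% names(w), logical(1))), logical(1))
  if (any(!have))
    warning(sum(!have), " gene(s) missing a condition were skipped")
  genes <- genes[have]
  sham <- unname(wide$sham[genes]); ph4 <- unname(wide$ph4h[genes])
  wk1 <- unname(wide$ph1wk[genes])
  fold <- (sham + pseudocount) / (ph4 + pseudocount)
  rec <- wk1 >= sham / recoveryFactor
  data.frame(gene = genes, sham = sham, ph4h = ph4, ph1wk = wk1,
             fold_down = fold, recovered = rec,
             passes = fold > fcThreshold & rec,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tumor-versus-normal downregulation filter (rank test on a cohort)
#'
#' Per gene: fold-down of pseudocounted medians
#' `(median normal + pc) / (median tumor + pc)` and a two-sided
#' Mann-Whitney rank test (normal approximation with tie correction) of
#' tumor versus normal values; Benjamini-Hochberg q-values are reported
#' alongside raw p-values. A gene passes iff fold_down > `fcThreshold` and
#' the raw p-value (or the q-value when `useBH = TRUE`) is below `alpha`.
#' A gene constant across all samples gets p = 1 by convention.
#'
#' @param expr data.frame with columns gene, sample, group (normal/tumor),
#'   value.
#' @param fcThreshold fold-change threshold on medians (default 2, strict).
#' @param alpha significance level (default 1e-4, the printed star level).
#' @param pseudocount added to both medians (default 0.1).
#' @param useBH use BH q-values instead of raw p for the pass rule.
#' @return data.frame with gene, normal_median, tumor_median, fold_down,
#'   p_value, q_value, passes.
#' @export
tumorFilter <- function(expr, fcThreshold = 2, alpha = 1e-4,
                        pseudocount = 0.1, useBH = FALSE) {
  stopifnot(all(c("gene", "group", "value") %in% names(expr)),
            all(expr$group %in% c("normal", "tumor")))
  expr$gene <- normalizeSymbols(expr$gene)
  genes <- sort(unique(expr$gene))
  nNorm <- length(unique(expr$sample[expr$group == "normal"]))
  nTum <- length(unique(expr$sample[expr$group == "tumor"]))
  if (nNorm < 3 || nTum < 3)
    stop("need at least 3 samples per group, got ", nNorm, " normal / ",
         nTum, " tumor")
  res <- lapply(genes, function(g) {
    v <- expr[expr$gene == g, , drop = FALSE]
    norm <- v$value[v$group == "normal"]
    tum <- v$value[v$group == "tumor"]
    medN <- stats::median(norm); medT <- stats::median(tum)
    p <- if (length(unique(c(norm, tum))) == 1) 1 else
      suppressWarnings(stats::wilcox.test(tum, norm,
                                          exact = FALSE)$p.value)
    c(medN, medT, (medN + pseudocount) / (medT + pseudocount), p)
  })
  m <- do.call(rbind, res)
  q <- stats::p.adjust(m[, 4], method = "BH")
  crit <- if (useBH) q else m[, 4]
  data.frame(gene = genes, normal_median = m[, 1], tumor_median = m[, 2],
             fold_down = m[, 3], p_value = m[, 4], q_value = q,
             passes = m[, 3] > fcThreshold & crit < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Exclude known tumor suppressor genes from a passing gene list
#'
#' Genes on the known-TSG list (default the three previously reported
#' methylation-silenced liver TSGs AJAP1, GATA5 and LRAT) are marked
#' excluded; the remainder are candidates.
#'
#' @param genes character vector of passing genes.
#' @param knownTsgs character vector of known TSGs.
#' @return data.frame with gene, known_tsg, status (candidate /
#'   excluded_known_tsg).
#' @export
#' @examples
#' excludeKnown(c("GCK", "AJAP1", "EFS"))
excludeKnown <- function(genes, knownTsgs = c("AJAP1", "GATA5", "LRAT")) {
  genes <- unique(normalizeSymbols(genes))
  known <- genes %in% normalizeSymbols(knownTsgs)
  data.frame(gene = genes, known_tsg = known,
             status = ifelse(known, "excluded_known_tsg", "candidate"),
             stringsAsFactors = FALSE)
}

#' Run the full candidate filter cascade
#'
#' Applies, in pipeline order, (1) restriction to the
#' hypermethylation-confirmed genes, (2) the regeneration filter
#' ([regenerationFilter()]), (3) the tumor cohort filter ([tumorFilter()])
#' on the regeneration passers, and (4) the known-TSG exclusion
#' ([excludeKnown()]); symbols are case-normalized so mouse regeneration
#' symbols match their human counterparts, and unmatched confirmed genes are
#' reported via message.
#'
#' @param confirmedGenes character, hypermethylation-confirmed genes.
#' @param regenExpr regeneration expression table (see
#'   [regenerationFilter()]).
#' @param tumorExpr cohort expression table (see [tumorFilter()]).
#' @param fcRegeneration,fcTumor fold-change thresholds (default 2).
#' @param alpha rank-test significance level (default 1e-4).
#' @param recoveryFactor recovery tolerance (default 2).
#' @param pseudocount fold-change pseudocount (default 0.1).
#' @param knownTsgs known-TSG exclusion list.
#' @param useBH use BH q-values in the tumor pass rule.
#' @return A [CandidateTable-class] with per-gene stage flags and the funnel
#'   of stage counts (confirmed, regeneration_pass, tumor_pass, candidates).
#' @export
runCascade <- function(confirmedGenes, regenExpr, tumorExpr,
                       fcRegeneration = 2, fcTumor = 2, alpha = 1e-4,
                       recoveryFactor = 2, pseudocount = 0.1,
                       knownTsgs = c("AJAP1", "GATA5", "LRAT"),
                       useBH = FALSE) {
  confirmed <- sort(unique(normalizeSymbols(confirmedGenes)))
  n <- length(confirmed)
  tab <- data.frame(gene = confirmed,
                    hypermethylated_confirmed = rep(TRUE, n),
                    regeneration_pass = rep(FALSE, n),
                    tumor_pass = rep(FALSE, n),
                    known_tsg = rep(FALSE, n),
                    fold_down_ph4h = rep(NA_real_, n),
                    fold_down_tumor = rep(NA_real_, n),
                    p_value = rep(NA_real_, n), q_value = rep(NA_real_, n),
                    status = rep("excluded_regeneration", n),
                    stringsAsFactors = FALSE)
  if (length(confirmed)) {
    regenExpr <- regenExpr[normalizeSymbols(regenExpr$gene) %in% confirmed, ,
                           drop = FALSE]
    unmatched <- setdiff(confirmed, normalizeSymbols(regenExpr$gene))
    if (length(unmatched))
      message(length(unmatched),
              " confirmed gene(s) absent from the regeneration table")
    if (nrow(regenExpr)) {
      rr <- regenerationFilter(regenExpr, fcThreshold = fcRegeneration,
                               recoveryFactor = recoveryFactor,
                               pseudocount = pseudocount)
      idx <- match(rr$gene, tab$gene)
      tab$fold_down_ph4h[idx] <- rr$fold_down
      tab$regeneration_pass[idx] <- rr$passes
    }
    regenPass <- tab$gene[tab$regeneration_pass]
    tumorExpr <- tumorExpr[normalizeSymbols(tumorExpr$gene) %in% regenPass, ,
                           drop = FALSE]
    if (length(regenPass) && nrow(tumorExpr)) {
      tr <- tumorFilter(tumorExpr, fcThreshold = fcTumor, alpha = alpha,
                        pseudocount = pseudocount, useBH = useBH)
      idx <- match(tr$gene, tab$gene)
      tab$fold_down_tumor[idx] <- tr$fold_down
      tab$p_value[idx] <- tr$p_value
      tab$q_value[idx] <- tr$q_value
      tab$tumor_pass[idx] <- tr$passes
    }
    tab$known_tsg <- tab$gene %in% normalizeSymbols(knownTsgs)
    tab$status <- ifelse(!tab$regeneration_pass, "excluded_regeneration",
                  ifelse(!tab$tumor_pass, "excluded_tumor",
                  ifelse(tab$known_tsg, "excluded_known_tsg", "candidate")))
  }
  funnel <- c(confirmed = length(confirmed),
              regeneration_pass = sum(tab$regeneration_pass),
              tumor_pass = sum(tab$regeneration_pass & tab$tumor_pass),
              candidates = sum(tab$status == "candidate"))
  methods::new("CandidateTable", table = tab,
               funnel = stats::setNames(as.integer(funnel), names(funnel)))
}
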