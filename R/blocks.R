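#' Classify a SNP pair from its |D'| confidence bounds
#'
#' Gabriel-rule classification: \code{"STRONG_LD"} when the upper bound
#' exceeds 0.98 and the lower bound exceeds 0.70; \code{"RECOMB"} (strong
#' evidence for historical recombination) when the upper bound is below
#' 0.90; otherwise \code{"UNINFORMATIVE"}.
#'
#' @param CL,CU numeric vectors of lower/upper one-sided 95 percent
#'   confidence bounds on |D'|.
#' @param cu_strong,cl_strong,cu_recomb rule thresholds (defaults 0.98,
#'   0.70, 0.90).
#' @return character vector over \{"STRONG_LD", "RECOMB",
#'   "UNINFORMATIVE"\}.
#' @examples
#' classifyPair(0.80, 0.99)   # STRONG_LD
#' classifyPair(0.10, 0.85)   # RECOMB
#' @export
classifyPair <- function(CL, CU, cu_strong = 0.98, cl_strong = 0.70,
                         cu_recomb = 0.90) {
    ifelse(CU > cu_strong & CL > cl_strong, "STRONG_LD",
           ifelse(CU < cu_recomb, "RECOMB", "UNINFORMATIVE"))
}

.sat <- function(M) {
    ## summed-area table; .satSum(P, a, b) = sum(M[a:b, a:b])
    apply(apply(M, 2, cumsum), 1, cumsum)    # note: transposed, M symmetric
}

.satSum <- function(P, a, b) {
    tot <- P[cbind(b, b)]
    left <- ifelse(a > 1, P[cbind(pmax(a - 1, 1), b)], 0)
    top <- ifelse(a > 1, P[cbind(b, pmax(a - 1, 1))], 0)
    corner <- ifelse(a > 1, P[cbind(pmax(a - 1, 1), pmax(a - 1, 1))], 0)
    tot - left - top + corner
}

#' Gabriel haplotype-block detection
#'
#' A candidate span of consecutive SNPs [i..j] qualifies when its boundary
#' pair (i, j) is in strong LD and, among the informative pairs (strong LD
#' or recombination) wholly inside the span, the strong-LD fraction is at
#' least \code{min_strong_fraction}.  Qualifying candidates are accepted
#' greedily in decreasing physical span (ties: leftmost first), skipping
#' any candidate overlapping an already accepted block.  Only the core
#' Gabriel criterion is applied; size-stratified sub-rules of particular
#' GUI implementations are deliberately not reproduced.
#'
#' @param pairs data.frame of classified within-chromosome pairs with
#'   columns snp_i, snp_j, chrom and either \code{class} (from
#'   \code{\link{classifyPair}}) or CL and CU from which classes are
#'   derived.
#' @param markers marker map \code{GRanges} (defines SNP order and bp).
#' @param min_strong_fraction minimum strong-LD fraction among informative
#'   pairs in a span (default 0.95).
#' @param max_span_kb optional cap on candidate span; NULL (default) means
#'   unlimited, since real data show blocks beyond common 500-kb caps.
#' @param ... thresholds passed to \code{\link{classifyPair}} when classes
#'   are derived from CL/CU.
#' @return data.frame of blocks: chrom, first, last (1-based SNP indices in
#'   chromosome map order), start_bp, end_bp, n_snps, span_kb, snps
#'   (comma-separated ids).
#' @export
gabrielBlocks <- function(pairs, markers, min_strong_fraction = 0.95,
                          max_span_kb = NULL, ...) {
    if (is.null(pairs$class)) pairs$class <- classifyPair(pairs$CL, pairs$CU, ...)
    chroms <- unique(as.character(seqnames(markers)))
    blocks <- list()
    for (ch in chroms) {
        idx <- which(as.character(seqnames(markers)) == ch)
        m <- length(idx)
        if (m < 2L) next
        ids <- names(markers)[idx]
        bp <- GenomicRanges::start(markers)[idx]
        pc <- pairs[pairs$chrom == ch, , drop = FALSE]
        if (!nrow(pc)) next
        i <- match(pc$snp_i, ids)
        j <- match(pc$snp_j, ids)
        if (any(is.na(i)) || any(is.na(j)))
            stop("pair references a SNP absent from the marker map")
        S <- matrix(0, m, m); I <- matrix(0, m, m)
        strong <- pc$class == "STRONG_LD"
        inf <- pc$class != "UNINFORMATIVE"
        S[cbind(i, j)[strong, , drop = FALSE]] <- 1
        S[cbind(j, i)[strong, , drop = FALSE]] <- 1
        I[cbind(i, j)[inf, , drop = FALSE]] <- 1
        I[cbind(j, i)[inf, , drop = FALSE]] <- 1
        PS <- .sat(S); PI <- .sat(I)
        cand <- which(upper.tri(S) & S == 1, arr.ind = TRUE)
        if (!nrow(cand)) next
        a <- cand[, 1]; b <- cand[, 2]
        span_bp <- bp[b] - bp[a]
        if (!is.null(max_span_kb)) {
            ok <- span_bp <= max_span_kb * 1000
            a <- a[ok]; b <- b[ok]; span_bp <- span_bp[ok]
        }
        if (!length(a)) next
        n_strong <- .satSum(PS, a, b) / 2
        n_inf <- .satSum(PI, a, b) / 2
        ok <- n_inf > 0 & n_strong / n_inf >= min_strong_fraction
        a <- a[ok]; b <- b[ok]; span_bp <- span_bp[ok]
        if (!length(a)) next
        ord <- order(-span_bp, a, b)
        used <- logical(m)
        acc <- list()
        for (k in ord) {
            if (any(used[a[k]:b[k]])) next
            used[a[k]:b[k]] <- TRUE
            acc[[length(acc) + 1L]] <- data.frame(
                chrom = ch, first = a[k], last = b[k],
                start_bp = bp[a[k]], end_bp = bp[b[k]],
                n_snps = b[k] - a[k] + 1L,
                span_kb = (bp[b[k]] - bp[a[k]]) / 1000,
                snps = paste(ids[a[k]:b[k]], collapse = ","),
                stringsAsFactors = FALSE)
        }
        blocks <- c(blocks, acc)
    }
    if (!length(blocks))
        return(data.frame(chrom = character(0), first = integer(0),
                          last = integer(0), start_bp = integer(0),
                          end_bp = integer(0), n_snps = integer(0),
                          span_kb = numeric(0), snps = character(0)))
    out <- do.call(rbind, c(blocks, make.row.names = FALSE))
    out[order(out$chrom, out$start_bp), , drop = FALSE]
}

#' Per-chromosome block summary
#'
#' Summarizes detected blocks per chromosome and over the genome: block
#' count, total/min/max block span (kb), percent of chromosome length in
#' blocks (when chromosome lengths are supplied), SNPs inside blocks and
#' their percent of all mapped SNPs.
#'
#' @param blocks data.frame from \code{\link{gabrielBlocks}}.
#' @param markers marker map \code{GRanges} of all QC-passed SNPs.
#' @param chrom_lengths optional named numeric vector of chromosome
#'   lengths in bp; when absent the percent-length column is NA with a
#'   warning.
#' @return data.frame, one row per chromosome plus an "All" totals row.
#' @export
blockSummary <- function(blocks, markers, chrom_lengths = NULL) {
    chroms <- unique(as.character(seqnames(markers)))
    if (is.null(chrom_lengths))
        warning("chromosome lengths not supplied; percent-length column is NA")
    rows <- lapply(chroms, function(ch) {
        b <- blocks[blocks$chrom == ch, , drop = FALSE]
        m_ch <- sum(as.character(seqnames(markers)) == ch)
        len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
            chrom_lengths[[ch]] else NA_real_
        tot_kb <- sum(b$span_kb)
        data.frame(
            chrom = ch,
            n_blocks = nrow(b),
            total_kb = tot_kb,
            pct_length = if (!is.na(len)) 100 * tot_kb * 1000 / len else NA_real_,
            min_kb = if (nrow(b)) min(b$span_kb) else NA_real_,
            max_kb = if (nrow(b)) max(b$span_kb) else NA_real_,
            n_snps_in_blocks = sum(b$n_snps),
            pct_snps = 100 * sum(b$n_snps) / m_ch,
            stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, c(rows, make.row.names = FALSE))
    tot_len <- if (!is.null(chrom_lengths)) sum(chrom_lengths) else NA_real_
    all_row <- data.frame(
        chrom = "All",
        n_blocks = sum(tab$n_blocks),
        total_kb = sum(tab$total_kb),
        pct_length = if (!is.na(tot_len))
            100 * sum(tab$total_kb) * 1000 / tot_len else NA_real_,
        min_kb = if (any(tab$n_blocks > 0)) min(tab$min_kb, na.rm = TRUE)
                 else NA_real_,
        max_kb = if (any(tab$n_blocks > 0)) max(tab$max_kb, na.rm = TRUE)
                 else NA_real_,
        n_snps_in_blocks = sum(tab$n_snps_in_blocks),
        pct_snps = 100 * sum(tab$n_snps_in_blocks) / length(markers),
        stringsAsFactors = FALSE)
    rbind(tab, all_row)
}
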