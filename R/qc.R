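#' Per-marker summary statistics
#'
#' Computes, per SNP: call rate, reference-allele frequency among
#' non-missing genotypes, minor-allele frequency, observed heterozygosity
#' and the Hardy-Weinberg exact p-value.
#'
#' @param g a \linkS4class{SnpGenotypes}.
#' @param hwe_method \code{"exact"} (conditional exact test, default) or
#'   \code{"chisq"} (1-df goodness-of-fit).
#' @return a data.frame with one row per SNP (id, chrom, pos_bp, call_rate,
#'   p_ref, maf, het_obs, hwe_p).
#' @export
markerStats <- function(g, hwe_method = c("exact", "chisq")) {
    hwe_method <- match.arg(hwe_method)
    d <- dosage(g)
    mm <- markers(g)
    n_ind <- ncol(d)
    called <- !is.na(d)
    n_called <- rowSums(called)
    call_rate <- n_called / n_ind
    ref_count <- rowSums(d, na.rm = TRUE)
    p_ref <- ifelse(n_called > 0, ref_count / (2 * n_called), NA_real_)
    maf <- pmin(p_ref, 1 - p_ref)
    het_obs <- ifelse(n_called > 0,
                      rowSums(d == 1L, na.rm = TRUE) / n_called, NA_real_)
    nAA <- rowSums(d == 2L, na.rm = TRUE)
    nAa <- rowSums(d == 1L, na.rm = TRUE)
    naa <- rowSums(d == 0L, na.rm = TRUE)
    hwe_p <- vapply(seq_len(nrow(d)), function(i) {
        if (n_called[i] == 0L) return(NA_real_)
        if (hwe_method == "exact") hweExactPvalue(nAA[i], nAa[i], naa[i])
        else .hweChisqPvalue(nAA[i], nAa[i], naa[i])
    }, numeric(1))
    data.frame(id = names(mm), chrom = as.character(seqnames(mm)),
               pos_bp = GenomicRanges::start(mm), call_rate = call_rate,
               p_ref = p_ref, maf = maf, het_obs = het_obs, hwe_p = hwe_p,
               row.names = NULL)
}

#' Exact Hardy-Weinberg test p-value
#'
#' Conditional exact test: given the genotype total and the minor-allele
#' count, the two-sided p-value is the summed probability of all
#' heterozygote counts whose conditional probability does not exceed that
#' of the observed configuration (Wigginton-style enumeration).
#'
#' @param n_AA,n_Aa,n_aa nonnegative genotype counts; at least one must be
#'   positive.
#' @return p-value in (0, 1].
#' @examples
#' hweExactPvalue(1, 0, 1)   # 1/3
#' hweExactPvalue(0, 2, 0)   # 1
#' @export
hweExactPvalue <- function(n_AA, n_Aa, n_aa) {
    n_AA <- as.integer(n_AA); n_Aa <- as.integer(n_Aa); n_aa <- as.integer(n_aa)
    if (any(c(n_AA, n_Aa, n_aa) < 0L)) stop("genotype counts must be nonnegative")
    n <- n_AA + n_Aa + n_aa
    if (n == 0L) stop("all genotype counts are zero")
    rare <- min(2L * n_AA + n_Aa, 2L * n_aa + n_Aa)
    if (rare == 0L) return(1)                 # monomorphic: single configuration
    hets <- seq.int(rare %% 2L, rare, by = 2L)
    probs <- numeric(length(hets))
    mid_i <- which.min(abs(hets - rare * (2 * n - rare) / (2 * n)))
    mid <- hets[mid_i]
    probs[mid_i] <- 1
    homr <- (rare - mid) %/% 2L
    homc <- n - mid - homr
    h <- mid; i <- mid_i
    while (h > 1L) {                          # downward recurrence
        probs[i - 1L] <- probs[i] * h * (h - 1) / (4 * (homr + 1) * (homc + 1))
        homr <- homr + 1L; homc <- homc + 1L
        h <- h - 2L; i <- i - 1L
    }
    homr <- (rare - mid) %/% 2L
    homc <- n - mid - homr
    h <- mid; i <- mid_i
    while (h <= rare - 2L) {                  # upward recurrence
        probs[i + 1L] <- probs[i] * 4 * homr * homc / ((h + 2) * (h + 1))
        homr <- homr - 1L; homc <- homc - 1L
        h <- h + 2L; i <- i + 1L
    }
    probs <- probs / sum(probs)
    obs <- probs[match(n_Aa, hets)]
    min(1, sum(probs[probs <= obs * (1 + 1e-10)]))
}

.hweChisqPvalue <- function(n_AA, n_Aa, n_aa) {
    n <- n_AA + n_Aa + n_aa
    if (n == 0L) stop("all genotype counts are zero")
    p <- (2 * n_AA + n_Aa) / (2 * n)
    if (p == 0 || p == 1) return(1)
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    x2 <- sum((c(n_AA, n_Aa, n_aa) - e)^2 / e)
    stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

.ledgerRow <- function(step, unit, threshold, removed, remaining) {
    data.frame(step = step, unit = unit, threshold = threshold,
               removed = as.integer(removed), remaining = as.integer(remaining),
               stringsAsFactors = FALSE)
}

#' Per-individual quality control
#'
#' Removes individuals whose missing-genotype fraction exceeds
#' \code{max_missing} (strictly greater than, matching a "more than x
#' percent missing" rule).  Run before any per-marker filter so that
#' marker call rates are computed on the retained individuals.
#'
#' @param g a \linkS4class{SnpGenotypes}.
#' @param max_missing maximum tolerated missing fraction, in (0, 1);
#'   default 0.10.
#' @return list with elements \code{genotypes} (filtered) and
#'   \code{ledger} (one-row QC ledger data.frame).
#' @export
filterIndividuals <- function(g, max_missing = 0.10) {
    stopifnot(max_missing > 0, max_missing < 1)
    d <- dosage(g)
    if (nrow(d) == 0L || ncol(d) == 0L) stop("empty genotype matrix")
    miss <- colMeans(is.na(d))
    keep <- miss <= max_missing
    ledger <- .ledgerRow("individual_missingness", "individuals",
                         max_missing, sum(!keep), sum(keep))
    list(genotypes = g[, keep], ledger = ledger)
}

#' Per-marker quality control
#'
#' Applies, sequentially, (i) a call-rate filter, (ii) a minor-allele
#' frequency filter and (iii) a Hardy-Weinberg filter; a SNP removed at
#' one step is not counted at a later step, so the ledger rows sum to the
#' total removed.  Thresholds are inclusive as printed: a SNP is retained
#' when call rate >= \code{min_call}, MAF >= \code{min_maf} and HWE
#' p-value > \code{hwe_alpha}.
#'
#' @param g a \linkS4class{SnpGenotypes}, already individual-filtered.
#' @param min_call minimum call rate (default 0.95).
#' @param min_maf minimum minor-allele frequency (default 0.05).
#' @param hwe_alpha HWE rejection level (default 1e-5).
#' @param hwe_method see \code{\link{markerStats}}.
#' @return list with \code{genotypes}, \code{stats} (markerStats of the
#'   input with a \code{kept} flag) and \code{ledger}.
#' @export
markerQC <- function(g, min_call = 0.95, min_maf = 0.05, hwe_alpha = 1e-5,
                     hwe_method = c("exact", "chisq")) {
    st <- markerStats(g, hwe_method = match.arg(hwe_method))
    m0 <- nrow(st)
    fail_call <- st$call_rate < min_call
    rem1 <- m0 - sum(fail_call)
    fail_maf <- !fail_call & (is.na(st$maf) | st$maf < min_maf)
    rem2 <- rem1 - sum(fail_maf)
    fail_hwe <- !fail_call & !fail_maf & (is.na(st$hwe_p) | st$hwe_p <= hwe_alpha)
    rem3 <- rem2 - sum(fail_hwe)
    ledger <- rbind(
        .ledgerRow("call_rate", "SNPs", min_call, sum(fail_call), rem1),
        .ledgerRow("maf", "SNPs", min_maf, sum(fail_maf), rem2),
        .ledgerRow("hwe", "SNPs", hwe_alpha, sum(fail_hwe), rem3))
    keep <- !(fail_call | fail_maf | fail_hwe)
    st$kept <- keep
    list(genotypes = g[keep, ], stats = st, ledger = ledger)
}

#' Mendelian-inconsistency cleaning against sires
#'
#' A sire-daughter pair is in conflict at a SNP when the two are homozygous
#' for opposite alleles (dosages 2 vs 0).  The daughter genotype is set
#' missing, unless the sire conflicts with more than
#' \code{max_sire_conflict} of its genotyped daughters at that SNP, in
#' which case the sire genotype is blanked instead and the daughters kept
#' (a cluster of conflicts indicts the sire's genotype, not the
#' daughters').
#'
#' @param g a \linkS4class{SnpGenotypes} containing sires and daughters.
#' @param ped a \linkS4class{Pedigree} naming each daughter's sire.
#' @param max_sire_conflict fraction of daughters above which the sire is
#'   blanked (default 0.05).
#' @return list with \code{genotypes} (cleaned) and \code{conflicts}
#'   (data.frame: snp, sire, n_conflicts, action).
#' @export
mendelianClean <- function(g, ped, max_sire_conflict = 0.05) {
    d <- dosage(g)
    mm <- markers(g)
    r <- pedigreeTable(ped)
    sires <- unique(r$sire[!is.na(r$sire)])
    sires <- sires[sires %in% colnames(d)]
    reports <- list()
    for (s in sires) {
        kids <- r$id[!is.na(r$sire) & r$sire == s]
        kids <- kids[kids %in% colnames(d)]
        if (!length(kids)) next
        gs <- d[, s]
        gd <- d[, kids, drop = FALSE]
        conf <- (gs == 2L & gd == 0L) | (gs == 0L & gd == 2L)
        conf[is.na(conf)] <- FALSE
        nconf <- rowSums(conf)
        hit <- which(nconf > 0L)
        if (!length(hit)) next
        n_typed <- rowSums(!is.na(gd))
        blank_sire <- nconf > max_sire_conflict * n_typed
        for (i in hit) {
            if (blank_sire[i]) {
                d[i, s] <- NA_integer_
            } else {
                d[i, kids[conf[i, ]]] <- NA_integer_
            }
        }
        reports[[s]] <- data.frame(
            snp = names(mm)[hit], sire = s,
            n_conflicts = as.integer(nconf[hit]),
            action = ifelse(blank_sire[hit], "sire_blanked",
                            "daughters_blanked"),
            stringsAsFactors = FALSE, row.names = NULL)
    }
    conflicts <- if (length(reports)) do.call(rbind, c(reports,
                                                       make.row.names = FALSE))
                 else data.frame(snp = character(0), sire = character(0),
                                 n_conflicts = integer(0),
                                 action = character(0))
    list(genotypes = SnpGenotypes(d, mm), conflicts = conflicts)
}

#' Sire- and frequency-based genotype imputation
#'
#' For a missing daughter genotype with a genotyped sire, the paternal
#' allele distribution follows from the sire genotype (homozygote: certain;
#' heterozygote: 1/2 each) and the maternal allele from the current
#' reference-allele frequency; the genotype posterior is their convolution.
#' The modal genotype is imputed only when its posterior probability
#' reaches \code{accept_prob}, which prevents over-representation of very
#' frequent alleles.  After each full pass the allele frequencies are
#' re-estimated from the updated matrix (observed plus already-imputed
#' genotypes) and the pass repeats; the whole process is deterministic.
#'
#' @param g a \linkS4class{SnpGenotypes}, Mendelian-cleaned.
#' @param ped a \linkS4class{Pedigree}.
#' @param iterations number of inference passes (default 10).
#' @param accept_prob minimum posterior probability to impute; must exceed
#'   0.5 (a tie could otherwise be "modal").
#' @return an imputed \linkS4class{SnpGenotypes}; observed genotypes are
#'   never overwritten.
#' @export
imputeFromSire <- function(g, ped, iterations = 10L, accept_prob = 0.95) {
    if (accept_prob <= 0.5) stop("accept_prob must exceed 0.5")
    d <- dosage(g)
    mm <- markers(g)
    r <- pedigreeTable(ped)
    sire_of <- r$sire[match(colnames(d), r$id)]
    has_sire <- !is.na(sire_of) & sire_of %in% colnames(d)
    kid_cols <- which(has_sire)
    if (!length(kid_cols)) return(g)
    sire_cols <- match(sire_of[kid_cols], colnames(d))
    for (it in seq_len(iterations)) {
        n_called <- rowSums(!is.na(d))
        p <- ifelse(n_called > 0, rowSums(d, na.rm = TRUE) / (2 * n_called),
                    NA_real_)
        filled <- FALSE
        S <- d[, sire_cols, drop = FALSE]     # sire dosages aligned to kids
        K <- d[, kid_cols, drop = FALSE]
        Pp <- S / 2                            # P(paternal allele = ref)
        P2 <- Pp * p
        P1 <- Pp * (1 - p) + (1 - Pp) * p
        P0 <- (1 - Pp) * (1 - p)
        target <- is.na(K) & !is.na(S) & !is.na(p)
        if (any(target)) {
            idx <- which(target)
            post <- cbind(P0[idx], P1[idx], P2[idx])
            best <- max.col(post, ties.method = "first")
            ok <- post[cbind(seq_along(idx), best)] >= accept_prob
            if (any(ok)) {
                K[idx[ok]] <- as.integer(best[ok] - 1L)
                d[, kid_cols] <- K
                filled <- TRUE
            }
        }
        if (!filled && it > 1L) break          # converged, later passes no-op
    }
    SnpGenotypes(d, mm)
}

#' Write a QC ledger
#'
#' @param ledger a ledger data.frame (rbind of stage ledgers).
#' @param tsv_path,json_path output paths; either may be NULL.
#' @return invisibly, the ledger.
#' @export
writeQCLedger <- function(ledger, tsv_path = NULL, json_path = NULL) {
    if (!is.null(tsv_path))
        utils::write.table(ledger, tsv_path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    if (!is.null(json_path))
        jsonlite::write_json(ledger, json_path, dataframe = "rows",
                             auto_unbox = TRUE, digits = NA)
    invisible(ledger)
}
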