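#' Pairwise linkage disequilibrium from haplotype counts
#'
#' Given the four joint haplotype counts of a SNP pair (AB, Ab, aB, ab over
#' jointly non-missing haplotypes), computes D = p_AB - p_A p_B, the
#' normalized D' = |D| / Dmax with
#' Dmax = min(p_A (1-p_B), (1-p_A) p_B) when D > 0 and
#' Dmax = min(p_A p_B, (1-p_A)(1-p_B)) when D < 0, and
#' r2 = D^2 / (p_A (1-p_A) p_B (1-p_B)).  All statistics are invariant to
#' allele relabeling at either locus and r2 <= D'^2 always holds.  Pairs
#' with a monomorphic locus (in the jointly observed sample) are flagged
#' undefined and must be excluded from summaries.
#'
#' @param n11,n10,n01,n00 integer vectors of joint haplotype counts; the
#'   first index is the allele counted at the first locus.
#' @return data.frame with columns n, pA, pB, D, Dprime, r2, defined.
#' @examples
#' pairLD(4, 1, 1, 4)   # D = 0.15, D' = 0.6, r2 = 0.36
#' @export
pairLD <- function(n11, n10, n01, n00) {
    N <- n11 + n10 + n01 + n00
    if (any(N < 2)) stop("each pair needs at least 2 jointly observed haplotypes")
    pA <- (n11 + n10) / N
    pB <- (n11 + n01) / N
    pAB <- n11 / N
    D <- pAB - pA * pB
    dmax_pos <- pmin(pA * (1 - pB), (1 - pA) * pB)
    dmax_neg <- pmin(pA * pB, (1 - pA) * (1 - pB))
    Dmax <- ifelse(D >= 0, dmax_pos, dmax_neg)
    defined <- pA > 0 & pA < 1 & pB > 0 & pB < 1
    Dprime <- ifelse(defined & D != 0, abs(D) / Dmax, ifelse(defined, 0, NA))
    denom <- pA * (1 - pA) * pB * (1 - pB)
    r2 <- ifelse(defined, D^2 / denom, NA)
    data.frame(n = N, pA = pA, pB = pB, D = ifelse(defined, D, NA),
               Dprime = Dprime, r2 = r2, defined = defined)
}

#' Likelihood-based confidence bounds on |D'|
#'
#' Profiles the multinomial likelihood of the four haplotype counts over a
#' grid of |D'| values in [0, 1], with the two allele frequencies fixed at
#' their MLEs and p_AB = p_A p_B + sign(D) |D'| Dmax.  The likelihood is
#' normalized over the grid; CL is the largest grid value with at most 5
#' percent of the mass strictly below it and CU the smallest grid value
#' with at least 95 percent of the mass at or below it.  These are the
#' one-sided bounds used by the Gabriel block rule.
#'
#' @param n11,n10,n01,n00 integer vectors of joint haplotype counts.
#' @param grid_step grid resolution on |D'| (default 0.001).
#' @param chunk internal vectorization chunk size.
#' @return data.frame with columns CL, CU (NA for undefined pairs).
#' @export
dprimeCI <- function(n11, n10, n01, n00, grid_step = 0.001, chunk = 2000L) {
    np <- length(n11)
    stopifnot(length(n10) == np, length(n01) == np, length(n00) == np)
    grid <- seq(0, 1, by = grid_step)
    CL <- rep(NA_real_, np)
    CU <- rep(NA_real_, np)
    st <- pairLD(n11, n10, n01, n00)
    ok <- which(st$defined)
    for (lo in seq(1, length(ok), by = chunk)) {
        sel <- ok[lo:min(lo + chunk - 1L, length(ok))]
        k <- length(sel)
        pA <- st$pA[sel]; pB <- st$pB[sel]; D <- st$D[sel]
        s <- ifelse(D >= 0, 1, -1)
        Dmax <- ifelse(D >= 0, pmin(pA * (1 - pB), (1 - pA) * pB),
                       pmin(pA * pB, (1 - pA) * (1 - pB)))
        ll <- matrix(-Inf, nrow = k, ncol = length(grid))
        cnt <- cbind(n11[sel], n10[sel], n01[sel], n00[sel])
        for (gi in seq_along(grid)) {
            p11 <- pA * pB + s * grid[gi] * Dmax
            p10 <- pA - p11
            p01 <- pB - p11
            p00 <- 1 - pA - pB + p11
            P <- cbind(p11, p10, p01, p00)
            P[P < 0 & P > -1e-12] <- 0       # clamp fp noise at the boundary
            term <- cnt * log(P)
            term[cnt == 0] <- 0              # 0 * log(0) := 0
            ll[, gi] <- rowSums(term)
        }
        ll <- ll - apply(ll, 1, max)
        L <- exp(ll)
        cum <- t(apply(L, 1, cumsum))
        cum <- cum / cum[, ncol(cum)]
        below <- cbind(0, cum[, -ncol(cum), drop = FALSE])  # mass strictly below g_k
        CL[sel] <- grid[apply(below <= 0.05, 1, function(z) max(which(z)))]
        CU[sel] <- grid[apply(cum >= 0.95 - 1e-12, 1, function(z) min(which(z)))]
    }
    data.frame(CL = CL, CU = CU)
}

.countJoint <- function(H1, H2 = NULL) {
    ## H: haplotypes x SNPs in {0,1,NA}; returns joint-count matrices between
    ## columns of H1 and H2 (H1 vs itself when H2 is NULL)
    M1 <- !is.na(H1); X1 <- H1; X1[!M1] <- 0L
    if (is.null(H2)) { M2 <- M1; X2 <- X1 } else {
        M2 <- !is.na(H2); X2 <- H2; X2[!M2] <- 0L
    }
    storage.mode(X1) <- "double"; storage.mode(X2) <- "double"
    storage.mode(M1) <- "double"; storage.mode(M2) <- "double"
    n11 <- crossprod(X1, X2)
    n1x <- crossprod(X1, M2)
    nx1 <- crossprod(M1, X2)
    N <- crossprod(M1, M2)
    list(n11 = n11, n10 = n1x - n11, n01 = nx1 - n11,
         n00 = N - n1x - nx1 + n11)
}

#' All syntenic (within-chromosome) pairwise LD
#'
#' Counts joint haplotypes over the non-missing intersection for every
#' within-chromosome SNP pair and returns the LD statistics, optionally
#' with Gabriel confidence bounds.  Memory scales with one chromosome's
#' SNP count squared, never with the genome-wide pair count.
#'
#' @param h a \linkS4class{HaplotypeSet}.
#' @param with_ci also compute \code{\link{dprimeCI}} bounds per pair.
#' @param max_dist_bp optional cap on pair distance (pairs farther apart
#'   are not emitted); NULL computes all pairs.
#' @param min_n minimum jointly observed haplotypes for a pair to be
#'   emitted (default 2).
#' @param grid_step passed to \code{\link{dprimeCI}}.
#' @return data.frame: snp_i, snp_j, chrom, dist_bp, n, D, Dprime, r2 and,
#'   with \code{with_ci}, CL and CU.  Undefined (monomorphic-in-pair)
#'   pairs are dropped.
#' @export
syntenicLD <- function(h, with_ci = FALSE, max_dist_bp = NULL, min_n = 2L,
                       grid_step = 0.001) {
    mm <- markers(h)
    H <- haplotypes(h)
    chroms <- unique(as.character(seqnames(mm)))
    out <- vector("list", length(chroms))
    for (ci in seq_along(chroms)) {
        idx <- which(as.character(seqnames(mm)) == chroms[ci])
        if (length(idx) < 2L) next
        cnt <- .countJoint(H[, idx, drop = FALSE])
        ut <- which(upper.tri(cnt$n11), arr.ind = TRUE)
        bp <- GenomicRanges::start(mm)[idx]
        dist_bp <- abs(bp[ut[, 2]] - bp[ut[, 1]])
        keep <- rep(TRUE, nrow(ut))
        if (!is.null(max_dist_bp)) keep <- dist_bp <= max_dist_bp
        n11 <- cnt$n11[ut][keep]; n10 <- cnt$n10[ut][keep]
        n01 <- cnt$n01[ut][keep]; n00 <- cnt$n00[ut][keep]
        Ntot <- n11 + n10 + n01 + n00
        enough <- Ntot >= min_n
        n11 <- n11[enough]; n10 <- n10[enough]
        n01 <- n01[enough]; n00 <- n00[enough]
        st <- pairLD(n11, n10, n01, n00)
        df <- data.frame(
            snp_i = names(mm)[idx[ut[keep, 1][enough]]],
            snp_j = names(mm)[idx[ut[keep, 2][enough]]],
            chrom = chroms[ci],
            dist_bp = dist_bp[keep][enough],
            n = st$n, D = st$D, Dprime = st$Dprime, r2 = st$r2,
            stringsAsFactors = FALSE)
        if (with_ci) {
            ci_df <- dprimeCI(n11, n10, n01, n00, grid_step = grid_step)
            df$CL <- ci_df$CL
            df$CU <- ci_df$CU
        }
        df <- df[!is.na(df$r2), , drop = FALSE]
        out[[ci]] <- df
    }
    res <- do.call(rbind, c(out, make.row.names = FALSE))
    if (is.null(res))
        res <- data.frame(snp_i = character(0), snp_j = character(0),
                          chrom = character(0), dist_bp = integer(0),
                          n = integer(0), D = numeric(0), Dprime = numeric(0),
                          r2 = numeric(0))
    res
}

#' Background LD between chromosomes (non-syntenic pairs)
#'
#' Samples a fraction of the SNPs on each chromosome (without replacement,
#' reproducibly from \code{seed}) and computes D' and r2 for every
#' between-chromosome pair among the sampled SNPs.  The mean non-syntenic
#' r2 estimates the association expected by chance, about 1/n for n
#' haplotypes.
#'
#' @param h a \linkS4class{HaplotypeSet} spanning at least 2 chromosomes.
#' @param fraction fraction of SNPs sampled per chromosome (default 0.05);
#'   ceiling(fraction * m_c) SNPs are taken from a chromosome with m_c SNPs.
#' @param seed integer seed for the sampling.
#' @return list with \code{pairs} (per-pair data.frame) and
#'   \code{summary} (n_pairs and mean/sd/min/max of D' and r2).
#' @export
nonsyntenicLD <- function(h, fraction = 0.05, seed = 1L) {
    mm <- markers(h)
    H <- haplotypes(h)
    chroms <- unique(as.character(seqnames(mm)))
    if (length(chroms) < 2L) stop("non-syntenic LD needs at least 2 chromosomes")
    sampled <- .withSeed(seed, lapply(chroms, function(ch) {
        idx <- which(as.character(seqnames(mm)) == ch)
        k <- ceiling(fraction * length(idx))
        sort(.sampleFrom(idx, k))
    }))
    names(sampled) <- chroms
    res <- list()
    for (a in seq_len(length(chroms) - 1L)) {
        for (b in seq((a + 1L), length(chroms))) {
            ia <- sampled[[a]]; ib <- sampled[[b]]
            cnt <- .countJoint(H[, ia, drop = FALSE], H[, ib, drop = FALSE])
            st <- pairLD(as.vector(cnt$n11), as.vector(cnt$n10),
                         as.vector(cnt$n01), as.vector(cnt$n00))
            gi <- rep(ia, times = length(ib))
            gj <- rep(ib, each = length(ia))
            df <- data.frame(snp_i = names(mm)[gi], snp_j = names(mm)[gj],
                             Dprime = st$Dprime, r2 = st$r2,
                             stringsAsFactors = FALSE)
            res[[paste(a, b)]] <- df[st$defined, , drop = FALSE]
        }
    }
    pairs <- do.call(rbind, c(res, make.row.names = FALSE))
    summary <- data.frame(
        n_pairs = nrow(pairs),
        mean_Dprime = mean(pairs$Dprime), sd_Dprime = stats::sd(pairs$Dprime),
        min_Dprime = min(pairs$Dprime), max_Dprime = max(pairs$Dprime),
        mean_r2 = mean(pairs$r2), sd_r2 = stats::sd(pairs$r2),
        min_r2 = min(pairs$r2), max_r2 = max(pairs$r2))
    list(pairs = pairs, summary = summary)
}

.decayEdges <- c(0, 10e3, 20e3, 40e3, 60e3, 100e3, 200e3, 500e3,
                 1e6, 2e6, 5e6, 10e6, 20e6, 50e6, Inf)
.decayLabels <- c("<10 kb", "10-20 kb", "20-40 kb", "40-60 kb", "60-100 kb",
                  "100-200 kb", "200-500 kb", "500 kb-1 Mb", "1-2 Mb",
                  "2-5 Mb", "5-10 Mb", "10-20 Mb", "20-50 Mb", ">50 Mb")

#' LD decay over map-distance bins
#'
#' Bins syntenic pairs by physical distance into the standard half-open
#' intervals [lower, upper): <10 kb, 10-20, 20-40, 40-60, 60-100, 100-200,
#' 200-500 kb, 0.5-1, 1-2, 2-5, 5-10, 10-20, 20-50 and >50 Mb, and reports
#' per bin the pair count and mean/SD/min/max of D' and r2.  Bin counts
#' always sum to the number of input pairs.
#'
#' @param pairs data.frame with columns dist_bp, Dprime, r2 (syntenic
#'   pairs only, e.g. from \code{\link{syntenicLD}}).
#' @return data.frame, one row per distance bin.
#' @export
ldDecayTable <- function(pairs) {
    bin <- cut(pairs$dist_bp, breaks = .decayEdges, labels = .decayLabels,
               right = FALSE, include.lowest = TRUE)
    stat <- function(v, f) {
        s <- tapply(v, bin, f)
        as.numeric(s)[match(.decayLabels, names(s))]
    }
    data.frame(
        bin = .decayLabels,
        n_pairs = as.integer(ifelse(is.na(stat(pairs$r2, length)), 0,
                                    stat(pairs$r2, length))),
        mean_Dprime = stat(pairs$Dprime, mean),
        sd_Dprime = stat(pairs$Dprime, stats::sd),
        min_Dprime = stat(pairs$Dprime, min),
        max_Dprime = stat(pairs$Dprime, max),
        mean_r2 = stat(pairs$r2, mean),
        sd_r2 = stat(pairs$r2, stats::sd),
        min_r2 = stat(pairs$r2, min),
        max_r2 = stat(pairs$r2, max),
        stringsAsFactors = FALSE)
}

#' Mean r2 in 1-Mb distance bins
#'
#' Helper for the half-length computation: bins pairs into consecutive
#' 1-Mb distance intervals ([0,1), [1,2), ... Mb) and returns the mean r2
#' per bin at the bin midpoint.
#'
#' @param pairs data.frame with dist_bp and r2.
#' @param bin_mb bin width in Mb (default 1).
#' @return data.frame with mid_Mb, mean_r2, n_pairs.
#' @export
r2ByMbBin <- function(pairs, bin_mb = 1) {
    b <- floor(pairs$dist_bp / (bin_mb * 1e6))
    agg <- stats::aggregate(pairs$r2, by = list(bin = b), FUN = mean)
    cnt <- as.vector(table(b)[as.character(agg$bin)])
    data.frame(mid_Mb = (agg$bin + 0.5) * bin_mb, mean_r2 = agg$x,
               n_pairs = as.integer(cnt))
}

#' Half-length of r2
#'
#' The distance at which average LD decays to half of its maximum: given
#' mean r2 per 1-Mb bin with the maximum in the first bin, returns
#' half_value = max/2 and the distance of the first crossing, linearly
#' interpolated between the midpoints of the two adjacent bins whose means
#' straddle the half value.
#'
#' @param mean_r2 numeric vector of per-bin mean r2, first bin = maximum.
#' @param mid_Mb numeric vector of bin midpoints in Mb (default 0.5, 1.5,
#'   ...).
#' @return list with half_value and distance_Mb.
#' @examples
#' halfLengthR2(c(0.4, 0.3, 0.2, 0.1))   # crosses 0.2 at 2.5 Mb
#' @export
halfLengthR2 <- function(mean_r2, mid_Mb = seq_along(mean_r2) - 0.5) {
    stopifnot(length(mean_r2) >= 2, length(mid_Mb) == length(mean_r2))
    if (which.max(mean_r2) != 1L)
        stop("maximum mean r2 must be attained in the first bin")
    half <- mean_r2[1] / 2
    j <- which(mean_r2 <= half)[1]
    if (is.na(j)) stop("no decay: mean r2 never falls to half its maximum")
    d <- mid_Mb[j - 1] +
        (half - mean_r2[j - 1]) / (mean_r2[j] - mean_r2[j - 1]) *
        (mid_Mb[j] - mid_Mb[j - 1])
    list(half_value = half, distance_Mb = d)
}
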