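#' Convert physical distance to genetic distance
#'
#' Applies the conversion policy of a \linkS4class{GeneticMap}:
#' \code{uniform1} uses 1 cM/Mb everywhere, \code{genome_avg} a single
#' genome-wide cM/Mb rate, \code{per_chrom} a per-chromosome rate.  With
#' rate R cM/Mb, c = dist_bp x R / 1e8 Morgans.
#'
#' @param dist_bp nonnegative integer vector of physical distances.
#' @param chrom chromosome label vector (used in \code{per_chrom} mode).
#' @param map a \linkS4class{GeneticMap}.
#' @return genetic distances in Morgans.
#' @examples
#' bpToMorgans(1e6, 1, geneticMap("uniform1"))                     # 0.01
#' bpToMorgans(1e6, 1, geneticMap("genome_avg", genomeRate = 1.85)) # 0.0185
#' @export
bpToMorgans <- function(dist_bp, chrom, map) {
    stopifnot(all(dist_bp >= 0))
    rate <- switch(map@mode,
        uniform1 = rep(1, length(dist_bp)),
        genome_avg = rep(map@genomeRate, length(dist_bp)),
        per_chrom = {
            r <- map@chromRates[as.character(chrom)]
            if (any(is.na(r)))
                stop("no cM/Mb rate for chromosome ",
                     as.character(chrom)[is.na(r)][1])
            unname(r)
        })
    dist_bp * rate / 1e8
}

#' Expected r2 under the Sved drift-recombination relationship
#'
#' E[r2] = 1 / (1 + 4 Ne c) + 1/n for effective size Ne, genetic distance
#' c in Morgans and a sample of n haplotypes.
#'
#' @param Ne effective population size.
#' @param c genetic distance in Morgans.
#' @param n chromosome sample size (number of haplotypes).
#' @return expected r2.
#' @export
svedExpectedR2 <- function(Ne, c, n) {
    1 / (1 + 4 * Ne * c) + 1 / n
}

#' Point estimate of historical effective population size
#'
#' Inverts the Sved relationship: Ne = (1 / (r2 - 1/n) - 1) / (4 c).
#' The estimate is undefined (NA) when r2 <= 1/n, where observed LD does
#' not exceed the sampling floor.
#'
#' @param r2_mean mean r2 of a distance bin.
#' @param c_mean mean genetic distance of the bin, Morgans; must be > 0.
#' @param n chromosome sample size (>= 2).
#' @return Ne, or NA when undefined.
#' @export
nePoint <- function(r2_mean, c_mean, n) {
    stopifnot(all(c_mean > 0), n >= 2)
    ifelse(r2_mean > 1 / n,
           (1 / (r2_mean - 1 / n) - 1) / (4 * c_mean),
           NA_real_)
}

#' Attach genetic distances to an LD pair table
#'
#' @param pairs data.frame with dist_bp and chrom (e.g. from
#'   \code{\link{syntenicLD}}).
#' @param map a \linkS4class{GeneticMap}.
#' @return \code{pairs} with an added column \code{c} (Morgans).
#' @export
addGeneticDistance <- function(pairs, map) {
    pairs$c <- bpToMorgans(pairs$dist_bp, pairs$chrom, map)
    pairs
}

#' Historical effective population size trajectory from binned LD
#'
#' Sorts syntenic pairs by genetic distance, stacks them into consecutive
#' bins of \code{bin_size} pairs (the final partial bin is dropped), and
#' per bin computes the mean distance c, mean r2, the generations-ago
#' mapping T = 1 / (2 c) and the Sved-inverted Ne.  For each requested
#' time point the bin with the nearest T is reported (ties resolved toward
#' the smaller mean distance).
#'
#' @param pairs data.frame with columns r2 and c (Morgans); see
#'   \code{\link{addGeneticDistance}}.
#' @param n chromosome sample size (number of haplotypes).
#' @param bin_size pairs per bin (default 1000).
#' @param time_points requested generations-ago values, descending or not;
#'   default \{1, 5, 10, 15, 25, 50, 75, 100, 150, 200, 250\}.
#' @return list with \code{bins} (one row per bin: c_mean, r2_mean, T, Ne)
#'   and \code{estimates} (one row per requested time point).
#' @export
neTrajectory <- function(pairs, n, bin_size = 1000L,
                         time_points = c(1, 5, 10, 15, 25, 50, 75, 100,
                                         150, 200, 250)) {
    stopifnot(all(time_points > 0), n >= 2)
    pairs <- pairs[!is.na(pairs$r2) & !is.na(pairs$c) & pairs$c > 0, ,
                   drop = FALSE]
    np <- nrow(pairs)
    if (np < bin_size)
        stop("need at least ", bin_size, " pairs, got ", np)
    ord <- order(pairs$c)
    nb <- np %/% bin_size
    use <- ord[seq_len(nb * bin_size)]
    bin_id <- rep(seq_len(nb), each = bin_size)
    c_mean <- as.vector(tapply(pairs$c[use], bin_id, mean))
    r2_mean <- as.vector(tapply(pairs$r2[use], bin_id, mean))
    Tgen <- 1 / (2 * c_mean)
    Ne <- nePoint(r2_mean, c_mean, n)
    bins <- data.frame(bin = seq_len(nb), c_mean = c_mean,
                       r2_mean = r2_mean, T = Tgen, Ne = Ne,
                       n_pairs = bin_size)
    est <- lapply(time_points, function(tp) {
        d <- abs(bins$T - tp)
        cand <- which(d == min(d))
        pick <- cand[which.min(bins$c_mean[cand])]
        cbind(T_requested = tp, bins[pick, , drop = FALSE])
    })
    estimates <- do.call(rbind, c(est, make.row.names = FALSE))
    list(bins = bins, estimates = estimates)
}
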