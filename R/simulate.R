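#' Simulation configuration
#'
#' Assembles and validates the configuration of the Wright-Fisher
#' simulator.  Defaults describe the desk-scale emulation of a dairy-sheep
#' SNP-array study: a few hundred diploids with a declining effective-size
#' trajectory, 4 chromosomes of 100 cM carrying array-ascertained SNPs
#' (MAF >= 0.05), and a half-sib daughter design (few sires, many
#' daughters out of distinct dams, dams not genotyped).
#'
#' @param ne_trajectory data.frame(generation, N): piecewise-constant
#'   diploid population size over the post-burn-in epoch; generations
#'   strictly increasing, the last entry sets the epoch length.
#' @param n_chromosomes,snps_per_chromosome,chromosome_length_cM genome
#'   shape; the physical map is 1 cM ~ 1 Mb, so a 100-cM chromosome spans
#'   100 Mb.
#' @param n_sires,daughters_per_sire half-sib sampling design.
#' @param missing_rate,genotype_error_rate degradation rates in [0, 1).
#' @param ascertainment_maf SNPs below this sampled MAF are dropped when
#'   the array sample is drawn (default 0.05).
#' @param burnin_factor burn-in length as a multiple of the largest
#'   trajectory N (default 4), run at the first trajectory size so LD
#'   equilibrates before the epoch of interest.
#' @param seed integer seed; every simulator draw is derived from it.
#' @return a validated configuration list of class \code{"SimConfig"}.
#' @export
simConfig <- function(ne_trajectory = data.frame(
                          generation = c(1L, 41L, 81L),
                          N = c(120L, 100L, 80L)),
                      n_chromosomes = 4L, snps_per_chromosome = 500L,
                      chromosome_length_cM = 100,
                      n_sires = 4L, daughters_per_sire = 15L,
                      missing_rate = 0.02, genotype_error_rate = 0.002,
                      ascertainment_maf = 0.05, burnin_factor = 4L,
                      seed = 1L) {
    stopifnot(is.data.frame(ne_trajectory),
              all(c("generation", "N") %in% names(ne_trajectory)),
              nrow(ne_trajectory) >= 1,
              all(diff(ne_trajectory$generation) > 0),
              all(ne_trajectory$N >= 2),
              n_chromosomes >= 1, snps_per_chromosome >= 2,
              chromosome_length_cM > 0,
              n_sires >= 1, daughters_per_sire >= 1,
              missing_rate >= 0, missing_rate < 1,
              genotype_error_rate >= 0, genotype_error_rate < 1,
              ascertainment_maf >= 0, ascertainment_maf < 0.5)
    cfg <- list(ne_trajectory = ne_trajectory,
                n_chromosomes = as.integer(n_chromosomes),
                snps_per_chromosome = as.integer(snps_per_chromosome),
                chromosome_length_cM = chromosome_length_cM,
                n_sires = as.integer(n_sires),
                daughters_per_sire = as.integer(daughters_per_sire),
                missing_rate = missing_rate,
                genotype_error_rate = genotype_error_rate,
                ascertainment_maf = ascertainment_maf,
                burnin_factor = as.integer(burnin_factor),
                seed = as.integer(seed))
    class(cfg) <- "SimConfig"
    cfg
}

## one meiosis on one chromosome: recombine the parent's two haplotypes
## with Poisson(length_cM / 100) crossovers uniformly placed on the map
.gamete <- function(h1, h2, cM, len_cM) {
    k <- stats::rpois(1L, len_cM / 100)
    start <- sample.int(2L, 1L) - 1L
    if (k == 0L) return(if (start == 0L) h1 else h2)
    breaks <- sort.int(stats::runif(k, 0, len_cM))
    pattern <- (start + findInterval(cM, breaks)) %% 2L
    out <- h1
    sel <- pattern == 1L
    out[sel] <- h2[sel]
    out
}

#' Forward Wright-Fisher simulation with recombination
#'
#' Simulates discrete, non-overlapping generations of diploids.  Founders
#' are initialized in linkage equilibrium with per-SNP allele frequencies
#' drawn uniformly on [0.1, 0.9]; there is no mutation afterwards, so all
#' polymorphism descends from the founder frequencies and drift (matching
#' pre-ascertained array sites).  Each offspring draws two parents
#' uniformly with replacement; each transmitted haplotype carries a
#' Poisson number of crossovers placed uniformly on the genetic map.  A
#' burn-in of \code{burnin_factor} x max(N) generations at the first
#' trajectory size precedes the trajectory epoch.  Fully deterministic
#' given \code{cfg$seed}.
#'
#' @param cfg a configuration from \code{\link{simConfig}}.
#' @return a \linkS4class{SimTruth} holding the final-generation haplotype
#'   pool per chromosome, the marker map (with true cM positions), the
#'   realized per-generation N and the configuration.
#' @export
simulatePopulation <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    .withSeed(cfg$seed, {
        m <- cfg$snps_per_chromosome
        len <- cfg$chromosome_length_cM
        len_bp <- round(len * 1e6)
        chrom <- rep(seq_len(cfg$n_chromosomes), each = m)
        bp <- unlist(lapply(seq_len(cfg$n_chromosomes), function(ch)
            sort(.sampleFrom(seq_len(len_bp), m))))
        cM <- bp / 1e6
        ids <- sprintf("snp%d_%d", chrom, unlist(lapply(
            seq_len(cfg$n_chromosomes), function(ch) seq_len(m))))
        mm <- markerMap(chrom, bp, ids, cM = cM)

        traj <- cfg$ne_trajectory
        epoch_len <- max(traj$generation)
        Nt <- traj$N[findInterval(seq_len(epoch_len), traj$generation)]
        burn <- cfg$burnin_factor * max(traj$N)
        Ns <- c(rep(traj$N[1], burn), Nt)

        cM_by <- split(cM, chrom)
        N0 <- Ns[1]
        pool <- lapply(seq_len(cfg$n_chromosomes), function(ch) {
            q <- stats::runif(m, 0.1, 0.9)
            matrix(stats::rbinom(2L * N0 * m, 1L, rep(q, each = 2L * N0)),
                   nrow = 2L * N0, ncol = m)
        })
        Nprev <- N0
        for (g in seq_along(Ns)[-1]) {
            N <- Ns[g]
            pa <- sample.int(Nprev, N, replace = TRUE)
            pb <- sample.int(Nprev, N, replace = TRUE)
            for (ch in seq_len(cfg$n_chromosomes)) {
                old <- pool[[ch]]
                new <- matrix(0L, nrow = 2L * N, ncol = m)
                cMc <- cM_by[[ch]]
                for (k in seq_len(N)) {
                    new[2L * k - 1L, ] <- .gamete(old[2L * pa[k] - 1L, ],
                                                  old[2L * pa[k], ], cMc, len)
                    new[2L * k, ] <- .gamete(old[2L * pb[k] - 1L, ],
                                             old[2L * pb[k], ], cMc, len)
                }
                pool[[ch]] <- new
            }
            Nprev <- N
        }
        for (ch in seq_along(pool)) storage.mode(pool[[ch]]) <- "integer"
        ne_df <- data.frame(generation = seq_along(Ns), N = Ns,
                            epoch = c(rep("burnin", burn),
                                      rep("trajectory", epoch_len)))
        new("SimTruth", haplotypes = pool, markers = mm,
            neByGeneration = ne_df, config = unclass(cfg))
    })
}

#' True-phase haplotype set from a simulation
#'
#' Assembles the final-generation haplotype pool (optionally a random
#' subset of haplotypes, so the 1/n sampling term of the Sved
#' relationship applies to a genuine sample) into a
#' \linkS4class{HaplotypeSet}.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param n_haplotypes optional number of haplotype rows to sample
#'   without replacement; NULL keeps the whole pool.
#' @param min_maf drop SNPs whose minor-allele frequency among the
#'   returned haplotypes falls below this (array-style ascertainment);
#'   default 0 keeps every segregating and fixed site.
#' @param seed seed for the subsampling.
#' @return a \linkS4class{HaplotypeSet}.
#' @export
truthHaplotypeSet <- function(truth, n_haplotypes = NULL, min_maf = 0,
                              seed = 1L) {
    H <- do.call(cbind, haplotypes(truth))
    carriers <- rep(sprintf("I%d", seq_len(nrow(H) / 2)), each = 2)
    origin <- rep(c("P", "M"), nrow(H) / 2)
    if (!is.null(n_haplotypes)) {
        stopifnot(n_haplotypes <= nrow(H))
        rows <- .withSeed(seed, sort(.sampleFrom(seq_len(nrow(H)),
                                                 n_haplotypes)))
        H <- H[rows, , drop = FALSE]
        carriers <- carriers[rows]
        origin <- origin[rows]
    }
    mm <- markers(truth)
    if (min_maf > 0) {
        p <- colMeans(H)
        keep <- pmin(p, 1 - p) >= min_maf
        H <- H[, keep, drop = FALSE]
        mm <- mm[keep]
    }
    HaplotypeSet(H, carriers, origin, mm)
}

#' Draw a gamete sample (study cohort chromosomes) from a simulation
#'
#' Emulates genotyping a fresh cohort: each of the n sampled chromosomes
#' is a recombinant gamete from a parent drawn uniformly with replacement
#' from the final generation.  This is exactly the chromosome-sampling
#' model that the 1/n term of the Sved relationship corrects for, which
#' makes it the right substrate for validating effective-size inference
#' (subsampling existing pool rows without replacement would understate
#' the sampling variance).
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param n_gametes number of chromosomes to draw.
#' @param min_maf drop SNPs below this sampled minor-allele frequency
#'   (array-style ascertainment); default 0.
#' @param seed integer seed.
#' @return a \linkS4class{HaplotypeSet} with one row per sampled gamete.
#' @export
sampleGametes <- function(truth, n_gametes, min_maf = 0, seed = 1L) {
    pool <- haplotypes(truth)
    mm <- markers(truth)
    cfg <- truth@config
    N <- nrow(pool[[1]]) / 2
    len <- cfg$chromosome_length_cM
    .withSeed(seed, {
        cM_by <- split(mm$cM, as.character(seqnames(mm)))
        cM_by <- cM_by[unique(as.character(seqnames(mm)))]
        par <- sample.int(N, n_gametes, replace = TRUE)
        H <- do.call(rbind, lapply(seq_len(n_gametes), function(g)
            unlist(lapply(seq_along(pool), function(ch)
                .gamete(pool[[ch]][2 * par[g] - 1, ],
                        pool[[ch]][2 * par[g], ], cM_by[[ch]], len)))))
        storage.mode(H) <- "integer"
        if (min_maf > 0) {
            p <- colMeans(H)
            keep <- pmin(p, 1 - p) >= min_maf
            H <- H[, keep, drop = FALSE]
            mm <- mm[keep]
        }
        HaplotypeSet(H, sprintf("G%d", seq_len(n_gametes)),
                     rep("U", n_gametes), mm)
    })
}

#' Draw a half-sib daughter design from a simulated population
#'
#' Selects \code{n_sires} sires from the final generation; each sire is
#' mated to \code{daughters_per_sire} distinct dams (distinct across the
#' whole design, drawn from the remaining final-generation individuals),
#' each mating producing one daughter by simulated meiosis.  Sires and
#' daughters are genotyped, dams are not (they appear in the pedigree
#' only).  SNPs whose minor-allele frequency in the genotyped sample
#' falls below \code{cfg$ascertainment_maf} are dropped, emulating array
#' ascertainment.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param cfg the \code{\link{simConfig}} used (supplies design sizes and
#'   the ascertainment threshold).
#' @param birth_years integer vector recycled over daughters in index
#'   order (default 2001:2008), so the pedigree carries a year structure.
#' @return list with \code{genotypes} (\linkS4class{SnpGenotypes}:
#'   sires then daughters), \code{pedigree} (\linkS4class{Pedigree}
#'   including ungenotyped dams), \code{haplotypes} (true phase of sires
#'   and daughters, \linkS4class{HaplotypeSet}), \code{sires} (ids) and
#'   \code{kept} (logical vector over the original SNPs).
#' @export
sampleHalfSib <- function(truth, cfg, birth_years = 2001:2008) {
    stopifnot(inherits(cfg, "SimConfig"))
    pool <- haplotypes(truth)
    mm <- markers(truth)
    N <- nrow(pool[[1]]) / 2
    n_d <- cfg$n_sires * cfg$daughters_per_sire
    if (N < cfg$n_sires + n_d)
        stop("population too small: need ", cfg$n_sires + n_d,
             " individuals, final generation has ", N)
    .withSeed(cfg$seed + 1L, {
        len <- cfg$chromosome_length_cM
        cM_by <- split(mm$cM, as.character(seqnames(mm)))
        cM_by <- cM_by[unique(as.character(seqnames(mm)))]
        perm <- .sampleFrom(seq_len(N), cfg$n_sires + n_d)
        sire_idx <- perm[seq_len(cfg$n_sires)]
        dam_idx <- perm[-seq_len(cfg$n_sires)]
        sire_ids <- sprintf("S%d", seq_len(cfg$n_sires))
        dam_ids <- sprintf("D%d", seq_len(n_d))
        ewe_ids <- sprintf("E%d", seq_len(n_d))
        H <- pool                           # per-chromosome pools
        hap_rows <- list(); hap_car <- character(0); hap_org <- character(0)
        ## sires' own two haplotypes (parental origin unknown)
        for (s in seq_len(cfg$n_sires)) {
            h1 <- do.call(c, lapply(H, function(x) x[2 * sire_idx[s] - 1, ]))
            h2 <- do.call(c, lapply(H, function(x) x[2 * sire_idx[s], ]))
            hap_rows <- c(hap_rows, list(h1, h2))
            hap_car <- c(hap_car, sire_ids[s], sire_ids[s])
            hap_org <- c(hap_org, "U", "U")
        }
        for (k in seq_len(n_d)) {
            s <- (k - 1L) %/% cfg$daughters_per_sire + 1L
            pat <- unlist(lapply(seq_along(H), function(ch)
                .gamete(H[[ch]][2 * sire_idx[s] - 1, ],
                        H[[ch]][2 * sire_idx[s], ], cM_by[[ch]], len)))
            mat <- unlist(lapply(seq_along(H), function(ch)
                .gamete(H[[ch]][2 * dam_idx[k] - 1, ],
                        H[[ch]][2 * dam_idx[k], ], cM_by[[ch]], len)))
            hap_rows <- c(hap_rows, list(pat, mat))
            hap_car <- c(hap_car, ewe_ids[k], ewe_ids[k])
            hap_org <- c(hap_org, "P", "M")
        }
        Hmat <- do.call(rbind, hap_rows)
        storage.mode(Hmat) <- "integer"
        ## genotypes of sires and daughters: dosage of allele 1
        geno_ids <- c(sire_ids, ewe_ids)
        dos <- vapply(seq_along(geno_ids), function(i) {
            rows <- which(hap_car == geno_ids[i])
            Hmat[rows[1], ] + Hmat[rows[2], ]
        }, integer(ncol(Hmat)))             # SNPs x individuals
        colnames(dos) <- geno_ids
        ## array ascertainment on the genotyped sample
        p <- rowMeans(dos) / 2
        maf <- pmin(p, 1 - p)
        kept <- maf >= cfg$ascertainment_maf
        mm_kept <- mm[kept]
        g <- SnpGenotypes(dos[kept, , drop = FALSE], mm_kept)
        hset <- HaplotypeSet(Hmat[, kept, drop = FALSE], hap_car, hap_org,
                             mm_kept)
        yrs <- rep(birth_years, length.out = n_d)
        ped <- Pedigree(
            id = c(sire_ids, dam_ids, ewe_ids),
            sire = c(rep(NA, cfg$n_sires + n_d),
                     sire_ids[(seq_len(n_d) - 1L) %/%
                              cfg$daughters_per_sire + 1L]),
            dam = c(rep(NA, cfg$n_sires + n_d), dam_ids),
            birth_year = c(rep(2000L, cfg$n_sires + n_d), yrs))
        list(genotypes = g, pedigree = ped, haplotypes = hset,
             sires = sire_ids, kept = kept)
    })
}

#' Degrade genotypes with missingness and error
#'
#' Sets each entry missing independently with \code{missing_rate}; each
#' surviving entry is replaced with probability \code{error_rate} by a
#' dosage drawn uniformly from the two other values.  Deterministic given
#' \code{seed}.
#'
#' @param g a \linkS4class{SnpGenotypes}.
#' @param missing_rate,error_rate rates in [0, 1).
#' @param seed integer seed.
#' @return a degraded \linkS4class{SnpGenotypes}.
#' @export
degradeGenotypes <- function(g, missing_rate, error_rate, seed = 1L) {
    stopifnot(missing_rate >= 0, missing_rate < 1,
              error_rate >= 0, error_rate < 1)
    d <- dosage(g)
    .withSeed(seed, {
        n <- length(d)
        miss <- stats::runif(n) < missing_rate
        d[miss] <- NA_integer_
        if (error_rate > 0) {
            err <- which(!is.na(d) & stats::runif(n) < error_rate)
            if (length(err)) {
                shift <- sample.int(2L, length(err), replace = TRUE)
                d[err] <- (d[err] + shift) %% 3L
            }
        }
        SnpGenotypes(d, markers(g))
    })
}
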