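#' Rule-based haplotype deduction from sire genotypes
#'
#' Deduces, for every genotyped non-sire individual ("daughter"), the
#' paternally and maternally inherited alleles using only forced Mendelian
#' logic: a homozygous daughter carries that allele on both chromosomes; a
#' heterozygous daughter with a homozygous sire received the sire allele
#' paternally and the other allele maternally; every other configuration
#' (heterozygous daughter with heterozygous or missing sire, missing
#' daughter genotype) is left unresolved.  Sires contribute their own two
#' haplotypes only at sites where they are homozygous; within-sire linkage
#' completion is deliberately not attempted, so every non-missing deduced
#' allele is exactly the transmitted allele.
#'
#' @param g a \linkS4class{SnpGenotypes}, Mendelian-cleaned.
#' @param ped a \linkS4class{Pedigree} naming each daughter's sire; a
#'   daughter without a recorded (or genotyped) sire is phased from her
#'   homozygous sites only.
#' @return a \linkS4class{HaplotypeSet}: two \code{"U"} rows per genotyped
#'   sire, then one \code{"P"} and one \code{"M"} row per daughter.
#' @export
deduceHaplotypes <- function(g, ped) {
    d <- dosage(g)
    mm <- markers(g)
    r <- pedigreeTable(ped)
    ids <- colnames(d)
    sires <- unique(r$sire[!is.na(r$sire)])
    sires <- sires[sires %in% ids]
    daughters <- setdiff(ids, sires)
    m <- nrow(d)
    rows <- list(); car <- character(0); org <- character(0)
    for (s in sires) {
        gs <- d[, s]
        hom <- !is.na(gs) & gs != 1L
        h <- rep(NA_integer_, m)
        h[hom] <- as.integer(gs[hom] / 2L)   # 0 or 1
        rows <- c(rows, list(h, h))
        car <- c(car, s, s)
        org <- c(org, "U", "U")
    }
    sire_of <- r$sire[match(daughters, r$id)]
    for (k in seq_along(daughters)) {
        gd <- d[, daughters[k]]
        pat <- rep(NA_integer_, m)
        mat <- rep(NA_integer_, m)
        hom <- !is.na(gd) & gd != 1L
        pat[hom] <- as.integer(gd[hom] / 2L)
        mat[hom] <- as.integer(gd[hom] / 2L)
        s <- sire_of[k]
        if (!is.na(s) && s %in% ids) {
            gs <- d[, s]
            forced <- !is.na(gd) & gd == 1L & !is.na(gs) & gs != 1L
            pat[forced] <- as.integer(gs[forced] / 2L)
            mat[forced] <- 1L - pat[forced]
        }
        rows <- c(rows, list(pat, mat))
        car <- c(car, daughters[k], daughters[k])
        org <- c(org, "P", "M")
    }
    H <- do.call(rbind, rows)
    storage.mode(H) <- "integer"
    HaplotypeSet(H, car, org, mm)
}

#' Select non-redundant haplotypes for LD estimation
#'
#' In a half-sib design the sires' chromosomes are over-represented among
#' the daughters' paternal haplotypes.  This selection keeps each sire's
#' own two haplotypes plus every daughter's maternally inherited haplotype
#' and drops the daughters' paternal copies, yielding (approximately)
#' independent chromosomes; the haplotype count n is recomputed.
#'
#' @param h a \linkS4class{HaplotypeSet} with origin tags.
#' @param ped a \linkS4class{Pedigree}; its recorded sires define the sire
#'   set.
#' @return the filtered \linkS4class{HaplotypeSet}.
#' @export
selectIndependentHaplotypes <- function(h, ped) {
    r <- pedigreeTable(ped)
    sires <- unique(r$sire[!is.na(r$sire)])
    keep <- carriers(h) %in% sires | (!(carriers(h) %in% sires) &
                                      origins(h) == "M")
    HaplotypeSet(haplotypes(h)[keep, , drop = FALSE],
                 carriers(h)[keep], origins(h)[keep], markers(h))
}
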