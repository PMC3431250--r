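#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
NULL

#' Build a validated marker map
#'
#' A marker map is a \linkS4class{GRanges} with one width-1 range per SNP:
#' autosome label as seqnames, 1-based physical position, optional genetic
#' position in centimorgans in the \code{cM} metadata column.  Within a
#' chromosome markers must be strictly sorted by position with unique
#' positions; identifiers must be unique genome-wide.
#'
#' @param chrom integer vector of autosome labels (positive integers).
#' @param pos_bp integer vector of 1-based physical positions.
#' @param id character vector of unique SNP identifiers.
#' @param cM optional numeric vector of genetic positions (centimorgans).
#' @return a \code{GRanges} marker map.
#' @examples
#' mm <- markerMap(c(1, 1, 2), c(100L, 200L, 50L), c("s1", "s2", "s3"))
#' @export
markerMap <- function(chrom, pos_bp, id, cM = NULL) {
    pos_bp <- as.integer(pos_bp)
    id <- as.character(id)
    if (length(chrom) == 1L) chrom <- rep(chrom, length(pos_bp))
    chrom <- as.integer(chrom)
    stopifnot(length(chrom) == length(pos_bp), length(id) == length(pos_bp))
    if (any(is.na(chrom)) || any(chrom < 1L))
        stop("chromosome labels must be positive integers (autosomes)")
    if (any(is.na(pos_bp)) || any(pos_bp < 1L))
        stop("physical positions must be positive 1-based integers")
    if (anyDuplicated(id))
        stop("duplicate SNP identifiers: ",
             paste(unique(id[duplicated(id)])[1:3], collapse = ", "))
    gr <- GRanges(seqnames = as.character(chrom),
                  ranges = IRanges(start = pos_bp, width = 1L))
    names(gr) <- id
    if (!is.null(cM)) {
        stopifnot(length(cM) == length(gr))
        if (any(cM < 0, na.rm = TRUE)) stop("cM positions must be nonnegative")
        mcols(gr)$cM <- as.numeric(cM)
    }
    ord <- order(chrom, pos_bp)
    gr <- gr[ord]
    bych <- split(GenomicRanges::start(gr), as.character(seqnames(gr)))
    for (ch in names(bych)) {
        p <- bych[[ch]]
        if (anyDuplicated(p))
            stop("duplicate positions on chromosome ", ch)
    }
    gr
}

.validMarkerMap <- function(gr) {
    ch <- as.integer(as.character(seqnames(gr)))
    if (any(is.na(ch)) || any(ch < 1L))
        return("marker map seqnames must be positive autosome labels")
    ord <- order(ch, GenomicRanges::start(gr))
    if (!identical(ord, seq_along(gr)))
        return("markers must be sorted by chromosome then position")
    if (is.null(names(gr)) || anyDuplicated(names(gr)))
        return("markers must carry unique identifiers as names")
    bych <- split(GenomicRanges::start(gr), ch)
    if (any(vapply(bych, anyDuplicated, 0L) > 0L))
        return("duplicate positions within a chromosome")
    TRUE
}

#' SnpGenotypes: allele-dosage matrix with a marker map
#'
#' Container for diploid SNP genotypes: a
#' \linkS4class{RangedSummarizedExperiment} whose single \code{"dosage"}
#' assay holds, per SNP (row) and individual (column), the count of the
#' reference allele (0, 1, 2) with \code{NA} for missing.  Row ranges are
#' the marker map (see \code{\link{markerMap}}).
#'
#' @aliases SnpGenotypes-class
#' @export
setClass("SnpGenotypes",
         contains = "RangedSummarizedExperiment")

setValidity("SnpGenotypes", function(object) {
    a <- SummarizedExperiment::assayNames(object)
    if (!identical(a, "dosage"))
        return("assays must be exactly 'dosage'")
    d <- SummarizedExperiment::assay(object, "dosage")
    if (!is.integer(d))
        return("dosage must be an integer matrix")
    bad <- d[!is.na(d)]
    if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
        return("dosages must be 0, 1, 2 or NA")
    if (is.null(colnames(d)) || anyDuplicated(colnames(d)))
        return("individuals must carry unique identifiers as colnames")
    v <- .validMarkerMap(SummarizedExperiment::rowRanges(object))
    if (!isTRUE(v)) return(v)
    TRUE
})

#' Construct a SnpGenotypes object
#'
#' @param dosage integer matrix, SNPs in rows and individuals in columns,
#'   entries in \{0, 1, 2, NA\}.
#' @param markers marker map \code{GRanges} from \code{\link{markerMap}},
#'   one range per row of \code{dosage}.
#' @return a \linkS4class{SnpGenotypes}.
#' @examples
#' mm <- markerMap(1, c(100, 200), c("s1", "s2"))
#' g <- SnpGenotypes(matrix(c(0L, 1L, 2L, NA), 2,
#'                   dimnames = list(NULL, c("i1", "i2"))), mm)
#' @export
SnpGenotypes <- function(dosage, markers) {
    storage.mode(dosage) <- "integer"
    if (nrow(dosage) != length(markers))
        stop("dosage rows (", nrow(dosage), ") do not match marker count (",
             length(markers), ")")
    rownames(dosage) <- names(markers)
    se <- SummarizedExperiment(assays = list(dosage = dosage),
                               rowRanges = markers)
    new("SnpGenotypes", se)
}

#' HaplotypeSet: phased chromosome copies
#'
#' One row per haplotype (chromosome copy) over the same marker map as the
#' genotypes; entries 0/1 count the reference allele, \code{NA} marks
#' unresolved sites.  Each haplotype is tagged with its carrier individual
#' and parental origin (\code{"P"} paternal, \code{"M"} maternal, \code{"U"}
#' unknown).  The row count \code{n} is the chromosome sample size used by
#' the Sved relationship for effective-size inference.
#'
#' @aliases HaplotypeSet-class
#' @export
setClass("HaplotypeSet",
         representation(haplotypes = "matrix",
                        carrier = "character",
                        origin = "character",
                        markers = "GRanges"))

setValidity("HaplotypeSet", function(object) {
    h <- object@haplotypes
    if (!is.integer(h)) return("haplotypes must be an integer matrix")
    bad <- h[!is.na(h)]
    if (length(bad) && (any(bad < 0L) || any(bad > 1L)))
        return("haplotype alleles must be 0, 1 or NA")
    if (nrow(h) != length(object@carrier) || nrow(h) != length(object@origin))
        return("carrier/origin length must equal haplotype row count")
    if (!all(object@origin %in% c("P", "M", "U")))
        return("origin must be 'P', 'M' or 'U'")
    if (ncol(h) != length(object@markers))
        return("haplotype columns must match marker count")
    if (any(table(object@carrier) > 2L))
        return("an individual may contribute at most 2 haplotypes")
    po <- object@origin %in% c("P", "M")
    if (anyDuplicated(paste(object@carrier[po], object@origin[po])))
        return("duplicate (carrier, origin) haplotype")
    v <- .validMarkerMap(object@markers)
    if (!isTRUE(v)) return(v)
    TRUE
})

#' Construct a HaplotypeSet
#'
#' @param haplotypes integer matrix (haplotypes x SNPs) over \{0, 1, NA\}.
#' @param carrier character vector of carrier individual ids, one per row.
#' @param origin character vector over \{"P","M","U"\}, one per row.
#' @param markers marker map \code{GRanges}.
#' @return a \linkS4class{HaplotypeSet}.
#' @export
HaplotypeSet <- function(haplotypes, carrier, origin, markers) {
    storage.mode(haplotypes) <- "integer"
    new("HaplotypeSet", haplotypes = haplotypes,
        carrier = as.character(carrier), origin = as.character(origin),
        markers = markers)
}

#' Pedigree: parent map with birth years
#'
#' Records of (id, sire, dam, birth_year); unknown parents are \code{NA}.
#' Parents without their own record are treated as founders.  The graph must
#' be acyclic and offspring cannot be born before a recorded parent.
#'
#' @aliases Pedigree-class
#' @export
setClass("Pedigree", representation(records = "data.frame"))

.pedigreeCycle <- function(id, sire, dam) {
    ## Kahn topological sort over recorded individuals; returns NULL or one cycle
    idx <- seq_along(id)
    names(idx) <- id
    parent1 <- ifelse(!is.na(sire) & sire %in% id, idx[sire], NA_integer_)
    parent2 <- ifelse(!is.na(dam) & dam %in% id, idx[dam], NA_integer_)
    indeg <- integer(length(id))
    children <- vector("list", length(id))
    for (i in idx) {
        for (p in c(parent1[i], parent2[i])) {
            if (!is.na(p)) {
                indeg[i] <- indeg[i] + 1L
                children[[p]] <- c(children[[p]], i)
            }
        }
    }
    queue <- idx[indeg == 0L]
    seen <- 0L
    while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        seen <- seen + 1L
        for (ch in children[[v]]) {
            indeg[ch] <- indeg[ch] - 1L
            if (indeg[ch] == 0L) queue <- c(queue, ch)
        }
    }
    if (seen == length(id)) return(NULL)
    ## walk parents from a node still in the cycle to report it
    v <- idx[indeg > 0L][1]
    path <- character(0)
    repeat {
        path <- c(path, id[v])
        v <- if (!is.na(parent1[v]) && indeg[parent1[v]] > 0L) parent1[v]
             else parent2[v]
        if (id[v] %in% path) {
            path <- c(path[which(path == id[v]):length(path)], id[v])
            return(path)
        }
    }
}

setValidity("Pedigree", function(object) {
    r <- object@records
    need <- c("id", "sire", "dam", "birth_year")
    if (!all(need %in% names(r)))
        return("records need columns id, sire, dam, birth_year")
    if (anyDuplicated(r$id))
        return(paste0("duplicate individual id: ",
                      r$id[duplicated(r$id)][1]))
    cyc <- .pedigreeCycle(r$id, r$sire, r$dam)
    if (!is.null(cyc))
        return(paste0("pedigree cycle: ", paste(cyc, collapse = " -> ")))
    for (pcol in c("sire", "dam")) {
        p <- r[[pcol]]
        known <- !is.na(p) & p %in% r$id
        if (any(known)) {
            py <- r$birth_year[match(p[known], r$id)]
            oy <- r$birth_year[known]
            bad <- !is.na(py) & !is.na(oy) & oy < py
            if (any(bad))
                return(paste0("individual ", r$id[known][bad][1],
                              " born before its recorded ", pcol))
        }
    }
    TRUE
})

#' Construct a Pedigree
#'
#' @param id,sire,dam character vectors; \code{NA} (or "0"/"" in the file
#'   readers) marks an unknown parent.
#' @param birth_year integer vector, \code{NA} allowed.
#' @return a \linkS4class{Pedigree}.
#' @examples
#' ped <- Pedigree(c("A", "B", "X"), c(NA, NA, "A"), c(NA, NA, "B"),
#'                 c(2000L, 2000L, 2002L))
#' @export
Pedigree <- function(id, sire, dam, birth_year = NA_integer_) {
    r <- data.frame(id = as.character(id), sire = as.character(sire),
                    dam = as.character(dam),
                    birth_year = as.integer(birth_year),
                    stringsAsFactors = FALSE)
    r$sire[r$sire %in% c("0", "")] <- NA_character_
    r$dam[r$dam %in% c("0", "")] <- NA_character_
    new("Pedigree", records = r)
}

#' GeneticMap: bp-to-Morgan conversion policy
#'
#' Selects one of three centimorgan-per-megabase conversion modes:
#' \code{"uniform1"} (1 cM ~ 1 Mb everywhere), \code{"genome_avg"} (a single
#' genome-wide rate) or \code{"per_chrom"} (one rate per chromosome, e.g.
#' from a linkage-map comparison).
#'
#' @aliases GeneticMap-class
#' @export
setClass("GeneticMap",
         representation(mode = "character",
                        genomeRate = "numeric",
                        chromRates = "numeric"))

setValidity("GeneticMap", function(object) {
    if (!object@mode %in% c("uniform1", "genome_avg", "per_chrom"))
        return("mode must be 'uniform1', 'genome_avg' or 'per_chrom'")
    if (object@mode == "genome_avg" &&
        (length(object@genomeRate) != 1L || object@genomeRate <= 0))
        return("genome_avg mode needs a single positive genomeRate")
    if (object@mode == "per_chrom" &&
        (length(object@chromRates) == 0L || any(object@chromRates <= 0) ||
         is.null(names(object@chromRates))))
        return("per_chrom mode needs named positive chromRates")
    TRUE
})

#' Construct a GeneticMap
#'
#' @param mode one of \code{"uniform1"}, \code{"genome_avg"},
#'   \code{"per_chrom"}.
#' @param genomeRate genome-wide rate in cM/Mb (mode \code{"genome_avg"}).
#' @param chromRates named numeric vector of per-chromosome rates in cM/Mb
#'   (mode \code{"per_chrom"}); names are autosome labels.
#' @return a \linkS4class{GeneticMap}.
#' @examples
#' geneticMap("genome_avg", genomeRate = 1.85)
#' @export
geneticMap <- function(mode = c("uniform1", "genome_avg", "per_chrom"),
                       genomeRate = numeric(0), chromRates = numeric(0)) {
    mode <- match.arg(mode)
    new("GeneticMap", mode = mode, genomeRate = as.numeric(genomeRate),
        chromRates = chromRates)
}

#' SimTruth: full output of the Wright-Fisher simulator
#'
#' Holds the final-generation haplotype pool per chromosome, the marker map
#' with true genetic positions, the realized per-generation population size
#' and the configuration used, so every downstream estimate can be checked
#' against truth.
#'
#' @aliases SimTruth-class
#' @export
setClass("SimTruth",
         representation(haplotypes = "list",
                        markers = "GRanges",
                        neByGeneration = "data.frame",
                        config = "list"))

setValidity("SimTruth", function(object) {
    if (!all(vapply(object@haplotypes, is.matrix, TRUE)))
        return("haplotypes must be a list of matrices (one per chromosome)")
    m <- sum(vapply(object@haplotypes, ncol, 0L))
    if (m != length(object@markers))
        return("total SNP count must match marker map")
    if (!all(c("generation", "N") %in% names(object@neByGeneration)))
        return("neByGeneration needs columns generation, N")
    TRUE
})

setMethod("show", "SnpGenotypes", function(object) {
    d <- SummarizedExperiment::assay(object, "dosage")
    cat("SnpGenotypes:", nrow(d), "SNPs x", ncol(d), "individuals on",
        length(unique(as.character(seqnames(rowRanges(object))))),
        "chromosome(s);",
        sprintf("%.2f%% missing\n", 100 * mean(is.na(d))))
})

setMethod("show", "HaplotypeSet", function(object) {
    cat("HaplotypeSet:", nrow(object@haplotypes), "haplotypes x",
        ncol(object@haplotypes), "SNPs from",
        length(unique(object@carrier)), "individuals\n")
})

setMethod("show", "Pedigree", function(object) {
    r <- object@records
    founders <- sum(is.na(r$sire) & is.na(r$dam))
    cat("Pedigree:", nrow(r), "individuals (", founders, "founders )\n")
})

setMethod("show", "GeneticMap", function(object) {
    cat("GeneticMap mode:", object@mode)
    if (object@mode == "genome_avg")
        cat(" (", object@genomeRate, "cM/Mb )")
    if (object@mode == "per_chrom")
        cat(" (", length(object@chromRates), "chromosome rates )")
    cat("\n")
})

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth:", length(object@haplotypes), "chromosome(s),",
        length(object@markers), "SNPs,",
        nrow(object@haplotypes[[1]]), "haplotypes in final generation\n")
})
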