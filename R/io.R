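#' Read PLINK-style text genotypes
#'
#' Reads a whitespace-separated \code{.map} file (chromosome, SNP id,
#' genetic position in cM, physical position in bp) and a \code{.ped} file
#' (family, id, sire, dam, sex, phenotype, then two allele columns per SNP;
#' \code{"0"} is a missing allele).  Markers on unmapped contigs
#' (chromosome \code{"0"}) or non-autosomal chromosomes (non-numeric
#' labels such as \code{"X"}) are dropped with a message, keeping autosomal
#' SNPs only.  Dosages count copies of the reference allele; by default the
#' reference is the first allele observed at each SNP in file order.
#' Half-missing genotypes (one allele \code{"0"}) are treated as fully
#' missing.
#'
#' @param ped_path,map_path paths to the \code{.ped} and \code{.map} files.
#' @param ref_allele \code{"first"} (default) to polarize against the first
#'   allele observed per SNP, or a single allele symbol (e.g. \code{"A"})
#'   used as the reference at every SNP where it is observed.
#' @return a \linkS4class{SnpGenotypes}.
#' @export
readGenotypes <- function(ped_path, map_path, ref_allele = "first") {
    stopifnot(file.exists(ped_path), file.exists(map_path))
    map <- utils::read.table(map_path, header = FALSE,
                             colClasses = "character")
    if (ncol(map) != 4L)
        stop(".map must have 4 columns (chrom, id, cM, bp)")
    names(map) <- c("chrom", "id", "cM", "bp")
    chrom_num <- suppressWarnings(as.integer(map$chrom))
    autosomal <- !is.na(chrom_num) & chrom_num >= 1L
    n_drop <- sum(!autosomal)
    if (n_drop > 0L)
        message(n_drop, " marker(s) unmapped or on sex chromosomes dropped; ",
                sum(autosomal), " autosomal SNP(s) kept")
    m_all <- nrow(map)

    lines <- readLines(ped_path)
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(trimws(lines), "[ \t]+")
    expected <- 6L + 2L * m_all
    nf <- lengths(fields)
    if (any(nf != expected))
        stop(".ped row ", which(nf != expected)[1], " has ",
             nf[nf != expected][1], " fields, expected ", expected)
    n <- length(fields)
    M <- matrix(unlist(fields), nrow = n, byrow = TRUE)
    ids <- M[, 2]
    if (anyDuplicated(ids)) stop("duplicate individual id in .ped")

    keep <- which(autosomal)
    dos <- matrix(NA_integer_, nrow = length(keep), ncol = n)
    for (k in seq_along(keep)) {
        j <- keep[k]
        a1 <- M[, 5L + 2L * j]
        a2 <- M[, 6L + 2L * j]
        inter <- as.vector(rbind(a1, a2))   # file scan order within the SNP
        obs <- inter[inter != "0"]
        alleles <- unique(obs)
        if (length(alleles) > 2L)
            stop("SNP ", map$id[j], " has ", length(alleles),
                 " distinct alleles; biallelic input required")
        if (length(alleles) == 0L) {
            next                             # all missing
        }
        ref <- if (identical(ref_allele, "first")) alleles[1]
               else if (ref_allele %in% alleles) ref_allele
               else alleles[1]
        x <- (a1 == ref) + (a2 == ref)
        x[a1 == "0" | a2 == "0"] <- NA_integer_
        dos[k, ] <- as.integer(x)
    }
    colnames(dos) <- ids
    cM <- suppressWarnings(as.numeric(map$cM[keep]))
    mm <- markerMap(chrom_num[keep], as.integer(map$bp[keep]),
                    map$id[keep],
                    cM = if (all(is.na(cM)) || all(cM == 0)) NULL else cM)
    ## markerMap sorts by (chrom, bp); permute dosage rows to match
    ord <- order(chrom_num[keep], as.integer(map$bp[keep]))
    SnpGenotypes(dos[ord, , drop = FALSE], mm)
}

#' Write PLINK-style text genotypes
#'
#' Inverse of \code{\link{readGenotypes}}: the reference allele is written
#' as \code{"A"} and the alternate as \code{"B"}, missing genotypes as
#' \code{"0 0"}.  Reading back with \code{ref_allele = "A"} reproduces the
#' object exactly; with the default polarization SNPs whose first listed
#' individual is homozygous alternate come back with dosages flipped
#' (x to 2 - x), which leaves every frequency-based statistic unchanged.
#'
#' @param g a \linkS4class{SnpGenotypes}.
#' @param ped_path,map_path output paths.
#' @return invisibly, the two paths.
#' @export
writeGenotypes <- function(g, ped_path, map_path) {
    mm <- markers(g)
    cM <- if (!is.null(mcols(mm)$cM)) mcols(mm)$cM else rep(0, length(mm))
    map <- data.frame(chrom = as.character(seqnames(mm)), id = names(mm),
                      cM = format(cM, trim = TRUE, scientific = FALSE),
                      bp = GenomicRanges::start(mm))
    utils::write.table(map, map_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    d <- dosage(g)
    code <- c("B B", "A B", "A A")      # dosage 0, 1, 2
    lines <- vapply(seq_len(ncol(d)), function(i) {
        x <- d[, i]
        al <- ifelse(is.na(x), "0 0", code[x + 1L])
        paste(c("FAM", colnames(d)[i], "0", "0", "0", "-9", al),
              collapse = " ")
    }, character(1))
    writeLines(lines, ped_path)
    invisible(c(ped = ped_path, map = map_path))
}

#' Read a pedigree TSV
#'
#' Tab-separated file with header columns \code{id}, \code{sire},
#' \code{dam}, \code{birth_year}; \code{"0"} or an empty field marks an
#' unknown parent.  Duplicate ids and pedigree cycles are rejected.
#'
#' @param path input path.
#' @return a \linkS4class{Pedigree}.
#' @export
readPedigree <- function(path) {
    stopifnot(file.exists(path))
    r <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
    need <- c("id", "sire", "dam", "birth_year")
    if (!all(need %in% names(r)))
        stop("pedigree TSV needs header columns id, sire, dam, birth_year")
    by <- suppressWarnings(as.integer(r$birth_year))
    Pedigree(r$id, r$sire, r$dam, by)
}

#' Write a pedigree TSV
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writePedigree <- function(ped, path) {
    r <- pedigreeTable(ped)
    out <- data.frame(id = r$id,
                      sire = ifelse(is.na(r$sire), "0", r$sire),
                      dam = ifelse(is.na(r$dam), "0", r$dam),
                      birth_year = ifelse(is.na(r$birth_year), "0",
                                          as.character(r$birth_year)))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a haplotype TSV
#'
#' One row per haplotype: carrier id, parental origin (\code{P}, \code{M}
#' or \code{U}), then one \code{0}/\code{1}/\code{.} symbol per SNP
#' (\code{.} = missing), tab-separated, no header.  The number of allele
#' columns must match the supplied marker map and an individual may
#' contribute at most two rows.
#'
#' @param path input path.
#' @param markers marker map \code{GRanges} the haplotypes refer to.
#' @return a \linkS4class{HaplotypeSet}.
#' @export
readHaplotypes <- function(path, markers) {
    stopifnot(file.exists(path))
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    m <- length(markers)
    nf <- lengths(fields)
    if (any(nf != m + 2L))
        stop("haplotype row ", which(nf != m + 2L)[1], " has ",
             nf[nf != m + 2L][1] - 2L, " allele columns, expected ", m)
    M <- matrix(unlist(fields), nrow = length(fields), byrow = TRUE)
    h <- M[, -(1:2), drop = FALSE]
    h[h == "."] <- NA
    storage.mode(h) <- "integer"
    HaplotypeSet(h, carrier = M[, 1], origin = M[, 2], markers = markers)
}

#' Write a haplotype TSV
#'
#' @param h a \linkS4class{HaplotypeSet}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeHaplotypes <- function(h, path) {
    mat <- haplotypes(h)
    sym <- matrix(as.character(mat), nrow = nrow(mat))
    sym[is.na(sym)] <- "."
    lines <- vapply(seq_len(nrow(sym)), function(i)
        paste(c(carriers(h)[i], origins(h)[i], sym[i, ]), collapse = "\t"),
        character(1))
    writeLines(lines, path)
    invisible(path)
}
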