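#' Pedigree inbreeding coefficients (Meuwissen-Luo)
#'
#' Computes, for every recorded individual, the inbreeding coefficient F
#' as the diagonal of the numerator relationship matrix minus one, using
#' the Meuwissen-Luo ancestor-traversal algorithm (no full matrix is ever
#' formed).  The result is identical to Wright's path-counting
#' coefficient.  Named parents without their own record are treated as
#' unique non-inbred founders, as are unknown parents.
#'
#' @param ped a \linkS4class{Pedigree} (acyclic; enforced by the class).
#' @return named numeric vector of F in [0, 1], one per recorded
#'   individual.
#' @examples
#' # offspring of a sire mated to his own daughter: F = 0.25
#' ped <- Pedigree(c("A", "B", "X", "Y"), c(NA, NA, "A", "A"),
#'                 c(NA, NA, "B", "X"), c(2000, 2000, 2002, 2004))
#' fPedigree(ped)["Y"]
#' @export
fPedigree <- function(ped) {
    r <- pedigreeTable(ped)
    ids <- r$id
    ## implicit founders: named parents without a record
    extra <- setdiff(stats::na.omit(c(r$sire, r$dam)), ids)
    all_id <- c(ids, extra)
    sire <- c(r$sire, rep(NA_character_, length(extra)))
    dam <- c(r$dam, rep(NA_character_, length(extra)))
    n <- length(all_id)
    si <- match(sire, all_id); si[is.na(si)] <- 0L
    di <- match(dam, all_id); di[is.na(di)] <- 0L

    ## topological order (parents first) by Kahn's algorithm
    indeg <- integer(n)
    children <- vector("list", n)
    for (i in seq_len(n)) for (p in c(si[i], di[i])) if (p > 0L) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
    }
    ord <- integer(0)
    queue <- which(indeg == 0L)
    while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        ord <- c(ord, v)
        for (ch in children[[v]]) {
            indeg[ch] <- indeg[ch] - 1L
            if (indeg[ch] == 0L) queue <- c(queue, ch)
        }
    }
    pos <- integer(n); pos[ord] <- seq_len(n)        # topological rank
    F <- numeric(n)
    D <- numeric(n)
    for (k in seq_len(n)) {
        i <- ord[k]
        s <- si[i]; d <- di[i]
        D[i] <- 1 - (if (s > 0L) 0.25 * (1 + F[s]) else 0) -
                    (if (d > 0L) 0.25 * (1 + F[d]) else 0)
        if (s == 0L || d == 0L) { F[i] <- 0; next }
        ## A_ii = sum over ancestors j of L_ij^2 D_j, traversed youngest-first
        L <- numeric(n)
        L[i] <- 1
        Aii <- 0
        active <- k
        while (length(active)) {
            k2 <- max(active)
            active <- active[active != k2]
            j <- ord[k2]
            if (L[j] == 0) next
            Aii <- Aii + L[j]^2 * D[j]
            for (p in c(si[j], di[j])) if (p > 0L) {
                if (L[p] == 0) active <- c(active, pos[p])
                L[p] <- L[p] + 0.5 * L[j]
            }
            L[j] <- 0
        }
        F[i] <- Aii - 1
    }
    out <- F[seq_along(ids)]
    names(out) <- ids
    out
}

#' Marker-based inbreeding estimators
#'
#' Three SNP-based estimators of individual inbreeding, computed per
#' individual over its m non-missing SNPs with reference-allele frequency
#' p per SNP (x is the dosage):
#' F1 (variance of the additive genotype)
#'   = mean((x - 2p)^2 / (2p(1-p))) - 1;
#' F2 (excess homozygosity)
#'   = mean(1 - x(2-x) / (2p(1-p)));
#' F3 (correlation between uniting gametes)
#'   = mean((x^2 - (1+2p)x + 2p^2) / (2p(1-p))).
#' Negative values (less homozygous than the base population) are
#' legitimate estimates and are never clamped here; clamping is a
#' reporting choice (see \code{\link{inbreedingTrend}}).
#'
#' @param g a \linkS4class{SnpGenotypes}.
#' @param freqs optional named (by SNP id) or positional numeric vector of
#'   reference-allele frequencies to use as the base population; defaults
#'   to frequencies estimated from the sample itself.
#' @return data.frame: id, F1, F2, F3, m (SNPs used per individual).
#' @export
fMarkers <- function(g, freqs = NULL) {
    d <- dosage(g)
    mm <- markers(g)
    if (is.null(freqs)) {
        n_called <- rowSums(!is.na(d))
        p <- ifelse(n_called > 0, rowSums(d, na.rm = TRUE) / (2 * n_called),
                    NA_real_)
    } else {
        p <- if (!is.null(names(freqs))) unname(freqs[names(mm)])
             else as.numeric(freqs)
        if (length(p) != nrow(d))
            stop("freqs must cover every SNP")
    }
    usable <- !is.na(p) & p > 0 & p < 1
    if (!all(usable))
        warning(sum(!usable), " SNP(s) with p = 0 or 1 excluded")
    d <- d[usable, , drop = FALSE]
    p <- p[usable]
    h <- 2 * p * (1 - p)
    x <- d                                  # m x n dosage with NA
    s1 <- (x - 2 * p)^2 / h
    s2 <- 1 - x * (2 - x) / h
    s3 <- (x^2 - (1 + 2 * p) * x + 2 * p^2) / h
    m_i <- as.integer(colSums(!is.na(x)))
    data.frame(id = colnames(d),
               F1 = colMeans(s1, na.rm = TRUE) - 1,
               F2 = colMeans(s2, na.rm = TRUE),
               F3 = colMeans(s3, na.rm = TRUE),
               m = m_i, row.names = NULL, stringsAsFactors = FALSE)
}

#' Inbreeding trend over birth years
#'
#' Per birth year and per inbreeding metric: the mean with negative
#' estimates clamped to 0 (the default, matching the convention of
#' reporting only positive inbreeding), or the raw mean; plus the fraction
#' of individuals exceeding the first-cousin level F > 0.0625.
#'
#' @param records data.frame with columns \code{id}, \code{birth_year} and
#'   one or more numeric metric columns (e.g. F_PED, F1, F2, F3).
#' @param clamp_negative clamp negative values to 0 before averaging
#'   (default TRUE); stored estimates are never modified.
#' @param threshold critical inbreeding level for the exceedance fraction
#'   (default 0.0625, the offspring-of-first-cousins value).
#' @return data.frame: year, n, then mean_<metric> and frac_high_<metric>
#'   per metric.
#' @export
inbreedingTrend <- function(records, clamp_negative = TRUE,
                            threshold = 0.0625) {
    stopifnot(all(c("id", "birth_year") %in% names(records)))
    metrics <- setdiff(names(records), c("id", "birth_year"))
    metrics <- metrics[vapply(records[metrics], is.numeric, TRUE)]
    keep <- !is.na(records$birth_year)
    records <- records[keep, , drop = FALSE]
    years <- sort(unique(records$birth_year))
    rows <- lapply(years, function(y) {
        sub <- records[records$birth_year == y, , drop = FALSE]
        out <- data.frame(year = y, n = nrow(sub))
        for (mtr in metrics) {
            v <- sub[[mtr]]
            vm <- if (clamp_negative) pmax(v, 0) else v
            out[[paste0("mean_", mtr)]] <- mean(vm, na.rm = TRUE)
            out[[paste0("frac_high_", mtr)]] <-
                mean(v > threshold, na.rm = TRUE)
        }
        out
    })
    do.call(rbind, c(rows, make.row.names = FALSE))
}
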