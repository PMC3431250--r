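## Independent oracles used to cross-check the package implementations.
## Each one takes a deliberately different computational route from the
## function it checks.

## HWE: direct multinomial enumeration via log-factorials (the package
## uses the Wigginton up/down recurrence instead).
hweOracleP <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    nA <- 2 * nAA + nAa
    r <- min(nA, 2 * n - nA)
    if (r == 0) return(1)
    hets <- seq(r %% 2, r, by = 2)
    logw <- vapply(hets, function(h) {
        hom_r <- (r - h) / 2
        hom_c <- n - h - hom_r
        lfactorial(n) - lfactorial(hom_r) - lfactorial(h) -
            lfactorial(hom_c) + h * log(2)
    }, numeric(1))
    w <- exp(logw - max(logw))
    p <- w / sum(w)
    obs <- p[match(min(nAa, r), hets)]  # het count w.r.t. the rarer allele
    sum(p[p <= obs * (1 + 1e-9)])
}

## Pedigree inbreeding: memoized Malecot coancestry recursion
## f(i,i) = (1 + F_i)/2, f(i,j) = (f(s_i,j) + f(d_i,j))/2 recursing on the
## topologically younger argument.  (The package uses the Meuwissen-Luo
## L-traversal instead.)
kinshipOracleF <- function(id, sire, dam) {
    n <- length(id)
    si <- match(sire, id); di <- match(dam, id)
    ## topological depth: founders 0, else 1 + max(parent depth)
    depth <- rep(NA_integer_, n)
    while (anyNA(depth)) {
        for (i in which(is.na(depth))) {
            ds <- if (is.na(si[i])) 0L else depth[si[i]]
            dd <- if (is.na(di[i])) 0L else depth[di[i]]
            if (!is.na(ds) && !is.na(dd)) depth[i] <- 1L + max(ds, dd)
        }
    }
    memo <- new.env(parent = emptyenv())
    f <- function(i, j) {
        if (is.na(i) || is.na(j)) return(0)
        key <- paste(min(i, j), max(i, j))
        got <- memo[[key]]
        if (!is.null(got)) return(got)
        val <- if (i == j) {
            0.5 * (1 + f(si[i], di[i]))
        } else {
            a <- if (depth[i] >= depth[j]) i else j
            b <- if (a == i) j else i
            0.5 * (f(si[a], b) + f(di[a], b))
        }
        memo[[key]] <- val
        val
    }
    vapply(seq_len(n), function(i) f(si[i], di[i]), numeric(1))
}

## Gabriel blocks: brute-force candidate enumeration with explicit loops
## (the package uses summed-area tables).
gabrielOracle <- function(class_mat, bp, min_frac = 0.95,
                          max_span_kb = NULL) {
    m <- length(bp)
    cand <- list()
    for (a in seq_len(m - 1)) for (b in seq(a + 1, m)) {
        if (class_mat[a, b] != "STRONG_LD") next
        if (!is.null(max_span_kb) && bp[b] - bp[a] > max_span_kb * 1000)
            next
        ns <- 0L; ni <- 0L
        for (i in a:(b - 1)) for (j in (i + 1):b) {
            cl <- class_mat[i, j]
            if (cl == "STRONG_LD") { ns <- ns + 1L; ni <- ni + 1L }
            else if (cl == "RECOMB") ni <- ni + 1L
        }
        if (ni > 0L && ns / ni >= min_frac)
            cand[[length(cand) + 1L]] <- c(a = a, b = b,
                                           span = bp[b] - bp[a])
    }
    if (!length(cand))
        return(data.frame(first = integer(0), last = integer(0)))
    cd <- do.call(rbind, cand)
    cd <- cd[order(-cd[, "span"], cd[, "a"], cd[, "b"]), , drop = FALSE]
    used <- logical(m)
    acc <- list()
    for (k in seq_len(nrow(cd))) {
        a <- cd[k, "a"]; b <- cd[k, "b"]
        if (any(used[a:b])) next
        used[a:b] <- TRUE
        acc[[length(acc) + 1L]] <- data.frame(first = as.integer(a),
                                              last = as.integer(b))
    }
    out <- do.call(rbind, acc)
    out[order(out$first), , drop = FALSE]
}

## random classified-pair fixture for a chromosome of m SNPs
randomClassifiedChrom <- function(m, seed) {
    set.seed(seed)
    bp <- sort(sample.int(1e6, m))
    cls <- matrix("UNINFORMATIVE", m, m)
    ut <- which(upper.tri(cls), arr.ind = TRUE)
    draw <- sample(c("STRONG_LD", "RECOMB", "UNINFORMATIVE"),
                   nrow(ut), replace = TRUE, prob = c(0.45, 0.35, 0.2))
    cls[ut] <- draw
    cls[ut[, c(2, 1)]] <- draw
    ids <- sprintf("c%d_s%d", seed, seq_len(m))
    mm <- markerMap(rep(1L, m), bp, ids)
    pairs <- data.frame(snp_i = ids[ut[, 1]], snp_j = ids[ut[, 2]],
                        chrom = "1", class = draw,
                        stringsAsFactors = FALSE)
    list(markers = mm, pairs = pairs, class_mat = cls, bp = bp)
}

## genotype fixture builder (SNPs x individuals dosage)
makeGenotypes <- function(dos, chrom = 1L) {
    m <- nrow(dos)
    mm <- markerMap(rep(chrom, length.out = m), seq_len(m) * 1000L,
                    sprintf("fix%d", seq_len(m)))
    if (is.null(colnames(dos)))
        colnames(dos) <- sprintf("ind%d", seq_len(ncol(dos)))
    SnpGenotypes(dos, mm)
}
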