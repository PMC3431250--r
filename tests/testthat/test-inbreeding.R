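test_that("pedigree F reproduces the classical mating values", {
    ## parent x own-offspring
    p1 <- Pedigree(c("A", "B", "X", "Y"), c(NA, NA, "A", "A"),
                   c(NA, NA, "B", "X"), c(2000, 2000, 2002, 2004))
    expect_equal(unname(fPedigree(p1)["Y"]), 0.25)
    ## paternal half sibs
    p2 <- Pedigree(c("S", "D1", "D2", "H1", "H2", "Z"),
                   c(NA, NA, NA, "S", "S", "H1"),
                   c(NA, NA, NA, "D1", "D2", "H2"),
                   c(2000, 2000, 2000, 2002, 2002, 2004))
    expect_equal(unname(fPedigree(p2)["Z"]), 0.125)
    ## first cousins
    p3 <- Pedigree(c("G1", "G2", "A", "B", "M1", "M2", "C1", "C2", "Q"),
                   c(NA, NA, "G1", "G1", NA, NA, "A", "B", "C1"),
                   c(NA, NA, "G2", "G2", NA, NA, "M1", "M2", "C2"),
                   c(rep(2000, 6), 2002, 2002, 2004))
    expect_equal(unname(fPedigree(p3)["Q"]), 0.0625)
    ## founders and outbred individuals are non-inbred
    expect_equal(unname(fPedigree(p3)[c("A", "C1")]), c(0, 0))
})

test_that("Meuwissen-Luo F equals the coancestry-recursion oracle", {
    set.seed(41)
    for (rep in 1:40) {
        n <- sample(6:12, 1)
        id <- sprintf("i%d", seq_len(n))
        sire <- dam <- rep(NA_character_, n)
        for (k in 3:n) {
            ## draw parents among older individuals (or leave unknown)
            if (runif(1) < 0.8) {
                pr <- sample(k - 1, 2, replace = TRUE)
                sire[k] <- id[pr[1]]
                dam[k] <- id[pr[2]]
            }
        }
        ped <- Pedigree(id, sire, dam, seq_len(n))
        got <- fPedigree(ped)
        want <- kinshipOracleF(id, sire, dam)
        expect_equal(unname(got), want, tolerance = 1e-12,
                     info = paste("pedigree rep", rep))
    }
})

test_that("pedigree cycles are rejected", {
    expect_error(Pedigree(c("A", "B"), c("B", "A"), c(NA, NA), c(0, 0)),
                 "cycle")
})

test_that("marker F estimators match hand arithmetic at the extremes", {
    mm <- markerMap(1, (1:4) * 1000L, sprintf("s%d", 1:4))
    p_half <- rep(0.5, 4)
    all_het <- SnpGenotypes(matrix(1L, 4, 1, dimnames = list(NULL, "i")), mm)
    f <- fMarkers(all_het, freqs = p_half)
    expect_equal(c(f$F1, f$F2, f$F3), c(-1, -1, -1))
    all_hom <- SnpGenotypes(matrix(2L, 4, 1, dimnames = list(NULL, "i")), mm)
    f2 <- fMarkers(all_hom, freqs = p_half)
    expect_equal(c(f2$F1, f2$F2, f2$F3), c(1, 1, 1))
    ## mixed case, hand-computed from the three formulas
    mm2 <- markerMap(1, c(1000L, 2000L), c("a", "b"))
    g3 <- SnpGenotypes(matrix(c(0L, 1L), 2, 1, dimnames = list(NULL, "i")),
                       mm2)
    f3 <- fMarkers(g3, freqs = c(a = 0.5, b = 0.25))
    expect_equal(f3$F1, 1 / 3)
    expect_equal(f3$F2, -1 / 3)
    expect_equal(f3$F3, 0)
    ## fixed SNPs are excluded with a warning
    expect_warning(
        f4 <- fMarkers(g3, freqs = c(a = 0.5, b = 1)), "excluded")
    expect_identical(f4$m, 1L)
})

test_that("missing genotypes shrink the per-individual marker count", {
    mm <- markerMap(1, (1:3) * 1000L, sprintf("s%d", 1:3))
    d <- matrix(c(1L, NA, 1L, 1L, 1L, 1L), 3, 2,
                dimnames = list(NULL, c("u", "v")))
    f <- fMarkers(SnpGenotypes(d, mm), freqs = rep(0.5, 3))
    expect_identical(f$m, c(2L, 3L))
    expect_equal(f$F1, c(-1, -1))
})

test_that("marker F is centered at zero for outbred HWE individuals", {
    set.seed(43)
    m <- 4000L; n <- 60L
    p <- runif(m, 0.1, 0.9)
    d <- matrix(rbinom(m * n, 2, rep(p, n)), nrow = m)
    g <- makeGenotypes(d)
    f <- fMarkers(g, freqs = p)
    for (v in list(f$F1, f$F2, f$F3))
        expect_lt(abs(mean(v)), 3 * stats::sd(v) / sqrt(n))
})

test_that("marker F recovers the true inbreeding of selfed lines", {
    set.seed(44)
    m <- 4000L; n <- 50L
    p <- runif(m, 0.2, 0.8)
    for (gens in c(1L, 2L)) {
        Ftrue <- 1 - 0.5^gens
        ## draw genotypes from the inbred mixture: IBD with prob Ftrue
        ibd <- matrix(rbinom(m * n, 1, Ftrue), nrow = m)
        hom <- matrix(rbinom(m * n, 1, rep(p, n)), nrow = m) * 2L
        hwe <- matrix(rbinom(m * n, 2, rep(p, n)), nrow = m)
        d <- ifelse(ibd == 1L, hom, hwe)
        storage.mode(d) <- "integer"
        f <- fMarkers(makeGenotypes(d), freqs = p)
        for (v in list(f$F1, f$F2, f$F3))
            expect_lt(abs(mean(v) - Ftrue), 3 * stats::sd(v) / sqrt(n))
    }
})

test_that("the birth-year trend clamps negatives for reporting only", {
    rec <- data.frame(id = c("a", "b", "c", "d", "e"),
                      birth_year = c(2001L, 2001L, 2002L, 2002L, 2002L),
                      F1 = c(-0.02, 0.02, 0.05, 0.07, 0.10))
    tr <- inbreedingTrend(rec)
    expect_equal(tr$mean_F1, c(0.01, mean(c(0.05, 0.07, 0.10))))
    tr_raw <- inbreedingTrend(rec, clamp_negative = FALSE)
    expect_equal(tr_raw$mean_F1[1], 0)
    ## fraction above the first-cousin critical level
    expect_equal(tr$frac_high_F1, c(0, 2 / 3))
    ## input records are untouched
    expect_equal(rec$F1[1], -0.02)
})
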