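test_that("individual filter removes strictly-more-than-threshold missingness", {
    set.seed(1)
    d <- matrix(sample(0:2, 400, replace = TRUE), nrow = 100)
    d[1:11, 1] <- NA        # 11% missing -> removed
    d[1:10, 2] <- NA        # exactly 10% -> retained
    g <- makeGenotypes(d)
    res <- filterIndividuals(g, max_missing = 0.10)
    expect_identical(res$ledger$removed, 1L)
    expect_identical(individuals(res$genotypes), individuals(g)[-1])

    res2 <- filterIndividuals(makeGenotypes(matrix(1L, 5, 3)))
    expect_identical(res2$ledger$removed, 0L)
    expect_error(filterIndividuals(g[, 0]), "empty")
})

test_that("HWE exact p-values match hand enumeration", {
    expect_equal(hweExactPvalue(1, 0, 1), 1 / 3)
    expect_equal(hweExactPvalue(0, 2, 0), 1)
    expect_equal(hweExactPvalue(5, 0, 0), 1)   # monomorphic
    expect_error(hweExactPvalue(0, 0, 0), "zero")
})

test_that("HWE exact test agrees with the enumeration oracle (small n)", {
    for (n in c(2:8, 12)) {
        for (nAA in 0:n) for (nAa in 0:(n - nAA)) {
            naa <- n - nAA - nAa
            expect_equal(hweExactPvalue(nAA, nAa, naa),
                         hweOracleP(nAA, nAa, naa), tolerance = 1e-10,
                         info = sprintf("(%d,%d,%d)", nAA, nAa, naa))
        }
    }
})

test_that("marker QC filters sequentially with a conserving ledger", {
    n <- 40L
    row_of <- function(counts) {    # counts = c(n2, n1, n0, nNA)
        sample(rep(c(2L, 1L, 0L, NA), counts))
    }
    set.seed(3)
    d <- rbind(
        row_of(c(10, 17, 10, 3)),   # call rate 37/40 = 0.925 -> (i)
        row_of(c(10, 16, 10, 4)),   # call rate 0.90          -> (i)
        row_of(c(39, 1, 0, 0)),     # MAF 1/80                -> (ii)
        row_of(c(0, 1, 39, 0)),     # MAF 1/80                -> (ii)
        row_of(c(38, 2, 0, 0)),     # MAF 2/80 = 0.025        -> (ii)
        row_of(c(0, 40, 0, 0)),     # all het: HWE breaks     -> (iii)
        row_of(c(10, 20, 10, 0)),   # perfect HWE             -> pass
        row_of(c(9, 22, 9, 0)),     # pass
        row_of(c(12, 20, 8, 0)),    # pass
        row_of(c(36, 4, 0, 0)))     # MAF 0.05 exactly        -> pass (>=)
    g <- makeGenotypes(d)
    res <- markerQC(g)
    expect_identical(res$ledger$removed, c(2L, 3L, 1L))
    expect_identical(res$ledger$remaining, c(8L, 5L, 4L))
    expect_identical(sum(res$stats$kept), 4L)
    ## ledger conservation: remaining_k = remaining_{k-1} - removed_k
    full <- rbind(.start = data.frame(step = "input", unit = "SNPs",
                                      threshold = NA, removed = 0L,
                                      remaining = nrow(d)), res$ledger)
    expect_identical(diff(full$remaining), -full$removed[-1])
})

test_that("a low-call SNP is never tested downstream and MAF 0.05 is kept", {
    res <- markerQC(makeGenotypes(rbind(
        c(2L, NA, NA, NA, NA, 2L, 1L, 0L, 1L, 1L),  # call rate 0.6
        c(2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 1L))),  # MAF 0.05
        min_call = 0.95, min_maf = 0.05)
    ## the low-call SNP is counted once, at step (i) only; the boundary
    ## MAF = 0.05 SNP survives the inclusive filter
    expect_identical(res$ledger$removed, c(1L, 0L, 0L))
    expect_identical(sum(res$stats$kept), 1L)
})

test_that("Mendelian cleaning blanks the minority party", {
    ## sire S hom-ref; daughters: one opposing hom (conflict), one het (fine)
    d <- cbind(S = c(2L, 2L), d1 = c(0L, 1L), d2 = c(1L, 1L))
    g <- makeGenotypes(d)
    ped <- Pedigree(c("S", "d1", "d2"), c(NA, "S", "S"), c(NA, NA, NA),
                    c(2000L, 2002L, 2002L))
    res <- mendelianClean(g, ped, max_sire_conflict = 0.6)
    expect_true(is.na(dosage(res$genotypes)[1, "d1"]))
    expect_identical(dosage(res$genotypes)[1, "S"], 2L)   # sire kept
    expect_identical(dosage(res$genotypes)[2, "d1"], 1L)  # het untouched

    ## sire against 10 opposing daughters: the sire is blanked instead
    d2 <- cbind(S = 2L, matrix(0L, 1, 10,
                               dimnames = list(NULL, sprintf("k%d", 1:10))))
    g2 <- makeGenotypes(d2)
    ped2 <- Pedigree(c("S", sprintf("k%d", 1:10)),
                     c(NA, rep("S", 10)), rep(NA, 11), 2000L)
    res2 <- mendelianClean(g2, ped2)
    expect_true(is.na(dosage(res2$genotypes)[1, "S"]))
    expect_identical(unname(dosage(res2$genotypes)[1, -1]), rep(0L, 10))
    expect_identical(res2$conflicts$n_conflicts, 10L)
    expect_identical(res2$conflicts$action, "sire_blanked")
})

test_that("sire imputation fills only confident posteriors, deterministically", {
    ## SNP1: sire hom-ref, p(ref) = 0.99 -> posterior 0.99, imputed
    ## SNP2: sire hom-ref, p(ref) = 0.90 -> posterior 0.90, left missing
    ## SNP3: sire het, p = 0.5 -> (0.25, 0.5, 0.25), left missing
    freq_cols <- function(p, n = 100L) {
        k <- round(2 * n * p)
        c(rep(2L, k %/% 2), if (k %% 2) 1L, rep(0L, n))[1:n]
    }
    d <- rbind(c(2L, NA, freq_cols(0.99, 98)),
               c(2L, NA, freq_cols(0.90, 98)),
               c(1L, NA, freq_cols(0.50, 98)))
    colnames(d) <- c("S", "kid", sprintf("x%d", 1:98))
    g <- makeGenotypes(d)
    ped <- Pedigree(c("S", "kid"), c(NA, "S"), c(NA, NA), c(2000L, 2002L))
    p_ref <- markerStats(g)$p_ref
    res <- imputeFromSire(g, ped, accept_prob = 0.95)
    post_snp1 <- (d[1, "S"] / 2) * p_ref[1]
    expect_gte(post_snp1, 0.95)
    expect_identical(dosage(res)[1, "kid"], 2L)
    expect_true(is.na(dosage(res)[2, "kid"]))
    expect_true(is.na(dosage(res)[3, "kid"]))
    ## observed entries are never rewritten
    obs <- !is.na(dosage(g))
    expect_identical(dosage(res)[obs], dosage(g)[obs])
    ## deterministic
    expect_identical(dosage(imputeFromSire(g, ped, accept_prob = 0.95)),
                     dosage(res))
    expect_error(imputeFromSire(g, ped, accept_prob = 0.5), "exceed 0.5")
})

test_that("imputation is calibrated on simulated half-sib data", {
    sim <- tinySim()
    g_true <- sim$hs$genotypes
    g_deg <- degradeGenotypes(g_true, missing_rate = 0.15, error_rate = 0,
                              seed = 9L)
    ## on a MAF-ascertained panel (MAF >= 0.05) no single-locus posterior
    ## can reach 0.95, so the default threshold leaves everything missing
    imp95 <- imputeFromSire(g_deg, sim$hs$pedigree, accept_prob = 0.95)
    expect_identical(sum(is.na(dosage(g_deg)) & !is.na(dosage(imp95))), 0L)
    ## at a threshold the panel can meet, accuracy matches the calibration
    ap <- 0.75
    imp <- imputeFromSire(g_deg, sim$hs$pedigree, accept_prob = ap)
    filled <- is.na(dosage(g_deg)) & !is.na(dosage(imp))
    expect_gt(sum(filled), 20)
    acc <- mean(dosage(imp)[filled] == dosage(g_true)[filled])
    se <- sqrt(ap * (1 - ap) / sum(filled))
    expect_gte(acc, ap - 3 * se)
    ## imputed daughters stay Mendelian-consistent with their sires
    r <- pedigreeTable(sim$hs$pedigree)
    kids <- r$id[!is.na(r$sire) & r$id %in% individuals(imp)]
    for (k in kids) {
        s <- r$sire[r$id == k]
        gs <- dosage(imp)[, s]; gk <- dosage(imp)[, k]
        new_entries <- filled[, k]
        conf <- new_entries & !is.na(gs) & ((gs == 2 & gk == 0) |
                                            (gs == 0 & gk == 2))
        expect_identical(sum(conf, na.rm = TRUE), 0L)
    }
})

test_that("Mendelian conflict rate matches the analytic error expectation", {
    sim <- tinySim()
    g_true <- sim$hs$genotypes
    e <- 0.04
    g_err <- degradeGenotypes(g_true, missing_rate = 0, error_rate = e,
                              seed = 13L)
    res <- mendelianClean(g_err, sim$hs$pedigree, max_sire_conflict = 1)
    observed <- sum(res$conflicts$n_conflicts)
    ## P(observe v | true t) under the uniform-error model
    pobs <- function(v, t) ifelse(v == t, 1 - e, e / 2)
    r <- pedigreeTable(sim$hs$pedigree)
    kids <- r$id[!is.na(r$sire) & r$id %in% individuals(g_true)]
    mu <- 0; v2 <- 0
    for (k in kids) {
        s <- r$sire[r$id == k]
        ts <- dosage(g_true)[, s]; tk <- dosage(g_true)[, k]
        p <- pobs(2, ts) * pobs(0, tk) + pobs(0, ts) * pobs(2, tk)
        mu <- mu + sum(p)
        v2 <- v2 + sum(p * (1 - p))
    }
    expect_lt(abs(observed - mu), 3 * sqrt(v2))
})
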