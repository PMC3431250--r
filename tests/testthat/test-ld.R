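test_that("pairwise D', r2 match hand arithmetic", {
    p <- pairLD(4, 1, 1, 4)
    expect_equal(p$D, 0.15)
    expect_equal(p$Dprime, 0.6)
    expect_equal(p$r2, 0.36)
    perfect <- pairLD(5, 0, 0, 5)
    expect_equal(perfect$Dprime, 1)
    expect_equal(perfect$r2, 1)
    indep <- pairLD(1, 1, 1, 1)
    expect_equal(indep$D, 0)
    expect_equal(indep$Dprime, 0)
    expect_equal(indep$r2, 0)
    mono <- pairLD(5, 0, 5, 0)    # second locus monomorphic
    expect_false(mono$defined)
    expect_true(is.na(mono$r2))
})

test_that("r2 <= D'^2 and allele-relabeling invariance hold under random counts", {
    set.seed(20)
    for (rep in 1:300) {
        cnt <- as.numeric(rmultinom(1, sample(10:200, 1),
                                    prob = runif(4, 0.05, 1)))
        st <- pairLD(cnt[1], cnt[2], cnt[3], cnt[4])
        if (!st$defined) next
        expect_lte(st$r2, st$Dprime^2 + 1e-12)
        ## swap alleles at locus A: (n11,n10,n01,n00) -> (n01,n00,n11,n10)
        sw <- pairLD(cnt[3], cnt[4], cnt[1], cnt[2])
        expect_equal(sw$Dprime, st$Dprime, tolerance = 1e-12)
        expect_equal(sw$r2, st$r2, tolerance = 1e-12)
        expect_equal(abs(sw$D), abs(st$D), tolerance = 1e-12)
        ## swap at locus B
        sb <- pairLD(cnt[2], cnt[1], cnt[4], cnt[3])
        expect_equal(sb$Dprime, st$Dprime, tolerance = 1e-12)
        expect_equal(sb$r2, st$r2, tolerance = 1e-12)
    }
})

test_that("|D'| confidence bounds behave per the Gabriel classification", {
    ci <- dprimeCI(c(50, 25, 2), c(0, 25, 1), c(0, 25, 1), c(50, 25, 2))
    ## complete association: strong-LD bounds
    expect_gte(ci$CU[1], 0.98)
    expect_gte(ci$CL[1], 0.70)
    ## independence at high counts: recombination
    expect_lt(ci$CU[2], 0.90)
    ## tiny table: wide, uninformative interval
    expect_gt(ci$CU[3] - ci$CL[3], 0.5)
    expect_true(all(ci$CL <= ci$CU))
})

test_that("CI bounds bracket the MLE D' for well-populated tables", {
    set.seed(21)
    for (rep in 1:25) {
        cnt <- as.numeric(rmultinom(1, 500, prob = runif(4, 0.25, 1)))
        if (any(cnt < 100)) next
        st <- pairLD(cnt[1], cnt[2], cnt[3], cnt[4])
        ci <- dprimeCI(cnt[1], cnt[2], cnt[3], cnt[4])
        expect_lte(ci$CL, st$Dprime + 1e-9)
        expect_gte(ci$CU, st$Dprime - 1e-9)
    }
})

test_that("decay table places pairs into half-open bins and conserves counts", {
    pairs <- data.frame(dist_bp = c(5e3, 15e3, 15e6, 10000L),
                        Dprime = c(1, 0.5, 0.2, 0.8),
                        r2 = c(1, 0.25, 0.04, 0.64))
    tab <- ldDecayTable(pairs)
    expect_identical(tab$n_pairs[tab$bin == "<10 kb"], 1L)
    ## exactly 10,000 bp belongs to the 10-20 kb bin (half-open edges)
    expect_identical(tab$n_pairs[tab$bin == "10-20 kb"], 2L)
    expect_identical(tab$n_pairs[tab$bin == "10-20 Mb"], 1L)
    expect_identical(sum(tab$n_pairs), nrow(pairs))
    ## per-bin means equal hand-computed values
    expect_equal(tab$mean_r2[tab$bin == "10-20 kb"], mean(c(0.25, 0.64)))
    expect_equal(tab$mean_Dprime[tab$bin == "10-20 kb"], mean(c(0.5, 0.8)))
    expect_identical(tab$bin,
                     c("<10 kb", "10-20 kb", "20-40 kb", "40-60 kb",
                       "60-100 kb", "100-200 kb", "200-500 kb",
                       "500 kb-1 Mb", "1-2 Mb", "2-5 Mb", "5-10 Mb",
                       "10-20 Mb", "20-50 Mb", ">50 Mb"))
})

test_that("half-length of r2 interpolates the first crossing", {
    hl <- halfLengthR2(c(0.4, 0.3, 0.2, 0.1))
    expect_equal(hl$half_value, 0.2)
    expect_equal(hl$distance_Mb, 2.5)
    hl2 <- halfLengthR2(c(0.4, 0.1))
    expect_equal(hl2$distance_Mb, 0.5 + (0.2 - 0.4) / (0.1 - 0.4) * 1)
    expect_error(halfLengthR2(c(0.3, 0.3)), "no decay")
    expect_error(halfLengthR2(c(0.2, 0.4, 0.1)), "first bin")
})

test_that("syntenic LD counts only jointly observed haplotypes", {
    mm <- markerMap(1, c(1e3, 2e3), c("a", "b"))
    H <- rbind(c(1L, 1L), c(1L, 1L), c(0L, 0L), c(0L, 0L),
               c(1L, NA), c(NA, 0L))
    h <- HaplotypeSet(H, sprintf("i%d", 1:6), rep("U", 6), mm)
    pairs <- syntenicLD(h)
    expect_identical(nrow(pairs), 1L)
    expect_identical(pairs$n, 4)          # the two half-missing rows drop out
    expect_equal(pairs$r2, 1)
    expect_identical(pairs$dist_bp, 1000L)
})

test_that("non-syntenic sampling is seeded, sized, and summarized", {
    set.seed(99)
    mm <- markerMap(rep(1:2, each = 100),
                    rep(seq(1e4, 1e6, length.out = 100), 2),
                    sprintf("s%d", 1:200))
    H <- matrix(rbinom(40 * 200, 1, 0.5), nrow = 40)
    storage.mode(H) <- "integer"
    h <- HaplotypeSet(H, sprintf("i%d", rep(1:20, each = 2)),
                      rep(c("P", "M"), 20), mm)
    r1 <- nonsyntenicLD(h, fraction = 0.05, seed = 3)
    ## ceiling(0.05 * 100) = 5 SNPs per chromosome -> 25 cross pairs at most
    expect_lte(r1$summary$n_pairs, 25L)
    expect_gte(r1$summary$n_pairs, 20L)   # a few may be undefined
    r2 <- nonsyntenicLD(h, fraction = 0.05, seed = 3)
    expect_identical(r1$pairs, r2$pairs)
    r3 <- nonsyntenicLD(h, fraction = 0.05, seed = 4)
    expect_false(identical(r1$pairs$snp_i, r3$pairs$snp_i))
    expect_equal(r1$summary$mean_r2, mean(r1$pairs$r2))
})
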