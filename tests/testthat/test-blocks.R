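test_that("pair classification follows the confidence-bound thresholds", {
    expect_identical(classifyPair(0.80, 0.99), "STRONG_LD")
    expect_identical(classifyPair(0.10, 0.85), "RECOMB")
    expect_identical(classifyPair(0.50, 0.95), "UNINFORMATIVE")
    ## boundary behaviour: strict inequalities
    expect_identical(classifyPair(0.70, 0.99), "UNINFORMATIVE")
    expect_identical(classifyPair(0.80, 0.98), "UNINFORMATIVE")
    expect_identical(classifyPair(0.10, 0.90), "UNINFORMATIVE")
})

.blockFixture <- function(class_by_pair, bp) {
    m <- length(bp)
    ids <- sprintf("b%d", seq_len(m))
    mm <- markerMap(rep(1L, m), bp, ids)
    ut <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
    pairs <- data.frame(snp_i = ids[ut[, 1]], snp_j = ids[ut[, 2]],
                        chrom = "1", class = class_by_pair,
                        stringsAsFactors = FALSE)
    list(markers = mm, pairs = pairs)
}

test_that("all-strong triple forms one block; an inner recombinant breaks it", {
    fx <- .blockFixture(rep("STRONG_LD", 3), c(1e3, 2e3, 3e3))
    b <- gabrielBlocks(fx$pairs, fx$markers)
    expect_identical(nrow(b), 1L)
    expect_identical(b$n_snps, 3L)

    ## pair order in the fixture: (1,2), (1,3), (2,3)
    fx2 <- .blockFixture(c("RECOMB", "STRONG_LD", "STRONG_LD"),
                         c(1e3, 2e3, 3e3))
    b2 <- gabrielBlocks(fx2$pairs, fx2$markers)
    ## strong fraction of [1..3] is 2/3 < 0.95: only the 2-SNP block (2,3)
    expect_identical(nrow(b2), 1L)
    expect_identical(c(b2$first, b2$last), c(2L, 3L))
})

test_that("two perfect triples separated by recombinant pairs give two blocks", {
    m <- 10L
    bp <- seq(1e3, 1e4, length.out = m)
    cls <- matrix("RECOMB", m, m)
    for (grp in list(1:3, 8:10))
        cls[grp, grp] <- "STRONG_LD"
    ut <- which(upper.tri(cls), arr.ind = TRUE)
    fx <- .blockFixture(cls[ut], bp)
    b <- gabrielBlocks(fx$pairs, fx$markers)
    expect_identical(nrow(b), 2L)
    expect_identical(b$first, c(1L, 8L))
    expect_identical(b$last, c(3L, 10L))
    ## matches the exhaustive oracle
    o <- gabrielOracle(cls, bp)
    expect_identical(b$first, o$first)
    expect_identical(b$last, o$last)
})

test_that("block calling equals the exhaustive-candidate oracle on random panels", {
    for (seed in 1:25) {
        fx <- randomClassifiedChrom(m = sample(5:20, 1), seed = seed)
        got <- gabrielBlocks(fx$pairs, fx$markers)
        want <- gabrielOracle(fx$class_mat, fx$bp)
        expect_identical(got$first, want$first, info = paste("seed", seed))
        expect_identical(got$last, want$last, info = paste("seed", seed))
    }
})

test_that("blocks never overlap, boundaries are strong, span cap respected", {
    for (seed in 26:35) {
        fx <- randomClassifiedChrom(m = 15, seed = seed)
        b <- gabrielBlocks(fx$pairs, fx$markers)
        if (nrow(b) > 1) {
            ord <- order(b$first)
            expect_true(all(b$first[ord][-1] > b$last[ord][-nrow(b)]))
        }
        for (k in seq_len(nrow(b)))
            expect_identical(fx$class_mat[b$first[k], b$last[k]], "STRONG_LD")
        bc <- gabrielBlocks(fx$pairs, fx$markers, max_span_kb = 100)
        if (nrow(bc)) expect_true(all(bc$span_kb <= 100))
    }
})

test_that("raising the strong fraction shrinks the qualifying-candidate set", {
    ## note: total *blocked length* is not monotone in the fraction --
    ## greedy longest-first selection can trade one long accepted block for
    ## two shorter disjoint ones when the long candidate disqualifies.
    ## The monotone object is the candidate set itself.
    qualifying <- function(cls, bp, min_frac) {
        m <- length(bp)
        out <- character(0)
        for (a in seq_len(m - 1)) for (b in seq(a + 1, m)) {
            if (cls[a, b] != "STRONG_LD") next
            ns <- 0L; ni <- 0L
            for (i in a:(b - 1)) for (j in (i + 1):b) {
                if (cls[i, j] == "STRONG_LD") { ns <- ns + 1L; ni <- ni + 1L }
                else if (cls[i, j] == "RECOMB") ni <- ni + 1L
            }
            if (ni > 0L && ns / ni >= min_frac)
                out <- c(out, paste(a, b))
        }
        out
    }
    for (seed in 36:42) {
        fx <- randomClassifiedChrom(m = 12, seed = seed)
        fr <- c(0.5, 0.8, 0.95, 1)
        sets <- lapply(fr, function(f) qualifying(fx$class_mat, fx$bp, f))
        for (k in seq_along(fr)[-1])
            expect_true(all(sets[[k]] %in% sets[[k - 1]]))
        ## and the greedy caller only ever accepts qualifying candidates
        b <- gabrielBlocks(fx$pairs, fx$markers, min_strong_fraction = 0.95)
        if (nrow(b))
            expect_true(all(paste(b$first, b$last) %in% sets[[3]]))
    }
})

test_that("block summary aggregates spans, SNP fractions and totals", {
    mm <- markerMap(rep(1:2, c(30, 20)),
                    c(seq(1e4, 30e4, 1e4), seq(1e4, 20e4, 1e4)),
                    sprintf("s%d", 1:50))
    blocks <- data.frame(chrom = c("1", "1", "2"),
                         first = c(1L, 10L, 3L), last = c(3L, 15L, 4L),
                         start_bp = c(1e4, 1e5, 3e4),
                         end_bp = c(3e4, 1.5e5, 4e4),
                         n_snps = c(3L, 6L, 2L),
                         span_kb = c(20, 50, 10),
                         snps = c("", "", ""))
    s <- blockSummary(blocks, mm,
                      chrom_lengths = c("1" = 3e5, "2" = 2e5))
    r1 <- s[s$chrom == "1", ]
    expect_identical(r1$n_blocks, 2L)
    expect_equal(r1$total_kb, 70)
    expect_equal(r1$min_kb, 20)
    expect_equal(r1$max_kb, 50)
    expect_equal(r1$pct_length, 100 * 70e3 / 3e5)
    expect_equal(r1$pct_snps, 100 * 9 / 30)
    all_row <- s[s$chrom == "All", ]
    expect_identical(all_row$n_blocks, 3L)
    expect_equal(all_row$total_kb, 80)
    expect_equal(all_row$pct_snps, 100 * 11 / 50)
    ## summing per-chromosome counts reproduces the genome total
    expect_identical(sum(s$n_blocks[s$chrom != "All"]), all_row$n_blocks)
    expect_warning(blockSummary(blocks, mm), "lengths")
})
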