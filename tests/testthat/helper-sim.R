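## Simulations are expensive; build each condition once per test run and
## share it across test files.
.simCache <- new.env(parent = emptyenv())

cachedSim <- function(key, maker) {
    got <- .simCache[[key]]
    if (is.null(got)) {
        got <- maker()
        .simCache[[key]] <- got
    }
    got
}

## small population, quick: exercises QC / phasing / imputation logic
tinyCfg <- function(seed = 5L) simConfig(
    ne_trajectory = data.frame(generation = c(1L, 10L), N = c(30L, 30L)),
    n_chromosomes = 2L, snps_per_chromosome = 200L,
    chromosome_length_cM = 100,
    n_sires = 3L, daughters_per_sire = 8L,
    missing_rate = 0.05, genotype_error_rate = 0.01, seed = seed)

tinySim <- function() cachedSim("tiny", function() {
    cfg <- tinyCfg()
    truth <- simulatePopulation(cfg)
    hs <- sampleHalfSib(truth, cfg)
    list(cfg = cfg, truth = truth, hs = hs)
})

## constant-size population for drift-recombination (Sved) recovery: the
## denser SNP panel keeps enough segregating sites after the 4N burn-in
## that 1000-pair bins cover T in [5, 50]
neConstCfg <- function(seed = 101L) simConfig(
    ne_trajectory = data.frame(generation = c(1L, 100L), N = c(100L, 100L)),
    n_chromosomes = 4L, snps_per_chromosome = 2000L,
    chromosome_length_cM = 100,
    n_sires = 4L, daughters_per_sire = 15L,
    missing_rate = 0, genotype_error_rate = 0, seed = seed)

neConstSim <- function() cachedSim("ne_const", function() {
    cfg <- neConstCfg()
    truth <- simulatePopulation(cfg)
    ## chromosomes of a genotyped cohort: fresh gametes, so the 1/n
    ## correction of the Sved relationship matches the sampling model
    hap <- sampleGametes(truth, 100L, min_maf = 0.05, seed = cfg$seed)
    pairs <- syntenicLD(hap)
    list(cfg = cfg, truth = truth, hap = hap, pairs = pairs)
})

## declining history: a recent 10-generation contraction (the selection-
## scheme story).  LD relaxes toward a new equilibrium at rate about
## 2c + 1/(2N) per generation, so at desk-scale N an old, gradual decline
## is already forgotten at every usable c; a recent sharp contraction is
## the identifiable desk-scale analogue (recent bins re-equilibrate fast,
## distant bins still remember the larger ancestral size).
neDeclineCfg <- function(seed = 202L) simConfig(
    ne_trajectory = data.frame(generation = c(1L, 111L, 120L),
                               N = c(120L, 30L, 30L)),
    n_chromosomes = 4L, snps_per_chromosome = 2000L,
    chromosome_length_cM = 100,
    n_sires = 4L, daughters_per_sire = 10L,
    missing_rate = 0, genotype_error_rate = 0, seed = seed)

neDeclineSim <- function() cachedSim("ne_decline", function() {
    cfg <- neDeclineCfg()
    truth <- simulatePopulation(cfg)
    hap <- sampleGametes(truth, 60L, min_maf = 0.05, seed = cfg$seed)
    pairs <- syntenicLD(hap)
    list(cfg = cfg, truth = truth, hap = hap, pairs = pairs)
})

## one shared end-to-end pipeline run (desk-scale defaults, seed 7)
pipelineRun <- function() cachedSim("pipeline", function() {
    out <- file.path(tempdir(), "ldstructure_pipeline_out")
    res <- runPipeline(list(seed = 7), out_dir = out)
    list(out = out, res = res)
})

## true diploid N at T generations before sampling, from the realized
## trajectory (burn-in included ancestrally)
trueNAt <- function(truth, T) {
    ne <- neByGeneration(truth)
    last <- max(ne$generation)
    idx <- pmax(1L, pmin(last, last - round(T) + 1L))
    ne$N[idx]
}
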