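.parseConfigFile <- function(path) {
    lines <- readLines(path)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    kv <- strsplit(lines, "=", fixed = TRUE)
    bad <- lengths(kv) != 2L
    if (any(bad)) stop("malformed config line: ", lines[bad][1])
    vals <- lapply(kv, function(x) {
        v <- trimws(x[2])
        if (toupper(v) %in% c("TRUE", "FALSE")) return(as.logical(v))
        num <- suppressWarnings(as.numeric(v))
        if (!is.na(num)) num else v
    })
    names(vals) <- trimws(vapply(kv, `[`, "", 1))
    vals
}

.defaultPipelineConfig <- function() {
    list(simulate = TRUE,
         ## QC thresholds
         max_missing = 0.10, min_call = 0.95, min_maf = 0.05,
         hwe_alpha = 1e-5, mendel_sire_fraction = 0.05,
         impute_iterations = 10, accept_prob = 0.95,
         ## blocks
         min_strong_fraction = 0.95, cu_strong = 0.98, cl_strong = 0.70,
         cu_recomb = 0.90, grid_step = 0.001,
         ## Ne
         conversion_mode = "uniform1", genome_rate = 1, bin_size = 1000,
         generation_interval = 4,
         ## background LD
         nonsyntenic_fraction = 0.05,
         seed = 1)
}

.writeTSV <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

#' Run the full genome-structure pipeline
#'
#' Chains the analysis stages: genotype intake (from PLINK-style files or
#' the built-in simulator), two-stage QC with Mendelian cleaning and
#' sire/frequency imputation, haplotype intake (supplied/true phase where
#' available, rule-based deduction otherwise) with sire-balanced
#' selection, pairwise LD with confidence bounds, LD-decay and
#' per-chromosome summaries, Gabriel block calling, the LD-based
#' effective-population-size trajectory, and pedigree plus marker
#' inbreeding with the birth-year trend.  Every output table is written as
#' TSV into \code{out_dir} together with a QC ledger (TSV and JSON) and a
#' structured JSON log of every threshold and seed used.  Reruns with the
#' same configuration and seed produce byte-identical outputs.
#'
#' @param config a named list, or the path of a plain-text
#'   \code{key = value} file, overriding the defaults: QC thresholds
#'   (\code{max_missing} 0.10, \code{min_call} 0.95, \code{min_maf} 0.05,
#'   \code{hwe_alpha} 1e-5), Mendelian/imputation settings, Gabriel bounds
#'   (0.98/0.70/0.90, \code{min_strong_fraction} 0.95, optional
#'   \code{max_span_kb}), Ne settings (\code{conversion_mode},
#'   \code{genome_rate}, \code{bin_size} 1000, \code{generation_interval}
#'   4 years), \code{nonsyntenic_fraction} 0.05 and \code{seed}.  With
#'   \code{simulate = TRUE} (default) the simulator supplies the data;
#'   otherwise \code{ped_path}/\code{map_path}/\code{pedigree_path} (and
#'   optionally \code{haplotype_path}) name the inputs.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with every stage table and the log.
#' @export
runPipeline <- function(config = list(), out_dir = "ldstructure_out") {
    if (is.character(config) && length(config) == 1L)
        config <- .parseConfigFile(config)
    cfg <- utils::modifyList(.defaultPipelineConfig(), config)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ledger <- NULL
    log <- list(config = cfg[order(names(cfg))])
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e) {
            if (!is.null(ledger))
                writeQCLedger(ledger, file.path(out_dir, "qc_ledger.tsv"),
                              file.path(out_dir, "qc_ledger.json"))
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE)
        })
    }

    ## ---- intake ----
    truth_hap <- NULL
    intake <- stage("input", {
        if (isTRUE(cfg$simulate)) {
            sim_cfg <- simConfig(seed = as.integer(cfg$seed))
            truth <- simulatePopulation(sim_cfg)
            hs <- sampleHalfSib(truth, sim_cfg)
            g <- degradeGenotypes(hs$genotypes, sim_cfg$missing_rate,
                                  sim_cfg$genotype_error_rate,
                                  seed = sim_cfg$seed + 2L)
            list(g = g, ped = hs$pedigree, hap = hs$haplotypes)
        } else {
            g <- readGenotypes(cfg$ped_path, cfg$map_path)
            ped <- readPedigree(cfg$pedigree_path)
            hap <- if (!is.null(cfg$haplotype_path))
                readHaplotypes(cfg$haplotype_path, markers(g)) else NULL
            list(g = g, ped = ped, hap = hap)
        }
    })
    g <- intake$g; ped <- intake$ped; truth_hap <- intake$hap

    ## ---- QC ----
    qc <- stage("qc", {
        ind <- filterIndividuals(g, max_missing = cfg$max_missing)
        mk <- markerQC(ind$genotypes, min_call = cfg$min_call,
                       min_maf = cfg$min_maf, hwe_alpha = cfg$hwe_alpha)
        md <- mendelianClean(mk$genotypes, ped,
                             max_sire_conflict = cfg$mendel_sire_fraction)
        gq <- imputeFromSire(md$genotypes, ped,
                             iterations = as.integer(cfg$impute_iterations),
                             accept_prob = cfg$accept_prob)
        list(g = gq, ledger = rbind(ind$ledger, mk$ledger),
             conflicts = md$conflicts, stats = mk$stats)
    })
    ledger <- qc$ledger
    ## ledger self-check: remaining_k = remaining_{k-1} - removed_k per unit
    for (u in unique(ledger$unit)) {
        sub <- ledger[ledger$unit == u, ]
        if (nrow(sub) > 1 &&
            !all(diff(sub$remaining) == -sub$removed[-1]))
            stop("ledger arithmetic check failed for unit ", u)
    }
    g <- qc$g

    ## ---- haplotypes ----
    hap <- stage("haplotypes", {
        h <- if (!is.null(truth_hap)) {
            keep <- match(names(markers(g)), names(markers(truth_hap)))
            HaplotypeSet(haplotypes(truth_hap)[, keep, drop = FALSE],
                         carriers(truth_hap), origins(truth_hap),
                         markers(g))
        } else deduceHaplotypes(g, ped)
        selectIndependentHaplotypes(h, ped)
    })

    ## ---- LD ----
    ld <- stage("ld", {
        pairs <- syntenicLD(hap, with_ci = TRUE,
                            grid_step = cfg$grid_step,
                            max_dist_bp = if (!is.null(cfg$max_pair_dist_bp))
                                cfg$max_pair_dist_bp else NULL)
        ns <- nonsyntenicLD(hap, fraction = cfg$nonsyntenic_fraction,
                            seed = as.integer(cfg$seed))
        list(pairs = pairs, nonsyntenic = ns)
    })
    pairs <- ld$pairs

    decay <- stage("ld_decay", {
        tab <- ldDecayTable(pairs)
        ns <- ld$nonsyntenic$summary
        rbind(tab, data.frame(
            bin = "Non-syntenic", n_pairs = ns$n_pairs,
            mean_Dprime = ns$mean_Dprime, sd_Dprime = ns$sd_Dprime,
            min_Dprime = ns$min_Dprime, max_Dprime = ns$max_Dprime,
            mean_r2 = ns$mean_r2, sd_r2 = ns$sd_r2,
            min_r2 = ns$min_r2, max_r2 = ns$max_r2))
    })

    table1 <- stage("per_chromosome", {
        st <- markerStats(g)
        chroms <- unique(st$chrom)
        rows <- lapply(chroms, function(ch) {
            s <- st[st$chrom == ch, ]
            pc <- pairs[pairs$chrom == ch, ]
            near <- pc[pc$dist_bp < 1e5, ]
            data.frame(chrom = ch, n_snp = nrow(s),
                       mean_spacing_kb = if (nrow(s) > 1)
                           mean(diff(sort(s$pos_bp))) / 1000 else NA_real_,
                       mean_maf = mean(s$maf, na.rm = TRUE),
                       mean_het = mean(s$het_obs, na.rm = TRUE),
                       mean_Dprime = mean(pc$Dprime),
                       mean_r2 = mean(pc$r2),
                       mean_r2_lt100kb = if (nrow(near)) mean(near$r2)
                                         else NA_real_)
        })
        do.call(rbind, c(rows, make.row.names = FALSE))
    })

    half <- tryCatch({
        bins1mb <- r2ByMbBin(pairs)
        halfLengthR2(bins1mb$mean_r2, bins1mb$mid_Mb)
    }, error = function(e) list(half_value = NA_real_,
                                distance_Mb = NA_real_))

    ## ---- blocks ----
    blocks <- stage("blocks", {
        gabrielBlocks(pairs, markers(g),
                      min_strong_fraction = cfg$min_strong_fraction,
                      max_span_kb = cfg$max_span_kb,
                      cu_strong = cfg$cu_strong, cl_strong = cfg$cl_strong,
                      cu_recomb = cfg$cu_recomb)
    })
    bsum <- stage("block_summary", {
        mm <- markers(g)
        lens <- tapply(GenomicRanges::start(mm),
                       as.character(seqnames(mm)), max)
        blockSummary(blocks, mm, chrom_lengths = lens)
    })

    ## ---- Ne ----
    ne <- stage("ne", {
        gmap <- switch(cfg$conversion_mode,
            uniform1 = geneticMap("uniform1"),
            genome_avg = geneticMap("genome_avg",
                                    genomeRate = cfg$genome_rate),
            per_chrom = geneticMap("per_chrom",
                                   chromRates = unlist(cfg$chrom_rates)),
            stop("unknown conversion_mode ", cfg$conversion_mode))
        tr <- neTrajectory(addGeneticDistance(pairs, gmap),
                           n = nHaplotypes(hap),
                           bin_size = as.integer(cfg$bin_size))
        est <- tr$estimates
        est$years_ago <- est$T_requested * cfg$generation_interval
        est$mode <- cfg$conversion_mode
        list(bins = tr$bins, estimates = est)
    })

    ## ---- inbreeding ----
    inb <- stage("inbreeding", {
        fp <- fPedigree(ped)
        fm <- fMarkers(g)
        r <- pedigreeTable(ped)
        rec <- data.frame(id = fm$id,
                          birth_year = r$birth_year[match(fm$id, r$id)],
                          F_PED = unname(fp[fm$id]),
                          F1 = fm$F1, F2 = fm$F2, F3 = fm$F3)
        list(records = rec, trend = inbreedingTrend(rec))
    })

    ## ---- outputs ----
    stage("report", {
        .writeTSV(table1, file.path(out_dir, "per_chromosome.tsv"))
        .writeTSV(decay, file.path(out_dir, "ld_decay.tsv"))
        .writeTSV(pairs, file.path(out_dir, "ld_pairs.tsv"))
        .writeTSV(blocks, file.path(out_dir, "blocks.tsv"))
        .writeTSV(bsum, file.path(out_dir, "block_summary.tsv"))
        .writeTSV(ne$estimates, file.path(out_dir, "ne_trajectory.tsv"))
        .writeTSV(inb$records, file.path(out_dir, "inbreeding.tsv"))
        .writeTSV(inb$trend, file.path(out_dir, "inbreeding_trend.tsv"))
        .writeTSV(qc$conflicts, file.path(out_dir, "mendel_conflicts.tsv"))
        writeQCLedger(ledger, file.path(out_dir, "qc_ledger.tsv"),
                      file.path(out_dir, "qc_ledger.json"))
        log$n_haplotypes <- nHaplotypes(hap)
        log$n_syntenic_pairs <- nrow(pairs)
        log$half_length <- half
        jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
    invisible(list(genotypes = g, haplotypes = hap, ledger = ledger,
                   table1 = table1, decay = decay, pairs = pairs,
                   blocks = blocks, block_summary = bsum, ne = ne,
                   inbreeding = inb, half_length = half, log = log))
}
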