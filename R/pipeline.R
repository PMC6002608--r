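#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or an already-parsed list and checks the whole
#' document at once, reporting every violation (including unknown keys,
#' which guard against silent typos) in a single error.
#'
#' Recognized keys: `seed` (integer), `index` (path to a library TSV; when
#' absent the default screen design is generated from the seed), `sim`
#' (any [screenSimConfig()] argument except `library`/`seed`), `analysis`
#' (`contrast`, `fdr`, `q`, `n_perm`, `metric`), `emit_fastq` (logical:
#' route the simulated counts through FASTQ emission and re-counting),
#' `log_level` (`"info"` or `"quiet"`).
#'
#' @param config list or YAML path.
#' @return Validated config list with defaults filled in.
#' @export
validateScreenConfig <- function(config) {
    if (is.character(config)) {
        if (!file.exists(config))
            stop("config file not found: ", config)
        config <- yaml::read_yaml(config)
    }
    if (!is.list(config)) stop("config must be a list or a YAML file path")
    errs <- character()
    known <- c("seed", "index", "sim", "analysis", "emit_fastq", "log_level")
    unknown <- setdiff(names(config), known)
    if (length(unknown))
        errs <- c(errs, paste0("unknown key(s): ",
                               paste(unknown, collapse = ", ")))
    seed <- config$seed
    if (is.null(seed)) seed <- 1L
    if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed))
        errs <- c(errs, "seed: must be a single integer")
    if (!is.null(config$index) && !is.character(config$index))
        errs <- c(errs, "index: must be a file path")
    if (!is.null(config$index) && is.character(config$index) &&
        !file.exists(config$index))
        errs <- c(errs, paste0("index: file not found: ", config$index))
    sim <- config$sim
    if (is.null(sim)) sim <- list()
    simKnown <- c("moi", "coverage", "n_replicates", "sort_depth",
                  "baseline_phago_prob", "effect_map", "editing_efficiency",
                  "essential_dropout", "pcr_dispersion", "read_depth",
                  "library_skew_sd", "include_initial", "allow_expansion")
    simUnknown <- setdiff(names(sim), simKnown)
    if (length(simUnknown))
        errs <- c(errs, paste0("sim: unknown key(s): ",
                               paste(simUnknown, collapse = ", ")))
    chkNum <- function(block, nm, lo, hi, what) {
        v <- block[[nm]]
        if (is.null(v)) return(character())
        if (!is.numeric(v) || length(v) != 1L || is.na(v) ||
            v < lo || v > hi)
            sprintf("%s: must be %s", nm, what)
        else character()
    }
    errs <- c(errs,
              chkNum(sim, "moi", 1e-12, Inf, "a positive number"),
              chkNum(sim, "coverage", 1e-12, Inf, "a positive number"),
              chkNum(sim, "n_replicates", 1, Inf, "an integer >= 1"),
              chkNum(sim, "sort_depth", 1, Inf, "a count >= 1"),
              chkNum(sim, "baseline_phago_prob", 0, 1, "a probability in [0, 1]"),
              chkNum(sim, "editing_efficiency", 0, 1, "a probability in [0, 1]"),
              chkNum(sim, "essential_dropout", 0, 1, "a probability in [0, 1]"),
              chkNum(sim, "pcr_dispersion", 0, Inf, "a non-negative number"),
              chkNum(sim, "read_depth", 1e-12, Inf, "a positive number"),
              chkNum(sim, "library_skew_sd", 0, Inf, "a non-negative number"))
    if (!is.null(sim$effect_map) &&
        (!is.numeric(unlist(sim$effect_map)) ||
         is.null(names(unlist(sim$effect_map))) ||
         any(unlist(sim$effect_map) < 0)))
        errs <- c(errs, "effect_map: must map gene names to multipliers >= 0")
    ana <- config$analysis
    if (is.null(ana)) ana <- list()
    anaKnown <- c("contrast", "fdr", "q", "n_perm", "metric")
    anaUnknown <- setdiff(names(ana), anaKnown)
    if (length(anaUnknown))
        errs <- c(errs, paste0("analysis: unknown key(s): ",
                               paste(anaUnknown, collapse = ", ")))
    errs <- c(errs,
              chkNum(ana, "fdr", 0, 1, "a probability in [0, 1]"),
              chkNum(ana, "q", 0, Inf, "a non-negative exponent"),
              chkNum(ana, "n_perm", 100, Inf, "an integer >= 100"))
    if (!is.null(ana$contrast) &&
        (!is.character(ana$contrast) || length(ana$contrast) != 2L))
        errs <- c(errs, "contrast: must name exactly two populations")
    if (!is.null(ana$metric) &&
        !ana$metric %in% c("signed_padj", "padj_only"))
        errs <- c(errs, "metric: must be 'signed_padj' or 'padj_only'")
    if (!is.null(config$emit_fastq) && !is.logical(config$emit_fastq))
        errs <- c(errs, "emit_fastq: must be TRUE or FALSE")
    if (!is.null(config$log_level) &&
        !config$log_level %in% c("info", "quiet"))
        errs <- c(errs, "log_level: must be 'info' or 'quiet'")
    if (length(errs))
        stop("invalid configuration:\n  - ",
             paste(errs, collapse = "\n  - "), call. = FALSE)
    defaults <- list(
        seed = as.integer(seed), index = config$index,
        sim = utils::modifyList(
            list(moi = 0.25, coverage = 1000, n_replicates = 3L,
                 sort_depth = 3e6, baseline_phago_prob = 0.4,
                 effect_map = list(), editing_efficiency = 0.8,
                 essential_dropout = 0.2, pcr_dispersion = 0.05,
                 read_depth = 500, library_skew_sd = 0.3,
                 include_initial = FALSE, allow_expansion = TRUE), sim),
        analysis = utils::modifyList(
            list(contrast = c("PhagoLate", "PhagoNeg"), fdr = 0.05,
                 q = 1, n_perm = 10000L, metric = "signed_padj"), ana),
        emit_fastq = isTRUE(config$emit_fastq),
        log_level = if (is.null(config$log_level)) "info" else config$log_level)
    defaults
}

#' Run the full screen pipeline
#'
#' Simulate (or count from emitted FASTQ), test per-sgRNA differential
#' abundance, and aggregate to genes, writing every stage's table plus a
#' machine-readable run manifest into one immutable output directory.
#' Re-running an identical configuration reproduces byte-identical TSVs;
#' an existing non-empty output directory is refused.
#'
#' @param config list or YAML path accepted by [validateScreenConfig()].
#' @param outdir output directory (must not already contain a run).
#' @return Invisibly, a list with `counts`, `stats`, `geneResults`,
#'   `manifest`, `outdir`.
#' @export
runScreenPipeline <- function(config, outdir) {
    config <- validateScreenConfig(config)
    if (dir.exists(outdir) && length(list.files(outdir)))
        stop("output directory ", outdir,
             " already contains a run; refusing to overwrite")
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    logPath <- file.path(outdir, "run.log")
    quiet <- identical(config$log_level, "quiet")
    say <- function(...) {
        msg <- paste0(...)
        cat(msg, "\n", file = logPath, append = TRUE, sep = "")
        if (!quiet) message(msg)
    }
    stage <- function(name, expr) {
        say("[", name, "] start")
        out <- tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
        say("[", name, "] done")
        out
    }

    lib <- stage("index", {
        if (is.null(config$index))
            defaultScreenLibrary(seed = config$seed)
        else readGuideLibrary(config$index)
    })
    say("[index] ", length(lib), " sgRNAs")

    sim <- config$sim
    effectMap <- unlist(sim$effect_map)
    if (is.null(effectMap)) effectMap <- numeric(0L)
    simConfig <- screenSimConfig(
        lib, effectMap = effectMap, moi = sim$moi, coverage = sim$coverage,
        nReplicates = sim$n_replicates, sortDepth = sim$sort_depth,
        baselinePhagoProb = sim$baseline_phago_prob,
        editingEfficiency = sim$editing_efficiency,
        essentialDropout = sim$essential_dropout,
        pcrDispersion = sim$pcr_dispersion, readDepth = sim$read_depth,
        librarySkewSd = sim$library_skew_sd,
        includeInitial = sim$include_initial,
        allowExpansion = sim$allow_expansion,
        seed = deriveSeed(config$seed, 11L))
    counts <- stage("simulate", simulateScreen(simConfig))
    say("[simulate] ", nrow(counts), " sgRNAs x ", ncol(counts), " samples")

    report <- NULL
    if (config$emit_fastq) {
        counted <- stage("count", {
            fqDir <- file.path(outdir, "fastq")
            paths <- emitFastq(counts, dir = fqDir,
                               seed = deriveSeed(config$seed, 13L))
            countReads(paths, lib)
        })
        report <- counted$report
        S4Vectors::metadata(counted$counts)$truth <- screenTruth(counts)
        counts <- counted$counts
        say("[count] assignment rate ",
            sprintf("%.4f", mean(report$assignment_rate)))
    }

    stats <- stage("test", guideWaldTest(counts,
                                         contrast = config$analysis$contrast))
    say("[test] ", sum(stats$p_adj < config$analysis$fdr, na.rm = TRUE),
        " sgRNAs at p_adj < ", config$analysis$fdr)

    geneResults <- stage("aggregate", aggregateGenes(
        stats, lib, q = config$analysis$q,
        nPerm = as.integer(config$analysis$n_perm),
        seed = deriveSeed(config$seed, 17L),
        sigLevel = config$analysis$fdr,
        metric = config$analysis$metric))
    say("[aggregate] ", nrow(geneResults), " genes, ",
        sum(geneResults$p_adj < config$analysis$fdr),
        " at p_adj < ", config$analysis$fdr)

    writeTsv <- function(df, name) {
        path <- file.path(outdir, name)
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        path
    }
    countsDf <- data.frame(sgrna_id = rownames(counts),
                           as.data.frame(assay(counts, "counts")),
                           check.names = FALSE)
    files <- c(counts = writeTsv(countsDf, "counts.tsv"),
               stats = writeTsv(stats, "sgrna_stats.tsv"),
               genes = writeTsv(geneResults, "gene_results.tsv"))
    if (!is.null(report))
        files["counting_report"] <- writeTsv(report, "counting_report.tsv")

    manifest <- list(
        config = config,
        config_hash = hashConfig(config),
        seed = config$seed,
        n_sgrnas = nrow(counts), n_samples = ncol(counts),
        n_genes = nrow(geneResults),
        outputs = lapply(stats::setNames(as.list(unname(files)), names(files)),
                         function(f) list(file = basename(f),
                                          md5 = unname(tools::md5sum(f)))))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    say("[done] run written to ", outdir)
    invisible(list(counts = counts, stats = stats,
                   geneResults = geneResults, manifest = manifest,
                   outdir = outdir))
}

# stable hash of the canonicalized config document
hashConfig <- function(config) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    unname(tools::md5sum(tmp))
}
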