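#' Configure the generative screen model
#'
#' Builds a validated [ScreenSimConfig-class]. Defaults are the emulated
#' screen's conditions: MOI 0.25, 1000x coverage, three replicates, 3e6
#' cells sorted per population, a 0.4 baseline probability that a wild-type
#' cell sorts PhagoLate, 80% editing efficiency, relative fitness 0.2 for
#' essential-gene knockouts, negative-binomial read overdispersion 0.05 and
#' 500 reads per sgRNA. `sortDepth` and `coverage` are scaled down for
#' desk-size runs via the arguments.
#'
#' @param library a [GuideLibrary-class].
#' @param effectMap named numeric, gene -> multiplier on the PhagoLate
#'   probability (1 = no effect, < 1 = depleted from PhagoLate).
#' @param moi,coverage,nReplicates,sortDepth,baselinePhagoProb
#'   screen-design parameters (see above).
#' @param editingEfficiency probability an integrated sgRNA yields knockout.
#' @param essentialDropout relative pre-sort fitness of essential knockouts.
#' @param pcrDispersion,readDepth read-count model parameters.
#' @param librarySkewSd sd of the log-normal plasmid-library skew.
#' @param includeInitial also simulate the unsorted pre-sort sample.
#' @param allowExpansion model post-selection expansion so that `sortDepth`
#'   may exceed the simulated cell pool (the protocol expands cells for 7
#'   days before sorting); with `FALSE`, oversampling is an error.
#' @param seed integer seed making the simulation reproducible.
#' @return A [ScreenSimConfig-class].
#' @export
screenSimConfig <- function(library, effectMap = numeric(0), moi = 0.25,
                            coverage = 1000, nReplicates = 3L,
                            sortDepth = 3e6, baselinePhagoProb = 0.4,
                            editingEfficiency = 0.8, essentialDropout = 0.2,
                            pcrDispersion = 0.05, readDepth = 500,
                            librarySkewSd = 0.3, includeInitial = FALSE,
                            allowExpansion = TRUE, seed = 1L) {
    new("ScreenSimConfig", library = library,
        effectMap = effectMap, moi = moi, coverage = coverage,
        nReplicates = as.integer(nReplicates), sortDepth = sortDepth,
        baselinePhagoProb = baselinePhagoProb,
        editingEfficiency = editingEfficiency,
        essentialDropout = essentialDropout,
        pcrDispersion = pcrDispersion, readDepth = readDepth,
        librarySkewSd = librarySkewSd, includeInitial = includeInitial,
        allowExpansion = allowExpansion, seed = as.integer(seed))
}

#' Simulate a FACS-sorted CRISPR knockout screen
#'
#' Runs the generative chain per replicate: (i) a log-normal plasmid-library
#' skew shared across replicates; (ii) Poisson-MOI infection under the
#' single-integration assumption, assigning transduced cells to sgRNAs
#' multinomially; (iii) thinning of edited essential-gene cells by their
#' relative fitness; (iv) per-cell PhagoLate assignment with probability
#' `baselinePhagoProb * effectMap[gene]` for edited cells (baseline
#' otherwise), followed by a multinomial sort of `sortDepth` cells per
#' population; (v) negative-binomial read counts with mean proportional to
#' each sgRNA's sorted-cell share.
#'
#' @param config a [ScreenSimConfig-class].
#' @return A [ScreenCounts-class]; `screenTruth(x)` returns the generative
#'   [ScreenTruth-class] (per-gene multipliers, expected per-population
#'   sgRNA shares, planted hits).
#' @examples
#' lib <- defaultScreenLibrary(seed = 1, nSlcGenes = 10, nEssentialGenes = 2,
#'                             nNonTargeting = 6)
#' cfg <- screenSimConfig(lib, coverage = 50, sortDepth = 2e4, readDepth = 50)
#' sc <- simulateScreen(cfg)
#' head(SummarizedExperiment::assay(sc))
#' @export
simulateScreen <- function(config) {
    stopifnot(is(config, "ScreenSimConfig"))
    validObject(config)
    lib <- config@library
    rec <- guides(lib)
    G <- length(lib)
    genes <- rec$gene
    mult <- rep(1, G)
    known <- names(config@effectMap) %in% genes
    if (any(!known))
        warning("effectMap genes absent from library: ",
                paste(names(config@effectMap)[!known], collapse = ", "))
    hit <- match(genes, names(config@effectMap))
    mult[!is.na(hit)] <- config@effectMap[hit[!is.na(hit)]]
    pEdited <- config@baselinePhagoProb * mult
    if (any(pEdited > 1))
        stop("effect multiplier drives PhagoLate probability above 1 for gene(s): ",
             paste(unique(genes[pEdited > 1]), collapse = ", "))
    isEss <- rec$category == "EssentialControl"

    state <- localSeed(config@seed)
    on.exit(restoreSeed(state))

    # (i) plasmid-library skew: one draw, shared by replicates
    skew <- stats::rlnorm(G, meanlog = 0, sdlog = config@librarySkewSd)
    w <- skew / sum(skew)

    pops <- c("PhagoLate", "PhagoNeg")
    if (config@includeInitial) pops <- c(pops, "Initial")
    samples <- expand.grid(replicate = seq_len(config@nReplicates),
                           population = pops, stringsAsFactors = FALSE)
    samples <- samples[order(samples$replicate), , drop = FALSE]
    sampleIds <- sprintf("rep%d_%s", samples$replicate, samples$population)
    counts <- matrix(0L, nrow = G, ncol = nrow(samples),
                     dimnames = list(rec$sgrna_id, sampleIds))
    totalReads <- config@readDepth * G
    pInfect <- 1 - exp(-config@moi)

    for (r in seq_len(config@nReplicates)) {
        # (ii) infection at MOI, single integration per transduced cell
        nExposed <- round(config@coverage * G / pInfect)
        nInfected <- stats::rbinom(1L, nExposed, pInfect)
        nCells <- as.vector(stats::rmultinom(1L, nInfected, w))
        # editing outcome
        nEdited <- stats::rbinom(G, nCells, config@editingEfficiency)
        nUnedited <- nCells - nEdited
        # (iii) essential knockouts are depleted before sorting
        nEdited[isEss] <- stats::rbinom(sum(isEss), nEdited[isEss],
                                        config@essentialDropout)
        nSurviving <- nEdited + nUnedited
        if (config@includeInitial) {
            j <- match(sprintf("rep%d_Initial", r), sampleIds)
            share0 <- nSurviving / sum(nSurviving)
            counts[, j] <- nbReads(share0 * totalReads, config@pcrDispersion)
        }
        # (iv) phenotype and sort
        nLate <- stats::rbinom(G, nEdited, pEdited) +
            stats::rbinom(G, nUnedited, config@baselinePhagoProb)
        nNeg <- nSurviving - nLate
        for (pop in c("PhagoLate", "PhagoNeg")) {
            pool <- if (pop == "PhagoLate") nLate else nNeg
            poolTotal <- sum(pool)
            if (poolTotal == 0)
                stop("simulated ", pop, " pool is empty in replicate ", r)
            if (!config@allowExpansion && config@sortDepth > poolTotal)
                stop("sortDepth (", config@sortDepth, ") exceeds the ",
                     poolTotal, " simulated ", pop, " cells of replicate ",
                     r, "; enable allowExpansion or lower sortDepth")
            sorted <- as.vector(stats::rmultinom(1L, config@sortDepth,
                                                 pool / poolTotal))
            # (v) PCR amplification + sequencing
            mu <- sorted / config@sortDepth * totalReads
            j <- match(sprintf("rep%d_%s", r, pop), sampleIds)
            counts[, j] <- nbReads(mu, config@pcrDispersion)
        }
    }

    truth <- expectedShares(config, mult, isEss, w)
    se <- ScreenCounts(counts, replicate = samples$replicate,
                       population = samples$population, library = lib)
    S4Vectors::metadata(se)$truth <- truth
    S4Vectors::metadata(se)$seed <- config@seed
    se
}

# NB reads with mean mu and dispersion alpha (variance mu + alpha mu^2)
nbReads <- function(mu, alpha) {
    mu <- pmax(mu, 0)
    if (alpha <= 0) return(stats::rpois(length(mu), mu))
    stats::rnbinom(length(mu), mu = mu, size = 1 / alpha)
}

# analytic expected per-sgRNA abundance shares per population
expectedShares <- function(config, mult, isEss, w) {
    e <- config@editingEfficiency
    d <- config@essentialDropout
    b <- config@baselinePhagoProb
    surv <- ifelse(isEss, (1 - e) + e * d, 1)
    editedFrac <- ifelse(isEss, e * d / pmax(surv, 1e-300), e)
    pLate <- editedFrac * b * mult + (1 - editedFrac) * b
    relLate <- w * surv * pLate
    relNeg <- w * surv * (1 - pLate)
    mat <- cbind(PhagoLate = relLate / sum(relLate),
                 PhagoNeg = relNeg / sum(relNeg))
    rownames(mat) <- guides(config@library)$sgrna_id
    effects <- tapply(mult, guides(config@library)$gene, function(x) x[1L])
    effects <- stats::setNames(as.numeric(effects), names(effects))
    new("ScreenTruth", effects = effects, guideExpected = mat,
        hits = names(effects)[effects != 1])
}

#' Construct a ScreenCounts container
#'
#' @param counts integer matrix, sgRNAs x samples; needs dimnames.
#' @param replicate,population per-sample metadata vectors.
#' @param library optional [GuideLibrary-class] supplying rowData.
#' @return A [ScreenCounts-class].
#' @export
ScreenCounts <- function(counts, replicate, population, library = NULL) {
    storage.mode(counts) <- "integer"
    cd <- S4Vectors::DataFrame(replicate = as.integer(replicate),
                               population = as.character(population),
                               row.names = colnames(counts))
    rd <- NULL
    if (!is.null(library)) {
        rd <- guides(library)
        ord <- match(rownames(counts), rd$sgrna_id)
        if (anyNA(ord))
            stop("counts rows absent from library: ",
                 paste(utils::head(rownames(counts)[is.na(ord)], 5L),
                       collapse = ", "))
        rd <- rd[ord, , drop = FALSE]
        rownames(rd) <- rownames(counts)
    }
    se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
    if (!is.null(rd)) rowData(se) <- rd
    new("ScreenCounts", se)
}

#' @describeIn ScreenCounts generative ground truth attached by
#'   [simulateScreen()] (`NULL` for measured data).
#' @param x a [ScreenCounts-class].
#' @export
setMethod("screenTruth", "ScreenCounts", function(x)
    S4Vectors::metadata(x)$truth)

setMethod("show", "ScreenCounts", function(object) {
    callNextMethod()
    tr <- screenTruth(object)
    if (!is.null(tr))
        cat("simulated screen;", length(tr@hits), "planted hit gene(s)\n")
})

#' Emit simulated FASTQ reads for a count matrix
#'
#' Writes one FASTQ file per sample. Before sequencing errors each sgRNA
#' contributes exactly its count in reads, each read being
#' `upstream flank + spacer + downstream flank`; substitution errors are
#' then applied independently per base at `errorRate`. Phred qualities are
#' a constant placeholder (`I`, Q40).
#'
#' @param counts a [ScreenCounts-class] whose rowData carries spacers (as
#'   produced with a library), or an integer matrix plus `library`.
#' @param cassette a [CassetteSpec-class].
#' @param errorRate per-base substitution probability in `[0, 1)`.
#' @param dir output directory (created if needed).
#' @param seed integer seed for error placement and read order.
#' @param library optional [GuideLibrary-class] when `counts` lacks spacers.
#' @return Named character vector of FASTQ paths (names = sample ids).
#' @export
emitFastq <- function(counts, cassette = cassetteSpec(), errorRate = 0,
                      dir = tempfile("fastq"), seed = 1L, library = NULL) {
    stopifnot(is(cassette, "CassetteSpec"))
    if (errorRate < 0 || errorRate >= 1)
        stop("errorRate must be in [0, 1)")
    if (is(counts, "ScreenCounts")) {
        mat <- assay(counts, "counts")
        sp <- rowData(counts)$spacer
    } else {
        mat <- counts
        sp <- NULL
    }
    if (is.null(sp)) {
        if (is.null(library)) stop("a GuideLibrary is needed to supply spacers")
        sp <- unname(spacers(library)[rownames(mat)])
    }
    if (anyNA(sp)) stop("spacers unavailable for some count rows")
    if (any(nchar(sp) != cassette@spacerLength))
        stop("spacer lengths do not match the cassette spacer slot")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    state <- localSeed(seed)
    on.exit(restoreSeed(state))
    templates <- paste0(cassette@upstream, sp, cassette@downstream)
    qual <- strrep("I", nchar(templates[1L]))
    paths <- character(ncol(mat))
    names(paths) <- colnames(mat)
    for (j in seq_len(ncol(mat))) {
        n <- mat[, j]
        reads <- rep(templates, n)
        if (errorRate > 0 && length(reads))
            reads <- mutateReads(reads, errorRate)
        ids <- sprintf("@%s:%d", colnames(mat)[j], seq_along(reads))
        path <- file.path(dir, paste0(colnames(mat)[j], ".fastq"))
        out <- as.vector(rbind(ids, reads, "+", qual))
        writeLines(out, path)
        paths[j] <- path
    }
    paths
}

# independent per-base substitution errors at rate e
mutateReads <- function(reads, e) {
    L <- nchar(reads[1L])
    nErr <- stats::rbinom(length(reads), L, e)
    idx <- which(nErr > 0L)
    if (!length(idx)) return(reads)
    bases <- c("A", "C", "G", "T")
    for (i in idx) {
        chars <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
        pos <- sample.int(L, nErr[i])
        for (p in pos) {
            chars[p] <- sample(setdiff(bases, chars[p]), 1L)
        }
        reads[i] <- paste(chars, collapse = "")
    }
    reads
}

#' Simulate two-channel flow-cytometry events
#'
#' Draws a mixture of three bivariate log-normal clusters on the uptake
#' (YG) and acidification (pHrodo) channels: double-negative (PhagoNeg),
#' YG-only positive (PhagoEarly) and double-positive (PhagoLate). True
#' labels are retained.
#'
#' @param nEvents number of events.
#' @param fractions length-3 numeric `(neg, early, late)` summing to 1.
#' @param channelParams list with per-cluster log-scale medians and a common
#'   `sdlog`; see defaults.
#' @param seed integer seed.
#' @return data.frame with columns `yg`, `phrodo`, `label`.
#' @export
simulateFlowEvents <- function(nEvents, fractions = c(0.4, 0.25, 0.35),
                               channelParams = list(
                                   negMedian = c(yg = 100, phrodo = 80),
                                   earlyMedian = c(yg = 2000, phrodo = 80),
                                   lateMedian = c(yg = 2000, phrodo = 2000),
                                   sdlog = 0.25),
                               seed = 1L) {
    if (length(fractions) != 3L || any(fractions < 0))
        stop("fractions must be three non-negative numbers")
    if (abs(sum(fractions) - 1) > 1e-8)
        stop("fractions must sum to 1")
    state <- localSeed(seed)
    on.exit(restoreSeed(state))
    labels <- sample(c("PhagoNeg", "PhagoEarly", "PhagoLate"), nEvents,
                     replace = TRUE, prob = fractions)
    med <- rbind(PhagoNeg = channelParams$negMedian,
                 PhagoEarly = channelParams$earlyMedian,
                 PhagoLate = channelParams$lateMedian)
    s <- channelParams$sdlog
    yg <- stats::rlnorm(nEvents, log(med[labels, "yg"]), s)
    phrodo <- stats::rlnorm(nEvents, log(med[labels, "phrodo"]), s)
    data.frame(yg = yg, phrodo = phrodo, label = labels,
               stringsAsFactors = FALSE)
}

#' Simulate BCECF calibration and sample ratio data
#'
#' Generates emission ratios from the sigmoidal calibration model at the
#' given pH grid plus Gaussian noise, and (optionally) sample ratios at
#' specified true pH values. Ground truth is retained.
#'
#' @param curveParams list with `rMin`, `rMax`, `pKa`, `hill`.
#' @param phGrid calibration pH values (e.g. `seq(4, 10, by = 0.5)`).
#' @param noiseSd Gaussian noise sd on the ratio scale.
#' @param samplePh optional true pH values for a sample ratio table.
#' @param seed integer seed.
#' @return list with `calibration` (data.frame `ph`, `ratio`) and, when
#'   `samplePh` is given, `samples` (data.frame `true_ph`, `ratio`).
#' @export
simulateBcecf <- function(curveParams = list(rMin = 1, rMax = 5,
                                             pKa = 7, hill = 1),
                          phGrid = seq(4, 10, by = 0.5), noiseSd = 0.05,
                          samplePh = NULL, seed = 1L) {
    if (!length(phGrid)) stop("phGrid must contain at least one pH value")
    state <- localSeed(seed)
    on.exit(restoreSeed(state))
    model <- function(ph)
        curveParams$rMin + (curveParams$rMax - curveParams$rMin) /
            (1 + 10^(curveParams$hill * (curveParams$pKa - ph)))
    cal <- data.frame(ph = phGrid,
                      ratio = model(phGrid) +
                          stats::rnorm(length(phGrid), 0, noiseSd))
    out <- list(calibration = cal, truth = curveParams)
    if (!is.null(samplePh))
        out$samples <- data.frame(
            true_ph = samplePh,
            ratio = model(samplePh) +
                stats::rnorm(length(samplePh), 0, noiseSd))
    out
}
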