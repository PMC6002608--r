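#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

GUIDE_CATEGORIES <- c("SLC", "EssentialControl", "NonTargeting")
NT_SENTINEL <- "NonTargeting"
SCREEN_POPULATIONS <- c("PhagoLate", "PhagoNeg", "Initial")

#' GuideLibrary: the sgRNA catalog of a pooled screen
#'
#' Holds one record per sgRNA (id, target gene, spacer sequence, category)
#' together with the declared spacer length. Spacers and ids are unique, so
#' the library doubles as an exact spacer-to-sgRNA lookup used by the read
#' counter and as the gene-to-sgRNA map used by gene aggregation.
#' Non-targeting controls carry the sentinel gene `"NonTargeting"`.
#'
#' @slot records `DataFrame` with columns `sgrna_id`, `gene`, `spacer`,
#'   `category` (one of `SLC`, `EssentialControl`, `NonTargeting`).
#' @slot spacerLength integer, the common spacer length in nucleotides.
#' @export
setClass("GuideLibrary",
         slots = c(records = "DataFrame", spacerLength = "integer"))

setValidity("GuideLibrary", function(object) {
    rec <- object@records
    needed <- c("sgrna_id", "gene", "spacer", "category")
    if (!all(needed %in% colnames(rec)))
        return(paste("records must have columns:",
                     paste(needed, collapse = ", ")))
    if (nrow(rec) == 0L)
        return("empty library: at least one sgRNA record is required")
    msgs <- character()
    if (length(object@spacerLength) != 1L || is.na(object@spacerLength) ||
        object@spacerLength < 1L)
        msgs <- c(msgs, "spacerLength must be a single positive integer")
    dup <- unique(rec$sgrna_id[duplicated(rec$sgrna_id)])
    if (length(dup))
        msgs <- c(msgs, paste0("duplicate sgrna_id: ",
                               paste(utils::head(dup, 5L), collapse = ", ")))
    dsp <- unique(rec$spacer[duplicated(rec$spacer)])
    if (length(dsp))
        msgs <- c(msgs, paste0("duplicate spacer: ",
                               paste(utils::head(dsp, 5L), collapse = ", ")))
    if (length(object@spacerLength) == 1L && !is.na(object@spacerLength) &&
        any(nchar(rec$spacer) != object@spacerLength))
        msgs <- c(msgs, sprintf("all spacers must be %d nt",
                                object@spacerLength))
    if (any(!grepl("^[ACGT]+$", rec$spacer)))
        msgs <- c(msgs, "spacers must contain only A, C, G, T")
    badcat <- setdiff(unique(rec$category), GUIDE_CATEGORIES)
    if (length(badcat))
        msgs <- c(msgs, paste0("unknown category: ",
                               paste(badcat, collapse = ", ")))
    nt <- rec$category == NT_SENTINEL
    if (any(nt) && any(rec$gene[nt] != NT_SENTINEL))
        msgs <- c(msgs,
                  "NonTargeting records must carry the sentinel gene 'NonTargeting'")
    if (length(msgs)) msgs else TRUE
})

#' ScreenCounts: sgRNA counts per sorted sample
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] wrapper: rows are
#' sgRNAs (rowData mirrors the [GuideLibrary-class] records), columns are
#' sequenced samples with `colData` columns `replicate` (integer) and
#' `population` (`PhagoLate`, `PhagoNeg` or `Initial`). The single assay
#' `counts` holds non-negative integer read counts. Simulated objects carry
#' their generative ground truth in `metadata(x)$truth`.
#'
#' @export
setClass("ScreenCounts", contains = "SummarizedExperiment")

setValidity("ScreenCounts", function(object) {
    msgs <- character()
    if (!"counts" %in% assayNames(object))
        return("assay 'counts' is required")
    k <- assay(object, "counts")
    if (anyNA(k) || any(k < 0) || any(k != round(k)))
        msgs <- c(msgs, "counts must be non-negative integers")
    cd <- colData(object)
    if (!all(c("replicate", "population") %in% colnames(cd))) {
        msgs <- c(msgs, "colData needs columns 'replicate' and 'population'")
    } else if (!all(cd$population %in% SCREEN_POPULATIONS)) {
        msgs <- c(msgs, paste("population must be one of:",
                              paste(SCREEN_POPULATIONS, collapse = ", ")))
    }
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msgs <- c(msgs, "sample ids (colnames) must be present and unique")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msgs <- c(msgs, "sgRNA ids (rownames) must be present and unique")
    if (length(msgs)) msgs else TRUE
})

#' CassetteSpec: read structure of the amplified sgRNA cassette
#'
#' A sequencing read covering the sgRNA cassette is modeled as
#' `upstream flank + spacer + downstream flank`. Defaults mirror the
#' lentiCRISPRv2 context: the end of the U6 promoter (ending in `ACCG`)
#' upstream and the start of the tracrRNA scaffold downstream.
#'
#' @slot upstream,downstream ACGT-only flank sequences.
#' @slot spacerLength integer length of the spacer slot.
#' @export
setClass("CassetteSpec",
         slots = c(upstream = "character", downstream = "character",
                   spacerLength = "integer"))

setValidity("CassetteSpec", function(object) {
    msgs <- character()
    if (length(object@upstream) != 1L || !nzchar(object@upstream) ||
        !grepl("^[ACGT]+$", object@upstream))
        msgs <- c(msgs, "upstream flank must be a non-empty ACGT string")
    if (length(object@downstream) != 1L || !nzchar(object@downstream) ||
        !grepl("^[ACGT]+$", object@downstream))
        msgs <- c(msgs, "downstream flank must be a non-empty ACGT string")
    if (length(object@spacerLength) != 1L || object@spacerLength < 1L)
        msgs <- c(msgs, "spacerLength must be a single positive integer")
    if (length(msgs)) msgs else TRUE
})

#' ScreenSimConfig: parameters of the generative screen model
#'
#' Defaults reproduce the screen design being emulated: MOI 0.25 (the
#' protocol's 0.2-0.3 window, chosen to favor single integrations), 1000
#' transduced cells per sgRNA, three replicates, 3e6 cells sorted per
#' population, and a two-way sort into PhagoLate / PhagoNeg where a cell's
#' probability of sorting PhagoLate is `baselinePhagoProb` times the effect
#' multiplier of its knocked-out gene.
#'
#' @export
setClass("ScreenSimConfig",
         slots = c(library = "GuideLibrary",
                   moi = "numeric",
                   coverage = "numeric",
                   nReplicates = "integer",
                   sortDepth = "numeric",
                   baselinePhagoProb = "numeric",
                   effectMap = "numeric",
                   editingEfficiency = "numeric",
                   essentialDropout = "numeric",
                   pcrDispersion = "numeric",
                   readDepth = "numeric",
                   librarySkewSd = "numeric",
                   includeInitial = "logical",
                   allowExpansion = "logical",
                   seed = "integer"))

setValidity("ScreenSimConfig", function(object) {
    msgs <- character()
    chkProb <- function(x, nm) {
        if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
            sprintf("%s must be a probability in [0, 1]", nm)
        else character()
    }
    msgs <- c(msgs,
              chkProb(object@baselinePhagoProb, "baselinePhagoProb"),
              chkProb(object@editingEfficiency, "editingEfficiency"),
              chkProb(object@essentialDropout, "essentialDropout"))
    if (object@moi <= 0) msgs <- c(msgs, "moi must be > 0")
    if (object@coverage <= 0) msgs <- c(msgs, "coverage must be > 0")
    if (object@nReplicates < 1L) msgs <- c(msgs, "nReplicates must be >= 1")
    if (object@sortDepth < 1) msgs <- c(msgs, "sortDepth must be >= 1")
    if (object@readDepth <= 0) msgs <- c(msgs, "readDepth must be > 0")
    if (object@pcrDispersion < 0) msgs <- c(msgs, "pcrDispersion must be >= 0")
    if (object@librarySkewSd < 0) msgs <- c(msgs, "librarySkewSd must be >= 0")
    if (length(object@effectMap) &&
        (is.null(names(object@effectMap)) || any(!nzchar(names(object@effectMap)))))
        msgs <- c(msgs, "effectMap must be a named numeric vector (gene -> multiplier)")
    if (any(object@effectMap < 0))
        msgs <- c(msgs, "effect multipliers must be >= 0")
    if (length(msgs)) msgs else TRUE
})

#' ScreenTruth: generative ground truth of a simulated screen
#'
#' @slot effects named per-gene effect multipliers (1 = no effect).
#' @slot guideExpected matrix of expected per-sgRNA abundance shares, one
#'   column per population.
#' @slot hits genes whose multiplier differs from 1.
#' @export
setClass("ScreenTruth",
         slots = c(effects = "numeric", guideExpected = "matrix",
                   hits = "character"))

setValidity("ScreenTruth", function(object) {
    planted <- names(object@effects)[object@effects != 1]
    if (!setequal(planted, object@hits))
        return("hits must be exactly the genes with multiplier != 1")
    TRUE
})

#' DispersionModel: per-sgRNA negative-binomial dispersions
#'
#' Raw method-of-moments estimates, the fitted mean-dispersion trend
#' `alpha(mu) = a1/mu + a0`, and the final log-space shrinkage of raw
#' values toward the trend (floored at `floor`).
#'
#' @export
setClass("DispersionModel",
         slots = c(raw = "numeric", trendCoef = "numeric",
                   trend = "numeric", final = "numeric",
                   baseMean = "numeric", weight = "numeric",
                   floor = "numeric"))

setValidity("DispersionModel", function(object) {
    msgs <- character()
    if (any(object@final < object@floor - 1e-15, na.rm = TRUE))
        msgs <- c(msgs, "final dispersions must respect the floor")
    if (any(object@trend < 0, na.rm = TRUE))
        msgs <- c(msgs, "trend must be non-negative")
    if (length(msgs)) msgs else TRUE
})

#' GateThresholds: quadrant-gate cutoffs for two-channel events
#'
#' @slot ygCut cutoff on the pH-insensitive uptake channel (YG).
#' @slot phrodoCut cutoff on the pH-sensitive channel (pHrodo).
#' @export
setClass("GateThresholds", slots = c(ygCut = "numeric", phrodoCut = "numeric"))

setValidity("GateThresholds", function(object) {
    if (length(object@ygCut) != 1L || length(object@phrodoCut) != 1L ||
        object@ygCut <= 0 || object@phrodoCut <= 0)
        return("both cuts must be single positive intensities")
    TRUE
})

#' CalibrationCurve: sigmoidal BCECF ratio-vs-pH model
#'
#' `R(pH) = rMin + (rMax - rMin) / (1 + 10^(hill * (pKa - pH)))`,
#' monotone increasing in pH for `hill > 0`. `phRange` records the pH span
#' of the calibration data; inversions outside `(rMin, rMax)` are clamped
#' to it.
#'
#' @export
setClass("CalibrationCurve",
         slots = c(rMin = "numeric", rMax = "numeric", pKa = "numeric",
                   hill = "numeric", residualSd = "numeric",
                   converged = "logical", phRange = "numeric"))

setValidity("CalibrationCurve", function(object) {
    msgs <- character()
    if (object@rMax <= object@rMin) msgs <- c(msgs, "rMax must exceed rMin")
    if (object@hill <= 0) msgs <- c(msgs, "hill slope must be > 0")
    if (length(object@phRange) != 2L || diff(object@phRange) <= 0)
        msgs <- c(msgs, "phRange must be an increasing pH interval")
    if (length(msgs)) msgs else TRUE
})
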