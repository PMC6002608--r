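#' Build an sgRNA library index
#'
#' Constructs a validated [GuideLibrary-class] from per-sgRNA records.
#' Duplicate ids or spacers and mixed spacer lengths are rejected with the
#' offending entries named.
#'
#' @param records data.frame (or DataFrame) with columns `sgrna_id`, `gene`,
#'   `spacer`, `category`.
#' @param spacerLength expected spacer length in nt; defaults to the length
#'   of the first spacer.
#' @return A [GuideLibrary-class].
#' @examples
#' lib <- buildGuideLibrary(data.frame(
#'     sgrna_id = c("g1", "g2"), gene = c("SLC2A1", "SLC2A1"),
#'     spacer = c(strrep("A", 20), strrep("C", 20)),
#'     category = "SLC"))
#' length(lib)
#' @export
buildGuideLibrary <- function(records, spacerLength = NULL) {
    records <- as.data.frame(records, stringsAsFactors = FALSE)
    needed <- c("sgrna_id", "gene", "spacer", "category")
    missing <- setdiff(needed, colnames(records))
    if (length(missing))
        stop("records lack required column(s): ",
             paste(missing, collapse = ", "))
    if (nrow(records) == 0L)
        stop("empty library: at least one sgRNA record is required")
    for (col in needed)
        records[[col]] <- as.character(records[[col]])
    if (is.null(spacerLength))
        spacerLength <- nchar(records$spacer[1L])
    lens <- unique(nchar(records$spacer))
    if (length(lens) > 1L)
        stop("mixed spacer lengths: found ", paste(sort(lens), collapse = ", "),
             " nt; all spacers must be ", spacerLength, " nt")
    rec <- S4Vectors::DataFrame(records[needed])
    rownames(rec) <- NULL
    new("GuideLibrary", records = rec,
        spacerLength = as.integer(spacerLength))
}

#' Default library design of the emulated screen
#'
#' Generates a library with the published composition — 391 SLC genes with
#' six sgRNAs each, 20 essential control genes with six sgRNAs each (120
#' sgRNAs) and 120 non-targeting sgRNAs (2,586 records in total) — with
#' unique random spacers. The true spacer sequences of the screen's
#' in-house library are not public, so spacers are generated; composition,
#' not sequence, is what downstream code depends on.
#'
#' @param seed integer seed; the same seed reproduces the same spacers.
#' @param nSlcGenes,nSgPerGene,nEssentialGenes,nNonTargeting design knobs,
#'   defaulting to the published design.
#' @param spacerLength spacer length in nt (default 20).
#' @return A [GuideLibrary-class].
#' @examples
#' lib <- defaultScreenLibrary(seed = 1)
#' libraryComposition(lib)
#' @export
defaultScreenLibrary <- function(seed = 1L, nSlcGenes = 391L, nSgPerGene = 6L,
                                 nEssentialGenes = 20L, nNonTargeting = 120L,
                                 spacerLength = 20L) {
    nEssential <- nEssentialGenes * nSgPerGene
    nTotal <- nSlcGenes * nSgPerGene + nEssential + nNonTargeting
    spacers <- randomSpacers(nTotal, spacerLength, seed = seed)
    slcGenes <- sprintf("SLC%03d", seq_len(nSlcGenes))
    essGenes <- sprintf("ESS%02d", seq_len(nEssentialGenes))
    records <- data.frame(
        sgrna_id = c(sprintf("%s_sg%d", rep(slcGenes, each = nSgPerGene),
                             rep(seq_len(nSgPerGene), nSlcGenes)),
                     sprintf("%s_sg%d", rep(essGenes, each = nSgPerGene),
                             rep(seq_len(nSgPerGene), nEssentialGenes)),
                     sprintf("NT_sg%03d", seq_len(nNonTargeting))),
        gene = c(rep(slcGenes, each = nSgPerGene),
                 rep(essGenes, each = nSgPerGene),
                 rep(NT_SENTINEL, nNonTargeting)),
        spacer = spacers,
        category = c(rep("SLC", nSlcGenes * nSgPerGene),
                     rep("EssentialControl", nEssential),
                     rep(NT_SENTINEL, nNonTargeting)),
        stringsAsFactors = FALSE)
    buildGuideLibrary(records, spacerLength = spacerLength)
}

# unique random ACGT k-mers, deterministic under seed
randomSpacers <- function(n, len, seed) {
    state <- localSeed(seed)
    on.exit(restoreSeed(state))
    out <- character(0L)
    while (length(out) < n) {
        draw <- vapply(seq_len(n - length(out)), function(i)
            paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  collapse = ""), character(1L))
        out <- unique(c(out, draw))
    }
    out[seq_len(n)]
}

# set.seed locally; restore the caller's RNG state afterwards
localSeed <- function(seed) {
    state <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    state
}

restoreSeed <- function(state) {
    if (is.null(state)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    } else {
        assign(".Random.seed", state, envir = globalenv())
    }
    invisible(NULL)
}

# stage-specific child seed, kept inside 32-bit integer range
deriveSeed <- function(seed, offset) {
    as.integer((as.numeric(seed) * 48271 + offset) %% 2147483587L + 1L)
}

#' @describeIn GuideLibrary-class number of sgRNA records.
#' @export
setMethod("length", "GuideLibrary", function(x) nrow(x@records))

#' @describeIn GuideLibrary-class the full record table as a `DataFrame`.
#' @export
setMethod("guides", "GuideLibrary", function(x) x@records)

#' @describeIn GuideLibrary-class spacer sequences, named by sgRNA id.
#' @export
setMethod("spacers", "GuideLibrary", function(x)
    stats::setNames(x@records$spacer, x@records$sgrna_id))

#' @describeIn GuideLibrary-class declared spacer length (nt).
#' @export
setMethod("spacerLength", "GuideLibrary", function(x) x@spacerLength)

#' @describeIn GuideLibrary-class per-record category vector.
#' @export
setMethod("guideCategories", "GuideLibrary", function(x)
    stats::setNames(x@records$category, x@records$sgrna_id))

#' @describeIn GuideLibrary-class genes and sgRNA counts per category.
#' @export
setMethod("libraryComposition", "GuideLibrary", function(x) {
    rec <- x@records
    split_ <- split(rec$gene, rec$category)
    cats <- GUIDE_CATEGORIES
    genes <- vapply(cats, function(ct) {
        g <- split_[[ct]]
        if (is.null(g)) 0L
        else if (ct == NT_SENTINEL) NA_integer_
        else length(unique(g))
    }, integer(1L))
    sgrnas <- vapply(cats, function(ct)
        sum(rec$category == ct), integer(1L))
    perGene <- table(rec$gene[rec$category != NT_SENTINEL])
    list(genes = genes, sgrnas = sgrnas,
         sgrnasPerGene = as.integer(perGene),
         genesPerCategory = genes, total = nrow(rec))
})

#' @describeIn GuideLibrary-class exact spacer lookup; returns the matching
#'   sgRNA id(s), `NA` where a spacer is absent from the library.
#' @export
setMethod("spacerLookup", "GuideLibrary", function(x, spacer) {
    idx <- match(spacer, x@records$spacer)
    stats::setNames(x@records$sgrna_id[idx], spacer)
})

setMethod("show", "GuideLibrary", function(object) {
    comp <- libraryComposition(object)
    cat("GuideLibrary with", length(object), "sgRNAs (",
        object@spacerLength, "nt spacers )\n")
    for (ct in GUIDE_CATEGORIES) {
        g <- comp$genes[[ct]]
        cat(sprintf("  %-17s %4d sgRNAs%s\n", ct, comp$sgrnas[[ct]],
                    if (is.na(g)) "" else sprintf(" / %d genes", g)))
    }
})

#' Read / write a library index as TSV
#'
#' The interchange format is a tab-separated UTF-8 table with header columns
#' `sgrna_id`, `gene`, `spacer`, `category`; lines starting with `#` are
#' ignored. `writeGuideLibrary` then `readGuideLibrary` reproduces the
#' library, order preserved.
#'
#' @param path file path.
#' @return `readGuideLibrary`: a [GuideLibrary-class].
#' @export
readGuideLibrary <- function(path) {
    if (!file.exists(path)) stop("no such index file: ", path)
    raw <- readLines(path, warn = FALSE)
    keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
    lineNo <- which(keep)
    if (!length(lineNo)) stop("empty library: ", path, " has no content")
    tab <- utils::read.delim(text = raw[keep], header = TRUE,
                             stringsAsFactors = FALSE,
                             colClasses = "character")
    needed <- c("sgrna_id", "gene", "spacer", "category")
    missing <- setdiff(needed, colnames(tab))
    if (length(missing))
        stop("index file ", path, " lacks column(s): ",
             paste(missing, collapse = ", "))
    if (nrow(tab) == 0L)
        stop("empty library: ", path, " contains a header only")
    dataLines <- lineNo[-1L]
    badCat <- which(!tab$category %in% GUIDE_CATEGORIES)
    if (length(badCat))
        stop("bad category token '", tab$category[badCat[1L]],
             "' at line ", dataLines[badCat[1L]], " of ", path)
    badSp <- which(!grepl("^[ACGT]+$", tab$spacer))
    if (length(badSp))
        stop("non-ACGT spacer '", tab$spacer[badSp[1L]],
             "' at line ", dataLines[badSp[1L]], " of ", path)
    buildGuideLibrary(tab)
}

#' @param library a [GuideLibrary-class].
#' @rdname readGuideLibrary
#' @export
writeGuideLibrary <- function(library, path) {
    stopifnot(is(library, "GuideLibrary"))
    utils::write.table(as.data.frame(library@records), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Export library spacers as FASTA
#'
#' One record per sgRNA; the id line carries the sgRNA id.
#'
#' @param library a [GuideLibrary-class].
#' @param path output FASTA path.
#' @export
exportSpacerFasta <- function(library, path) {
    stopifnot(is(library, "GuideLibrary"))
    seqs <- Biostrings::DNAStringSet(spacers(library))
    Biostrings::writeXStringSet(seqs, filepath = path)
    invisible(path)
}
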