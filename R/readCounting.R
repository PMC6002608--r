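#' Describe the sgRNA cassette read structure
#'
#' @param upstream,downstream flank sequences around the spacer slot;
#'   defaults mirror the lentiCRISPRv2 context (end of the U6 promoter and
#'   start of the tracrRNA scaffold).
#' @param spacerLength length of the spacer slot (nt).
#' @return A [CassetteSpec-class].
#' @export
cassetteSpec <- function(upstream = "TTGTGGAAAGGACGAAACACCG",
                         downstream = "GTTTTAGAGCTAGAAATAGCAAG",
                         spacerLength = 20L) {
    new("CassetteSpec", upstream = upstream, downstream = downstream,
        spacerLength = as.integer(spacerLength))
}

#' Extract the spacer from a read
#'
#' Locates the first exact occurrence of the upstream flank anywhere in the
#' read and returns the following `spacerLength` bases, provided they are
#' ACGT-only and are followed by at least the first four bases of the
#' downstream flank. Any failure returns `NA` (never an error): reads too
#' short, flank missing, corrupt spacer.
#'
#' @param reads character vector of read sequences.
#' @param cassette a [CassetteSpec-class].
#' @param minDownstreamMatch bases of the downstream flank that must follow
#'   the spacer (default 4).
#' @return Character vector of spacers, `NA` where extraction failed.
#' @examples
#' cs <- cassetteSpec("ACCG", "GTTT", 20L)
#' extractSpacer(paste0("ACCG", strrep("A", 20), "GTTT"), cs)
#' @export
extractSpacer <- function(reads, cassette = cassetteSpec(),
                          minDownstreamMatch = 4L) {
    stopifnot(is(cassette, "CassetteSpec"))
    up <- cassette@upstream
    L <- cassette@spacerLength
    need <- substr(cassette@downstream, 1L, minDownstreamMatch)
    pos <- regexpr(up, reads, fixed = TRUE)
    start <- pos + nchar(up)
    spacer <- substr(reads, start, start + L - 1L)
    down <- substr(reads, start + L, start + L + nchar(need) - 1L)
    ok <- pos > 0L & nchar(spacer) == L & down == need &
        grepl("^[ACGT]+$", spacer)
    spacer[!ok] <- NA_character_
    spacer
}

#' Count sgRNA-matching reads per sample
#'
#' Extracts spacers from each sample's FASTQ file(s) and matches them
#' exactly against the library index; each read contributes at most one
#' count to exactly one sgRNA, and sgRNAs with no reads appear with count
#' zero. No mismatch rescue is attempted unless `rescueMismatch = TRUE`
#' (then reads whose spacer is one substitution away from a unique library
#' spacer are assigned to it).
#'
#' @param fastqFiles named character vector or named list; names are sample
#'   ids (`rep<i>_<population>` parses into colData automatically),
#'   elements are FASTQ paths (gzip transparent), possibly several per
#'   sample.
#' @param library a [GuideLibrary-class].
#' @param cassette a [CassetteSpec-class].
#' @param sampleMeta optional data.frame with columns `sample_id`,
#'   `replicate`, `population` when ids do not follow the
#'   `rep<i>_<population>` convention.
#' @param reverseComplement also search the reverse complement of each read
#'   when the forward orientation yields nothing (default off; the
#'   amplification design fixes cassette orientation).
#' @param rescueMismatch allow single-substitution rescue (default off).
#' @return list with `counts` (a [ScreenCounts-class]) and `report`
#'   (data.frame: per-sample `total_reads`, `assigned_reads`,
#'   `unassigned_reads`, `assignment_rate`).
#' @export
countReads <- function(fastqFiles, library, cassette = cassetteSpec(),
                       sampleMeta = NULL, reverseComplement = FALSE,
                       rescueMismatch = FALSE) {
    stopifnot(is(library, "GuideLibrary"), is(cassette, "CassetteSpec"))
    if (is.null(names(fastqFiles)) || any(!nzchar(names(fastqFiles))))
        stop("fastqFiles must be named by sample id")
    sampleIds <- names(fastqFiles)
    if (anyDuplicated(sampleIds)) stop("duplicate sample ids")
    meta <- resolveSampleMeta(sampleIds, sampleMeta)
    libSpacers <- guides(library)$spacer
    G <- length(library)
    counts <- matrix(0L, nrow = G, ncol = length(sampleIds),
                     dimnames = list(guides(library)$sgrna_id, sampleIds))
    report <- data.frame(sample_id = sampleIds, total_reads = 0L,
                         assigned_reads = 0L, unassigned_reads = 0L,
                         assignment_rate = NA_real_,
                         stringsAsFactors = FALSE)
    for (j in seq_along(fastqFiles)) {
        paths <- unlist(fastqFiles[[j]], use.names = FALSE)
        seqs <- unlist(lapply(paths, readFastqSequences), use.names = FALSE)
        spacer <- extractSpacer(seqs, cassette)
        if (reverseComplement) {
            miss <- is.na(spacer)
            if (any(miss)) {
                rc <- as.character(Biostrings::reverseComplement(
                    Biostrings::DNAStringSet(seqs[miss])))
                spacer[miss] <- extractSpacer(rc, cassette)
            }
        }
        idx <- match(spacer, libSpacers)
        if (rescueMismatch) {
            miss <- which(!is.na(spacer) & is.na(idx))
            if (length(miss))
                idx[miss] <- rescueOneMismatch(spacer[miss], libSpacers)
        }
        tab <- tabulate(idx[!is.na(idx)], nbins = G)
        counts[, j] <- as.integer(tab)
        report$total_reads[j] <- length(seqs)
        report$assigned_reads[j] <- sum(tab)
        report$unassigned_reads[j] <- length(seqs) - sum(tab)
        report$assignment_rate[j] <-
            if (length(seqs)) sum(tab) / length(seqs) else NA_real_
    }
    sc <- ScreenCounts(counts, replicate = meta$replicate,
                       population = meta$population, library = library)
    list(counts = sc, report = report)
}

# sample ids "rep<i>_<population>" parse directly; otherwise sampleMeta rules
resolveSampleMeta <- function(sampleIds, sampleMeta) {
    if (!is.null(sampleMeta)) {
        need <- c("sample_id", "replicate", "population")
        if (!all(need %in% colnames(sampleMeta)))
            stop("sampleMeta needs columns: ", paste(need, collapse = ", "))
        idx <- match(sampleIds, sampleMeta$sample_id)
        if (anyNA(idx))
            stop("unknown sample id(s): ",
                 paste(sampleIds[is.na(idx)], collapse = ", "))
        return(data.frame(replicate = as.integer(sampleMeta$replicate[idx]),
                          population = as.character(sampleMeta$population[idx]),
                          stringsAsFactors = FALSE))
    }
    m <- regmatches(sampleIds,
                    regexec("^rep([0-9]+)_(PhagoLate|PhagoNeg|Initial)$",
                            sampleIds))
    bad <- vapply(m, length, integer(1L)) != 3L
    if (any(bad))
        stop("unknown sample id(s): ", paste(sampleIds[bad], collapse = ", "),
             "; use rep<i>_<population> ids or supply sampleMeta")
    data.frame(replicate = as.integer(vapply(m, `[`, character(1L), 2L)),
               population = vapply(m, `[`, character(1L), 3L),
               stringsAsFactors = FALSE)
}

# plain 4-line FASTQ parser (gzip transparent); errors name the record
readFastqSequences <- function(path) {
    if (!file.exists(path)) stop("no such FASTQ file: ", path)
    lines <- readLines(path, warn = FALSE)
    if (!length(lines)) return(character(0L))
    if (length(lines) %% 4L != 0L)
        stop("malformed FASTQ ", path, ": truncated record ",
             ceiling(length(lines) / 4), " (", length(lines),
             " lines, not a multiple of 4)")
    heads <- lines[seq(1L, length(lines), by = 4L)]
    plus <- lines[seq(3L, length(lines), by = 4L)]
    badH <- which(substr(heads, 1L, 1L) != "@")
    if (length(badH))
        stop("malformed FASTQ ", path, ": record ", badH[1L],
             " does not start with '@'")
    badP <- which(substr(plus, 1L, 1L) != "+")
    if (length(badP))
        stop("malformed FASTQ ", path, ": record ", badP[1L],
             " lacks the '+' separator")
    lines[seq(2L, length(lines), by = 4L)]
}

# assign spacers at Hamming distance exactly 1 from a unique library spacer
rescueOneMismatch <- function(spacer, libSpacers) {
    vapply(spacer, function(s) {
        d <- hammingTo(s, libSpacers)
        hit <- which(d == 1L)
        if (length(hit) == 1L) hit else NA_integer_
    }, integer(1L), USE.NAMES = FALSE)
}

hammingTo <- function(s, pool) {
    a <- strsplit(s, "", fixed = TRUE)[[1L]]
    vapply(strsplit(pool, "", fixed = TRUE),
           function(b) sum(a != b), integer(1L))
}
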