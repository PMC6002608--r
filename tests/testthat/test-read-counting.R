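cs4 <- cassetteSpec(upstream = "ACCG", downstream = "GTTT",
                    spacerLength = 20L)

# reference implementation: scan every offset for the flank, check the
# spacer slot and downstream bases by hand
bruteExtract <- function(read, cassette, minDown = 4L) {
    up <- cassette@upstream; L <- cassette@spacerLength
    need <- substr(cassette@downstream, 1L, minDown)
    for (i in seq_len(max(nchar(read) - nchar(up) + 1L, 0L))) {
        if (substr(read, i, i + nchar(up) - 1L) == up) {
            s <- substr(read, i + nchar(up), i + nchar(up) + L - 1L)
            d <- substr(read, i + nchar(up) + L,
                        i + nchar(up) + L + minDown - 1L)
            if (nchar(s) == L && d == need && grepl("^[ACGT]+$", s))
                return(s)
            return(NA_character_)
        }
    }
    NA_character_
}

test_that("spacer extraction follows the cassette structure", {
    sp <- strrep("AAAAT", 4L)
    expect_equal(extractSpacer(paste0("ACCG", sp, "GTTT"), cs4), sp)
    expect_true(is.na(extractSpacer(paste0("TTTT", sp, "GTTT"), cs4)))
    # flank at an interior position: search is position-free
    shifted <- paste0("CGATCGA", "ACCG", sp, "GTTTAGA")
    expect_equal(extractSpacer(shifted, cs4), sp)
    expect_equal(extractSpacer(shifted, cs4), bruteExtract(shifted, cs4))
    # too short for spacer + downstream check
    expect_true(is.na(extractSpacer(paste0("ACCG", substr(sp, 1, 10)), cs4)))
    # corrupted downstream flank
    expect_true(is.na(extractSpacer(paste0("ACCG", sp, "CCCC"), cs4)))
})

test_that("extraction agrees with a brute-force offset scan on random reads", {
    set.seed(11)
    for (i in 1:200) {
        read <- paste(sample(c("A", "C", "G", "T", "N"), sample(10:60, 1),
                             replace = TRUE, prob = c(rep(0.24, 4), 0.04)),
                      collapse = "")
        if (runif(1) < 0.5)  # plant a valid cassette half the time
            read <- paste0(substr(read, 1, 5), "ACCG",
                           paste(sample(c("A", "C", "G", "T"), 20,
                                        replace = TRUE), collapse = ""),
                           "GTTT", substr(read, 6, 12))
        expect_identical(extractSpacer(read, cs4), bruteExtract(read, cs4))
    }
})

test_that("counting assigns each read to exactly one sgRNA", {
    lib <- tinyLibrary(nGenes = 3L, nEssential = 1L, nNt = 2L)
    sp <- guides(lib)$spacer
    good <- paste0("ACCG", sp[1L], "GTTT")
    bad <- paste0("TCCG", sp[1L], "GTTT")   # corrupted upstream flank
    reads <- c(rep(good, 7L), rep(bad, 3L))
    d <- withr::local_tempdir()
    fq <- file.path(d, "rep1_PhagoLate.fastq")
    writeLines(as.vector(rbind(sprintf("@r%d", seq_along(reads)), reads,
                               "+", strrep("I", nchar(good)))), fq)
    res <- countReads(c(rep1_PhagoLate = fq), lib, cs4)
    expect_equal(res$report$total_reads, 10L)
    expect_equal(res$report$assigned_reads, 7L)
    expect_equal(res$report$unassigned_reads, 3L)
    k <- SummarizedExperiment::assay(res$counts)
    expect_equal(unname(k[1L, 1L]), 7L)
    expect_equal(sum(k), 7L)
})

test_that("one-mismatch reads stay unassigned unless rescue is enabled", {
    lib <- tinyLibrary(nGenes = 3L, nEssential = 1L, nNt = 2L)
    sp <- guides(lib)$spacer[2L]
    d <- withr::local_tempdir()
    # every single-substitution neighbor of the spacer
    neighbors <- unlist(lapply(seq_len(nchar(sp)), function(i)
        vapply(setdiff(c("A", "C", "G", "T"), substr(sp, i, i)),
               function(b) { s <- sp; substr(s, i, i) <- b; s },
               character(1L))))
    stopifnot(!any(neighbors %in% guides(lib)$spacer))
    reads <- paste0("ACCG", neighbors, "GTTT")
    fq <- file.path(d, "rep1_PhagoNeg.fastq")
    writeLines(as.vector(rbind(sprintf("@r%d", seq_along(reads)), reads,
                               "+", strrep("I", nchar(reads[1L])))), fq)
    strict <- countReads(c(rep1_PhagoNeg = fq), lib, cs4)
    expect_equal(strict$report$assigned_reads, 0L)
    rescued <- countReads(c(rep1_PhagoNeg = fq), lib, cs4,
                          rescueMismatch = TRUE)
    k <- SummarizedExperiment::assay(rescued$counts)
    expect_equal(unname(k[2L, 1L]), length(neighbors))
})

test_that("counting is order-independent and column sums match the report", {
    lib <- tinyLibrary(nGenes = 4L)
    set.seed(3)
    m <- matrix(rpois(length(lib) * 2L, 30), ncol = 2L,
                dimnames = list(guides(lib)$sgrna_id,
                                c("rep1_PhagoLate", "rep1_PhagoNeg")))
    storage.mode(m) <- "integer"
    d <- withr::local_tempdir()
    paths <- emitFastq(m, cs4, errorRate = 0, dir = d, library = lib)
    res <- countReads(paths, lib, cs4)
    expect_identical(SummarizedExperiment::assay(res$counts), m)
    expect_equal(unname(colSums(SummarizedExperiment::assay(res$counts))),
                 res$report$assigned_reads)
    # shuffle the reads of one sample
    lines <- readLines(paths[[1L]])
    rec <- matrix(lines, nrow = 4L)
    rec <- rec[, sample(ncol(rec)), drop = FALSE]
    writeLines(as.vector(rec), paths[[1L]])
    res2 <- countReads(paths, lib, cs4)
    expect_identical(SummarizedExperiment::assay(res2$counts), m)
})

test_that("malformed FASTQ and unknown sample ids are reported", {
    lib <- tinyLibrary(nGenes = 2L)
    d <- withr::local_tempdir()
    fq <- file.path(d, "x.fastq")
    writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), fq)
    expect_error(countReads(c(rep1_PhagoLate = fq), lib, cs4),
                 "truncated record 2")
    writeLines(c("@r1", "ACGT", "+", "IIII", "r2", "ACGT", "+", "IIII"), fq)
    expect_error(countReads(c(rep1_PhagoLate = fq), lib, cs4),
                 "record 2 does not start with '@'")
    writeLines(c("@r1", "ACGT", "x", "IIII"), fq)
    expect_error(countReads(c(rep1_PhagoLate = fq), lib, cs4),
                 "lacks the '\\+' separator")
    writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
    expect_error(countReads(c(mystery_sample = fq), lib, cs4),
                 "unknown sample id")
    meta <- data.frame(sample_id = "mystery_sample", replicate = 1L,
                       population = "Initial")
    res <- countReads(c(mystery_sample = fq), lib, cs4, sampleMeta = meta)
    expect_equal(SummarizedExperiment::colData(res$counts)$population,
                 "Initial")
})
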