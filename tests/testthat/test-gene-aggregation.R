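fakeStats <- function(n, seed = 1L) {
    set.seed(seed)
    data.frame(sgrna_id = sprintf("sg%03d", seq_len(n)),
               gene = sprintf("G%02d", rep(seq_len(ceiling(n / 6)),
                                           each = 6L))[seq_len(n)],
               log2_fold_change = rnorm(n),
               p_adj = runif(n),
               stringsAsFactors = FALSE)
}

test_that("ranking separates signs and matches a sort oracle", {
    st <- data.frame(sgrna_id = c("up", "down"), gene = c("A", "B"),
                     log2_fold_change = c(2, -2), p_adj = c(0.001, 0.001))
    rk <- rankGuides(st)
    expect_equal(rk$sgrna_id, c("up", "down"))
    expect_equal(rk$metric, c(3, -3), tolerance = 1e-9)

    st2 <- fakeStats(100L, seed = 2L)
    rk2 <- rankGuides(st2)
    r <- sign(st2$log2_fold_change) * (-log10(st2$p_adj + 1e-300))
    oracleOrd <- order(-r, -abs(st2$log2_fold_change), st2$sgrna_id)
    expect_equal(rk2$sgrna_id, st2$sgrna_id[oracleOrd])
})

test_that("tied metrics rank deterministically", {
    st <- fakeStats(30L, seed = 3L)
    st$p_adj <- 1
    a <- rankGuides(st)
    b <- rankGuides(st[sample(nrow(st)), ])
    expect_equal(a, b)
    expect_true(all(a$metric == 0))
    # ties are broken by |LFC| descending
    expect_true(all(diff(abs(a$metric)) <= 1e-15))
    expect_equal(a$sgrna_id,
                 st$sgrna_id[order(-abs(st$log2_fold_change), st$sgrna_id)])
})

test_that("undefined sgRNA statistics are excluded from the ranking", {
    st <- fakeStats(20L)
    st$p_adj[3L] <- NA
    st$log2_fold_change[5L] <- NA
    rk <- rankGuides(st)
    expect_equal(nrow(rk), 18L)
    expect_false(any(rk$sgrna_id %in% st$sgrna_id[c(3L, 5L)]))
})

test_that("enrichment score hits the analytic extremes", {
    ranked <- data.frame(sgrna_id = c("a", "b", "c", "d"),
                         metric = c(3, 2, 1, 0.5))
    expect_equal(enrichmentScore(ranked, c("a", "b"), q = 0), 1)
    expect_equal(enrichmentScore(ranked, c("c", "d"), q = 0), -1)
    expect_error(enrichmentScore(ranked, character(0)), "empty")
    expect_error(enrichmentScore(ranked, ranked$sgrna_id), "proper subset")
    expect_error(enrichmentScore(ranked, c("a", "zz")), "absent")
})

test_that("enrichment score equals the brute-force running sum", {
    set.seed(13)
    for (i in 1:50) {
        N <- 50L
        ranked <- data.frame(sgrna_id = sprintf("s%02d", 1:N),
                             metric = sort(rnorm(N, sd = 2),
                                           decreasing = TRUE))
        members <- sample(ranked$sgrna_id, 6L)
        for (q in c(0, 1, 2)) {
            expect_equal(enrichmentScore(ranked, members, q),
                         bruteES(ranked$sgrna_id, ranked$metric, members, q),
                         tolerance = 1e-12)
        }
    }
})

test_that("reversing the ranked list negates the score", {
    set.seed(14)
    ranked <- data.frame(sgrna_id = sprintf("s%02d", 1:40),
                         metric = sort(rnorm(40), decreasing = TRUE))
    rev <- data.frame(sgrna_id = rev(ranked$sgrna_id),
                      metric = rev(ranked$metric))
    members <- sample(ranked$sgrna_id, 5L)
    for (q in c(0, 1))
        expect_equal(enrichmentScore(rev, members, q),
                     -enrichmentScore(ranked, members, q),
                     tolerance = 1e-12)
})

test_that("q = 0 scores ignore metric rescaling", {
    set.seed(15)
    ranked <- data.frame(sgrna_id = sprintf("s%02d", 1:30),
                         metric = sort(rexp(30), decreasing = TRUE))
    members <- sample(ranked$sgrna_id, 4L)
    scaled <- ranked; scaled$metric <- scaled$metric * 17
    expect_equal(enrichmentScore(scaled, members, q = 0),
                 enrichmentScore(ranked, members, q = 0), tolerance = 1e-12)
})

test_that("permutation p-values are seeded, floored, and calibrated", {
    set.seed(16)
    ranked <- data.frame(sgrna_id = sprintf("s%03d", 1:200),
                         metric = sort(rnorm(200), decreasing = TRUE))
    members <- ranked$sgrna_id[1:5]     # all at the very top
    a <- permutationPvalue(ranked, members, nPerm = 500L, seed = 3L)
    b <- permutationPvalue(ranked, members, nPerm = 500L, seed = 3L)
    expect_identical(a, b)
    # observed more extreme than every matching-sign null: p at the floor
    pos <- match(members, ranked$sgrna_id)
    nulls <- phagoScreen:::nullScores(ranked, 5L, 1, 500L, 3L,
                                      exclude = pos)
    posSide <- nulls[nulls >= 0]
    expect_true(all(abs(posSide) < abs(a$es)))
    expect_equal(a$p_perm, 1 / (1 + length(posSide)), tolerance = 1e-12)
    expect_error(permutationPvalue(ranked, members, nPerm = 50L),
                 "at least 100")

    # null member sets give uniform p
    ps <- vapply(1:300, function(i) {
        set.seed(1000L + i)
        m <- sample(ranked$sgrna_id, 6L)
        permutationPvalue(ranked, m, nPerm = 400L,
                          seed = 2000L + i)$p_perm
    }, numeric(1L))
    ks <- suppressWarnings(stats::ks.test(ps, "punif"))
    expect_lt(unname(ks$statistic), 0.1)
})

test_that("gene aggregation builds the volcano table", {
    lib <- tinyLibrary(nGenes = 12L)
    rec <- guides(lib)
    n <- nrow(rec)
    set.seed(17)
    st <- data.frame(sgrna_id = rec$sgrna_id, gene = rec$gene,
                     log2_fold_change = rnorm(n, sd = 0.2),
                     p_adj = runif(n, 0.2, 1),
                     stringsAsFactors = FALSE)
    # one clearly depleted gene with all six sgRNAs significant
    hit <- rec$gene == "SLC003"
    st$log2_fold_change[hit] <- -2
    st$p_adj[hit] <- 1e-6
    gr <- aggregateGenes(st, lib, nPerm = 500L, seed = 4L)
    expect_equal(gr$gene[1L], "SLC003")
    expect_equal(gr$n_sig_sgrnas[gr$gene == "SLC003"], 6L)
    expect_equal(gr$direction[gr$gene == "SLC003"], "depleted")
    expect_lt(gr$mean_lfc[gr$gene == "SLC003"], 0)
    expect_false(any(grepl("NonTargeting", gr$gene)))
    expect_true(all(abs(gr$es) <= 1))
    expect_true(all(gr$n_sig_sgrnas <= gr$n_sgrnas))
    # BH monotone in p_perm
    ord <- order(gr$p_perm)
    expect_true(all(diff(gr$p_adj[ord]) >= -1e-15))
})

test_that("genes without ranked sgRNAs are dropped with a warning", {
    lib <- tinyLibrary(nGenes = 3L)
    rec <- guides(lib)
    st <- data.frame(sgrna_id = rec$sgrna_id, gene = rec$gene,
                     log2_fold_change = rnorm(nrow(rec)),
                     p_adj = runif(nrow(rec)), stringsAsFactors = FALSE)
    st$p_adj[rec$gene == "SLC002"] <- NA  # whole gene undefined
    expect_warning(gr <- aggregateGenes(st, lib, nPerm = 200L, seed = 1L),
                   "SLC002")
    expect_false("SLC002" %in% gr$gene)
})
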