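nbMatrix <- function(n, mu, alpha, nPer = 3L, seed = 1L, ratio = 1) {
    set.seed(seed)
    muMat <- cbind(matrix(mu, n, nPer), matrix(mu * ratio, n, nPer))
    k <- matrix(rnbinom(n * 2L * nPer, mu = muMat,
                        size = if (alpha > 0) 1 / alpha else Inf),
                nrow = n,
                dimnames = list(sprintf("g%04d", seq_len(n)),
                                c(sprintf("A%d", seq_len(nPer)),
                                  sprintf("B%d", seq_len(nPer)))))
    k
}
design6 <- factor(rep(c("A", "B"), each = 3L))

test_that("size factors follow the median-of-ratios definition", {
    m <- matrix(c(10L, 20L, 30L, 10L, 20L, 30L), ncol = 2L,
                dimnames = list(c("a", "b", "c"), c("s1", "s2")))
    expect_equal(unname(sizeFactors(m)), c(1, 1))
    m2 <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
    rownames(m2) <- c("a", "b", "c")
    expect_equal(unname(sizeFactors(m2)), c(1 / sqrt(2), sqrt(2)),
                 tolerance = 1e-12)
    set.seed(5)
    big <- matrix(rpois(1200, 50) + 1L, ncol = 6L)
    dimnames(big) <- list(sprintf("g%d", 1:200), sprintf("s%d", 1:6))
    expect_equal(unname(sizeFactors(big)), bruteSizeFactors(big))
})

test_that("size factors agree with DESeq2's estimator", {
    skip_if_not_installed("DESeq2")
    set.seed(8)
    m <- matrix(rnbinom(3000, mu = 200, size = 10) + 1L, ncol = 6L)
    dimnames(m) <- list(sprintf("g%d", 1:500), sprintf("s%d", 1:6))
    # DESeq2 takes the median on the log-ratio scale; with an even number
    # of rows the two medians interpolate differently, so agreement is to
    # interpolation error, not machine precision
    expect_equal(unname(sizeFactors(m)),
                 unname(DESeq2::estimateSizeFactorsForMatrix(m)),
                 tolerance = 1e-4)
})

test_that("zero-heavy matrices need the pseudo-reference fallback", {
    m <- matrix(c(0L, 5L, 0L, 4L, 0L, 6L), ncol = 2L,
                dimnames = list(c("a", "b", "c"), c("s1", "s2")))
    expect_error(sizeFactors(m), "pseudoReference")
    sf <- sizeFactors(m, pseudoReference = TRUE)
    expect_true(all(sf > 0))
})

test_that("dispersion estimation recovers planted overdispersion", {
    kPois <- nbMatrix(5000L, mu = 500, alpha = 0, seed = 21L)
    dmP <- estimateGuideDispersions(kPois, design = design6)
    expect_lte(median(dmP@final), 0.01)

    kNb <- nbMatrix(5000L, mu = 500, alpha = 0.1, seed = 22L)
    dmN <- estimateGuideDispersions(kNb, design = design6)
    expect_gte(median(dmN@final), 0.05)
    expect_lte(median(dmN@final), 0.2)

    const <- matrix(7L, nrow = 50L, ncol = 6L,
                    dimnames = list(sprintf("g%d", 1:50),
                                    sprintf("s%d", 1:6)))
    dmC <- estimateGuideDispersions(const, design = design6)
    expect_true(all(dmC@raw == 0))

    expect_error(estimateGuideDispersions(kPois[, c(1, 4)],
                                          design = factor(c("A", "B"))),
                 "at least 2 replicates")
})

test_that("Wald test handles identity, zeros and planted effects", {
    m <- nbMatrix(100L, mu = 300, alpha = 0.05, seed = 31L)
    m[, 4:6] <- m[, 1:3]                   # group B duplicates group A
    st <- guideWaldTest(m, contrast = c("A", "B"), design = design6,
                        dispersions = rep(0.05, nrow(m)))
    expect_true(all(st$log2_fold_change == 0))
    expect_true(all(st$wald_z == 0))
    expect_true(all(st$p_value == 1))

    m2 <- nbMatrix(50L, mu = 300, alpha = 0.05, seed = 32L)
    m2[7L, ] <- 0L
    st2 <- guideWaldTest(m2, contrast = c("A", "B"), design = design6)
    expect_true(st2$all_zero[7L])
    expect_true(is.na(st2$p_value[7L]))
    expect_false(any(is.na(st2$p_value[-7L])))

    # 4-fold depletion planted in 10% of guides (normalization must stay
    # anchored on the unchanged majority): mean planted LFC near -2
    lfcs <- vapply(1:5, function(s) {
        set.seed(40L + s)
        n <- 500L
        mu <- matrix(500, n, 6L)
        planted <- seq_len(50L)
        mu[planted, 4:6] <- 2000      # enriched in B = depleted from A
        k <- matrix(rnbinom(n * 6L, mu = mu, size = 1 / 0.05), nrow = n,
                    dimnames = list(sprintf("g%03d", 1:n),
                                    c("A1", "A2", "A3", "B1", "B2", "B3")))
        st <- guideWaldTest(k, contrast = c("A", "B"), design = design6)
        mean(st$log2_fold_change[planted])
    }, numeric(1L))
    expect_equal(mean(lfcs), -2, tolerance = 0.15)
})

test_that("null NB counts give calibrated type-I error", {
    k <- nbMatrix(10000L, mu = 500, alpha = 0.05, seed = 51L)
    st <- guideWaldTest(k, contrast = c("A", "B"), design = design6)
    frac <- mean(st$p_value < 0.05)
    expect_gte(frac, 0.03)
    expect_lte(frac, 0.07)
})

test_that("label swap negates LFC and z and keeps p", {
    k <- nbMatrix(300L, mu = 200, alpha = 0.08, seed = 61L)
    a <- guideWaldTest(k, contrast = c("A", "B"), design = design6)
    b <- guideWaldTest(k, contrast = c("B", "A"), design = design6)
    expect_equal(b$log2_fold_change, -a$log2_fold_change, tolerance = 1e-12)
    expect_equal(b$wald_z, -a$wald_z, tolerance = 1e-12)
    expect_equal(b$p_value, a$p_value, tolerance = 1e-12)
})

test_that("rescaling one sample is absorbed by normalization", {
    k <- nbMatrix(500L, mu = 300, alpha = 0.05, seed = 71L)
    a <- guideWaldTest(k, contrast = c("A", "B"), design = design6)
    k2 <- k; k2[, 2L] <- k2[, 2L] * 4L
    b <- guideWaldTest(k2, contrast = c("A", "B"), design = design6)
    expect_equal(b$log2_fold_change, a$log2_fold_change, tolerance = 1e-9)
    expect_equal(b$p_value, a$p_value, tolerance = 0.02)
})

test_that("BH adjustment matches its definition exactly", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L))
    expect_equal(bhAdjust(0.37), 0.37)
    set.seed(81)
    p <- runif(1000)
    expect_equal(bhAdjust(p), bruteBH(p), tolerance = 1e-14)
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
    expect_error(bhAdjust(c(0.5, -0.1)), "\\[0, 1\\]")
    # monotone in p within a run
    q <- bhAdjust(p)
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-15))
})
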