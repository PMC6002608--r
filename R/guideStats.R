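#' Median-of-ratios size factors
#'
#' The reference abundance of each sgRNA is its geometric mean across
#' samples (rows containing any zero are excluded); a sample's size factor
#' is the median over sgRNAs of the ratio of its counts to the reference.
#' With `pseudoReference = TRUE` the geometric mean is taken over positive
#' counts only, so libraries without a single all-nonzero row remain
#' normalizable.
#'
#' @param object a [ScreenCounts-class] or a count matrix.
#' @param pseudoReference fall back to a positive-counts geometric mean.
#' @return Positive numeric vector of per-sample size factors.
#' @examples
#' m <- matrix(c(10, 20, 20, 40), nrow = 2,
#'             dimnames = list(c("a", "b"), c("s1", "s2")))
#' sizeFactors(m)
#' @export
setMethod("sizeFactors", "ScreenCounts", function(object, ...)
    medianOfRatios(assay(object, "counts"), ...))

#' @rdname sizeFactors-ScreenCounts-method
#' @export
setMethod("sizeFactors", "matrix", function(object, ...)
    medianOfRatios(object, ...))

medianOfRatios <- function(counts, pseudoReference = FALSE) {
    counts <- as.matrix(counts)
    if (any(counts < 0)) stop("counts must be non-negative")
    logc <- log(counts)
    if (pseudoReference) {
        logc[!is.finite(logc)] <- NA
        ref <- exp(rowMeans(logc, na.rm = TRUE))
        use <- rowSums(counts) > 0
    } else {
        use <- rowSums(counts > 0) == ncol(counts)
        if (!any(use))
            stop("no sgRNA has nonzero counts in every sample; ",
                 "re-run with pseudoReference = TRUE")
        ref <- exp(rowMeans(logc))
    }
    ratios <- counts[use, , drop = FALSE] / ref[use]
    # zero counts carry no ratio information (relevant under the
    # pseudo-reference, where rows may contain zeros)
    ratios[counts[use, , drop = FALSE] == 0] <- NA
    sf <- apply(ratios, 2L, stats::median, na.rm = TRUE)
    if (any(!is.finite(sf) | sf <= 0))
        stop("degenerate size factor for sample(s): ",
             paste(colnames(counts)[!is.finite(sf) | sf <= 0],
                   collapse = ", "))
    sf
}

#' Estimate negative-binomial dispersions
#'
#' Per-sgRNA method-of-moments estimate on normalized counts,
#' `alpha_i = max(0, (withinVar_i - mean_i) / mean_i^2)` with the
#' within-group variance pooled over the design groups, followed by a
#' robust fit of the mean-dispersion trend `alpha(mu) = a1/mu + a0` over
#' sgRNAs with positive raw estimates, and log-space shrinkage of the raw
#' values toward the trend.
#'
#' @param object a [ScreenCounts-class] or count matrix.
#' @param sizeFactors per-sample size factors (computed if missing).
#' @param design factor of group membership per sample; defaults to the
#'   `population` column of the colData.
#' @param weight shrinkage weight toward the trend in log space (0 = raw,
#'   1 = trend; default 0.5).
#' @param floor lower bound on the final dispersion (default 1e-8).
#' @return A [DispersionModel-class].
#' @export
estimateGuideDispersions <- function(object, sizeFactors = NULL,
                                     design = NULL, weight = 0.5,
                                     floor = 1e-8) {
    counts <- if (is(object, "ScreenCounts")) assay(object, "counts")
              else as.matrix(object)
    if (is.null(design) && is(object, "ScreenCounts"))
        design <- factor(colData(object)$population)
    if (is.null(design)) stop("a design factor is required for a matrix input")
    design <- factor(design)
    if (any(table(design) < 2L))
        stop("at least 2 replicates per group are required to estimate ",
             "dispersions (groups: ",
             paste(sprintf("%s=%d", levels(design), table(design)),
                   collapse = ", "), ")")
    if (is.null(sizeFactors)) sizeFactors <- medianOfRatios(counts)
    k <- sweep(counts, 2L, sizeFactors, "/")
    mu <- rowMeans(k)
    groups <- levels(design)
    ss <- 0; df <- 0
    for (g in groups) {
        kg <- k[, design == g, drop = FALSE]
        m <- rowMeans(kg)
        ss <- ss + rowSums((kg - m)^2)
        df <- df + ncol(kg) - 1L
    }
    withinVar <- ss / df
    raw <- pmax(0, (withinVar - mu) / mu^2)
    raw[!is.finite(raw)] <- 0
    coef <- fitDispersionTrend(raw, mu)
    trend <- pmax(coef[["a1"]] / mu + coef[["a0"]], floor)
    trend[!is.finite(trend)] <- floor
    # Log-space mixing uses the chi-square log-bias correction for the
    # method-of-moments estimate (E[log(chisq_d/d)] = digamma(d/2) -
    # log(d/2)), the standard correction for averaging log variances;
    # without it the geometric mean is systematically low at small df.
    # Zero raw estimates carry no log-space information and take the trend.
    logBias <- digamma(df / 2) - log(df / 2)
    final <- trend
    pos <- raw > 0
    final[pos] <- exp((1 - weight) * (log(raw[pos]) - logBias) +
                      weight * log(trend[pos]))
    final <- pmax(final, floor)
    new("DispersionModel", raw = raw, trendCoef = coef, trend = trend,
        final = final, baseMean = mu, weight = weight, floor = floor)
}

# robust a1/mu + a0 trend over positive raw dispersions: a gamma-family
# GLM targets the conditional mean of the right-skewed raw estimates, with
# extreme outliers (beyond 15x either side of the running fit) dropped and
# the fit repeated, in the manner of mean-dispersion trend fits for
# sequencing counts
fitDispersionTrend <- function(raw, mu) {
    use <- raw > 0 & is.finite(mu) & mu > 0
    fallback <- c(a0 = max(stats::median(raw[use]), 0), a1 = 0)
    if (sum(use) < 10L) {
        if (!any(use)) fallback[["a0"]] <- 0
        return(fallback)
    }
    x <- 1 / mu[use]
    y <- raw[use]
    keep <- rep(TRUE, length(y))
    cf <- NULL
    for (it in 1:3) {
        fit <- tryCatch(
            suppressWarnings(stats::glm(y ~ x, subset = keep,
                                        family = stats::Gamma(link = "identity"),
                                        start = c(stats::median(y[keep]), 0))),
            error = function(e) NULL)
        if (is.null(fit)) return(fallback)
        cf <- stats::coef(fit)
        pred <- pmax(cf[[1L]] + cf[[2L]] * x, 1e-12)
        newKeep <- y < 15 * pred & y > pred / 15
        if (all(newKeep == keep)) break
        keep <- newKeep
        if (sum(keep) < 10L) return(fallback)
    }
    c(a0 = max(cf[[1L]], 0), a1 = max(cf[[2L]], 0))
}

#' @describeIn estimateGuideDispersions final (shrunk, floored) dispersions.
#' @export
setMethod("dispersions", "DispersionModel", function(object) object@final)

setMethod("show", "DispersionModel", function(object) {
    cat("DispersionModel over", length(object@final), "sgRNAs\n")
    cat(sprintf("  trend: %.3g/mu + %.3g; shrinkage weight %.2f\n",
                object@trendCoef[["a1"]], object@trendCoef[["a0"]],
                object@weight))
    cat(sprintf("  median final dispersion: %.4g\n",
                stats::median(object@final)))
})

#' Per-sgRNA negative-binomial Wald test
#'
#' Two-group differential abundance on normalized counts. Group means are
#' closed-form (the mean of normalized counts per group, with a pseudo-count
#' applied only when a group mean is zero); the log2 fold change contrasts
#' the first population against the second; the standard error comes from
#' the NB information, `SE = sqrt(sum_g (1/mu_g + alpha) / n_g) / ln 2`;
#' `z = LFC/SE` is referred to the standard normal, two-sided, and p-values
#' are Benjamini-Hochberg adjusted.
#'
#' sgRNAs with zero counts everywhere get `NA` statistics (flagged in
#' `all_zero`) and are excluded from the adjustment and later ranking.
#'
#' @param object a [ScreenCounts-class] or count matrix.
#' @param contrast length-2 character, populations to compare
#'   (default `c("PhagoLate", "PhagoNeg")`).
#' @param sizeFactors,dispersions precomputed inputs (computed if missing);
#'   `dispersions` may be a [DispersionModel-class] or a numeric vector.
#' @param design factor per sample when `object` is a matrix.
#' @param pseudocount value substituted for a zero group mean (default 0.5).
#' @return data.frame with one row per sgRNA: `sgrna_id`, `gene`,
#'   `base_mean`, `log2_fold_change`, `standard_error`, `wald_z`, `p_value`,
#'   `p_adj`, `all_zero`.
#' @export
guideWaldTest <- function(object, contrast = c("PhagoLate", "PhagoNeg"),
                          sizeFactors = NULL, dispersions = NULL,
                          design = NULL, pseudocount = 0.5) {
    counts <- if (is(object, "ScreenCounts")) assay(object, "counts")
              else as.matrix(object)
    if (is.null(design) && is(object, "ScreenCounts"))
        design <- factor(colData(object)$population)
    if (is.null(design)) stop("a design factor is required for a matrix input")
    design <- as.character(design)
    if (length(contrast) != 2L || !all(contrast %in% design))
        stop("contrast must name two populations present in the design")
    keep <- design %in% contrast
    counts <- counts[, keep, drop = FALSE]
    design <- factor(design[keep], levels = contrast)
    if (is.null(sizeFactors)) sizeFactors <- medianOfRatios(counts)
    else sizeFactors <- sizeFactors[keep]
    if (is.null(dispersions))
        dispersions <- estimateGuideDispersions(counts,
                                                sizeFactors = sizeFactors,
                                                design = design)
    alpha <- if (is(dispersions, "DispersionModel")) dispersions@final
             else dispersions
    k <- sweep(counts, 2L, sizeFactors, "/")
    inA <- design == contrast[1L]
    nA <- sum(inA); nB <- sum(!inA)
    muA <- rowMeans(k[, inA, drop = FALSE])
    muB <- rowMeans(k[, !inA, drop = FALSE])
    allZero <- muA == 0 & muB == 0
    muA0 <- ifelse(muA == 0, pseudocount, muA)
    muB0 <- ifelse(muB == 0, pseudocount, muB)
    lfc <- log2(muA0 / muB0)
    se <- sqrt((1 / muA0 + alpha) / nA + (1 / muB0 + alpha) / nB) / log(2)
    z <- lfc / se
    p <- 2 * stats::pnorm(-abs(z))
    lfc[allZero] <- NA_real_; se[allZero] <- NA_real_
    z[allZero] <- NA_real_; p[allZero] <- NA_real_
    padj <- rep(NA_real_, length(p))
    padj[!allZero] <- bhAdjust(p[!allZero])
    geneCol <- if (is(object, "ScreenCounts") &&
                   "gene" %in% colnames(rowData(object)))
        rowData(object)$gene else NA_character_
    data.frame(sgrna_id = rownames(counts), gene = geneCol,
               base_mean = rowMeans(k),
               log2_fold_change = lfc, standard_error = se, wald_z = z,
               p_value = p, p_adj = padj, all_zero = allZero,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (`q_(i) = min_{k >= i} p_(k) m / k`, capped at 1,
#' in the original order). Input outside `[0, 1]` is an error.
#'
#' @param p numeric vector of p-values.
#' @return Adjusted p-values in input order.
#' @export
bhAdjust <- function(p) {
    if (!length(p)) return(numeric(0L))
    if (anyNA(p) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1] and contain no NA")
    stats::p.adjust(p, method = "BH")
}
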