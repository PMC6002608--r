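#' Derive quadrant-gate thresholds from a negative control
#'
#' Each channel's cut is a high quantile (default 0.995) of a
#' negative-control event population — a reproducible surrogate for manual
#' gate placement.
#'
#' @param controlEvents data.frame with columns `yg`, `phrodo`.
#' @param quantile quantile used for both channels (default 0.995).
#' @return A [GateThresholds-class].
#' @export
fitGateThresholds <- function(controlEvents, quantile = 0.995) {
    checkEvents(controlEvents)
    if (nrow(controlEvents) < 100L)
        stop("at least 100 control events are required (got ",
             nrow(controlEvents), ")")
    new("GateThresholds",
        ygCut = unname(stats::quantile(controlEvents$yg, quantile,
                                       type = 7)),
        phrodoCut = unname(stats::quantile(controlEvents$phrodo, quantile,
                                           type = 7)))
}

checkEvents <- function(events) {
    if (!all(c("yg", "phrodo") %in% colnames(events)))
        stop("events need columns 'yg' and 'phrodo'")
    if (nrow(events) &&
        (any(!is.finite(events$yg)) || any(!is.finite(events$phrodo)) ||
         any(events$yg <= 0) || any(events$phrodo <= 0)))
        stop("intensities must be finite and positive")
    invisible(TRUE)
}

#' Classify events into phagocytosis stages
#'
#' Quadrant semantics of the two-channel readout: YG at or below its cut is
#' PhagoNeg (no uptake); YG above with pHrodo at or below its cut is
#' PhagoEarly (cargo taken up, phagosome not acidified); both above is
#' PhagoLate (uptake plus acidification). The YG-negative/pHrodo-positive
#' quadrant cannot be phagocytosis-positive without the uptake marker and
#' is assigned PhagoNeg; its size is reported by [gateFractions()]
#' diagnostics.
#'
#' @param events data.frame with columns `yg`, `phrodo`.
#' @param thresholds a [GateThresholds-class].
#' @return Character vector of labels.
#' @export
classifyEvents <- function(events, thresholds) {
    stopifnot(is(thresholds, "GateThresholds"))
    checkEvents(events)
    ifelse(events$yg <= thresholds@ygCut, "PhagoNeg",
           ifelse(events$phrodo <= thresholds@phrodoCut,
                  "PhagoEarly", "PhagoLate"))
}

#' Per-replicate gate fractions
#'
#' @param labels character vector from [classifyEvents()].
#' @param events optional events table; when supplied together with
#'   `thresholds`, the anomalous YG-/pHrodo+ quadrant is counted in the
#'   `n_yg_negative_phrodo_positive` diagnostic.
#' @param thresholds optional [GateThresholds-class] for the diagnostic.
#' @return list with `phago_neg`, `phago_early`, `phago_late` (proportions
#'   summing to 1), `n_events`, and the diagnostic count when computable.
#' @export
gateFractions <- function(labels, events = NULL, thresholds = NULL) {
    if (!length(labels)) stop("no events to summarize")
    bad <- setdiff(unique(labels), c("PhagoNeg", "PhagoEarly", "PhagoLate"))
    if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
    n <- length(labels)
    out <- list(phago_neg = sum(labels == "PhagoNeg") / n,
                phago_early = sum(labels == "PhagoEarly") / n,
                phago_late = sum(labels == "PhagoLate") / n,
                n_events = n)
    if (!is.null(events) && !is.null(thresholds))
        out$n_yg_negative_phrodo_positive <-
            sum(events$yg <= thresholds@ygCut &
                events$phrodo > thresholds@phrodoCut)
    out
}

#' Welch's two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom, two-sided, plus the mean difference (A minus B) with its 95%
#' confidence interval. Degenerate inputs (zero variance in both groups)
#' return `p = 1` for equal means and `p = 0` (flagged) otherwise.
#'
#' @param groupA,groupB numeric vectors, each of length >= 2.
#' @param conf confidence level for the interval (default 0.95).
#' @return list: `t`, `df`, `p_value`, `mean_difference`, `conf_int`,
#'   `degenerate`.
#' @export
welchTTest <- function(groupA, groupB, conf = 0.95) {
    if (length(groupA) < 2L || length(groupB) < 2L)
        stop("each group needs at least 2 values")
    if (stats::var(groupA) == 0 && stats::var(groupB) == 0) {
        d <- mean(groupA) - mean(groupB)
        return(list(t = if (d == 0) 0 else sign(d) * Inf,
                    df = NA_real_, p_value = if (d == 0) 1 else 0,
                    mean_difference = d, conf_int = c(d, d),
                    degenerate = TRUE))
    }
    fit <- stats::t.test(groupA, groupB, var.equal = FALSE,
                         conf.level = conf)
    list(t = unname(fit$statistic), df = unname(fit$parameter),
         p_value = fit$p.value,
         mean_difference = unname(diff(rev(fit$estimate))),
         conf_int = as.numeric(fit$conf.int), degenerate = FALSE)
}

#' Wilcoxon-Mann-Whitney test
#'
#' Exact two-sided p-value by enumeration of the U distribution when the
#' combined sample size is at most 12 and there are no ties; otherwise a
#' normal approximation with tie correction. All-identical data return
#' `p = 1`.
#'
#' @param groupA,groupB numeric vectors, each of length >= 3.
#' @return list: `U` (for group A), `p_value`, `exact`.
#' @export
mannWhitneyTest <- function(groupA, groupB) {
    if (length(groupA) < 3L || length(groupB) < 3L)
        stop("each group needs at least 3 values")
    n <- length(groupA); m <- length(groupB)
    ties <- anyDuplicated(c(groupA, groupB)) > 0L
    if (length(unique(c(groupA, groupB))) == 1L)
        return(list(U = n * m / 2, p_value = 1, exact = FALSE))
    exact <- (n + m) <= 12L && !ties
    fit <- suppressWarnings(
        stats::wilcox.test(groupA, groupB, exact = exact, correct = TRUE))
    list(U = unname(fit$statistic), p_value = min(1, fit$p.value),
         exact = exact)
}

#' Percentage of surviving intracellular bacteria
#'
#' Gentamicin-protection readout: surviving colony-forming units at time t
#' relative to time zero, as a percentage (may exceed 100 when bacteria
#' replicate intracellularly).
#'
#' @param cfuT CFU count at time t.
#' @param cfu0 CFU count at time zero (> 0).
#' @return `100 * cfuT / cfu0`.
#' @export
survivalPercentage <- function(cfuT, cfu0) {
    if (any(cfu0 <= 0)) stop("cfu0 must be positive")
    if (any(cfuT < 0)) stop("cfuT must be non-negative")
    100 * cfuT / cfu0
}
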