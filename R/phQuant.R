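#' Fit the BCECF in-situ calibration curve
#'
#' Nonlinear least squares of the four-parameter sigmoid
#' `R(pH) = rMin + (rMax - rMin) / (1 + 10^(hill * (pKa - pH)))` to
#' (pH, 490/440 emission ratio) calibration points obtained in
#' nigericin/valinomycin-clamped potassium buffers. Initialization is
#' multi-start: rMin/rMax from the data extremes, pKa from the half-max
#' crossing, hill over {0.5, 1, 2}; the best converged fit by residual sum
#' of squares wins.
#'
#' @param ph calibration pH values (>= 5 distinct values spanning >= 3 pH
#'   units).
#' @param ratio measured emission ratios.
#' @return A [CalibrationCurve-class].
#' @examples
#' d <- simulateBcecf(noiseSd = 0, seed = 1)$calibration
#' fitCalibration(d$ph, d$ratio)
#' @export
fitCalibration <- function(ph, ratio) {
    if (length(ph) != length(ratio)) stop("ph and ratio lengths differ")
    ok <- is.finite(ph) & is.finite(ratio)
    ph <- ph[ok]; ratio <- ratio[ok]
    if (length(unique(ph)) < 5L)
        stop("at least 5 distinct pH points are required")
    if (diff(range(ph)) < 3)
        stop("calibration must span at least 3 pH units")
    rho <- suppressWarnings(stats::cor(ph, ratio, method = "spearman"))
    if (!is.finite(rho) || abs(rho) < 0.5)
        stop("calibration not sigmoidal: ratio is not monotone in pH ",
             sprintf("(Spearman rho = %.2f)", rho))
    if (rho < 0)
        stop("calibration ratio must increase with pH ",
             "(490/440 convention); found a decreasing trend")
    span <- diff(range(ratio))
    rMin0 <- min(ratio) - 0.05 * span
    rMax0 <- max(ratio) + 0.05 * span
    half <- (min(ratio) + max(ratio)) / 2
    pKa0 <- ph[which.min(abs(ratio - half))]
    model <- ratio ~ rMin + (rMax - rMin) / (1 + 10^(hill * (pKa - pH)))
    dat <- data.frame(pH = ph, ratio = ratio)
    best <- NULL; bestRss <- Inf
    for (hill0 in c(0.5, 1, 2)) {
        fit <- tryCatch(
            minpack.lm::nlsLM(model, data = dat,
                              start = list(rMin = rMin0, rMax = rMax0,
                                           pKa = pKa0, hill = hill0),
                              lower = c(rMin = -Inf, rMax = -Inf,
                                        pKa = min(ph), hill = 1e-3),
                              upper = c(rMin = Inf, rMax = Inf,
                                        pKa = max(ph), hill = 20),
                              control = minpack.lm::nls.lm.control(
                                  maxiter = 200)),
            error = function(e) NULL)
        if (is.null(fit)) next
        rss <- sum(stats::residuals(fit)^2)
        if (rss < bestRss) { best <- fit; bestRss <- rss }
    }
    if (is.null(best))
        stop("calibration fit failed to converge from any start")
    cf <- stats::coef(best)
    dfres <- max(length(ph) - 4L, 1L)
    new("CalibrationCurve",
        rMin = unname(cf[["rMin"]]), rMax = unname(cf[["rMax"]]),
        pKa = unname(cf[["pKa"]]), hill = unname(cf[["hill"]]),
        residualSd = sqrt(bestRss / dfres), converged = TRUE,
        phRange = range(ph))
}

#' @describeIn fitCalibration forward model: predicted ratio at given pH.
#' @param curve a [CalibrationCurve-class].
#' @export
setMethod("calibrationRatio", "CalibrationCurve", function(curve, ph) {
    curve@rMin + (curve@rMax - curve@rMin) /
        (1 + 10^(curve@hill * (curve@pKa - ph)))
})

#' Invert emission ratios to pH
#'
#' Closed-form inversion of the calibration sigmoid,
#' `pH = pKa - log10((rMax - rMin)/(ratio - rMin) - 1) / hill`. Ratios at
#' or beyond the asymptotes are clamped to the calibrated pH range and
#' flagged.
#'
#' @param curve a converged [CalibrationCurve-class].
#' @param ratio positive emission ratio(s).
#' @return data.frame with columns `ratio`, `ph`, `out_of_range`.
#' @export
setMethod("ratioToPh", "CalibrationCurve", function(curve, ratio) {
    if (!curve@converged) stop("calibration curve did not converge")
    if (any(!is.finite(ratio)) || any(ratio <= 0))
        stop("ratios must be finite and positive")
    inside <- ratio > curve@rMin & ratio < curve@rMax
    ph <- rep(NA_real_, length(ratio))
    ph[inside] <- curve@pKa -
        log10((curve@rMax - curve@rMin) / (ratio[inside] - curve@rMin) - 1) /
        curve@hill
    low <- !inside & ratio <= curve@rMin
    high <- !inside & ratio >= curve@rMax
    ph[low] <- curve@phRange[1L]
    ph[high] <- curve@phRange[2L]
    clamped <- ph < curve@phRange[1L] | ph > curve@phRange[2L]
    ph <- pmin(pmax(ph, curve@phRange[1L]), curve@phRange[2L])
    data.frame(ratio = ratio, ph = ph,
               out_of_range = !inside | clamped)
})

setMethod("show", "CalibrationCurve", function(object) {
    cat(sprintf(paste0("CalibrationCurve: rMin %.3f, rMax %.3f, pKa %.3f, ",
                       "hill %.3f\n  residual sd %.4g over pH [%.1f, %.1f]\n"),
                object@rMin, object@rMax, object@pKa, object@hill,
                object@residualSd, object@phRange[1L], object@phRange[2L]))
})

#' Maximum projection of a z-stack
#'
#' @param zstack 3-D numeric array `(x, y, z)` with >= 1 plane.
#' @return 2-D matrix of per-pixel maxima over z.
#' @export
maxProject <- function(zstack) {
    if (is.matrix(zstack)) zstack <- array(zstack, c(dim(zstack), 1L))
    if (length(dim(zstack)) != 3L || dim(zstack)[3L] < 1L)
        stop("zstack must be a 3-D array with at least one z plane")
    apply(zstack, c(1L, 2L), max)
}

#' Background subtraction
#'
#' Pixel-wise subtraction clamped at zero. The default background estimate
#' is the median of the lowest-decile pixels of the image itself.
#'
#' @param image 2-D numeric matrix.
#' @param background scalar, matrix of matching shape, or `NULL` for the
#'   robust low-decile default.
#' @return Background-subtracted image, non-negative.
#' @export
subtractBackground <- function(image, background = NULL) {
    if (is.null(background)) {
        lowest <- image[image <= stats::quantile(image, 0.1)]
        background <- stats::median(lowest)
    }
    if (is.matrix(background) && !all(dim(background) == dim(image)))
        stop("background image shape ",
             paste(dim(background), collapse = "x"),
             " does not match image ", paste(dim(image), collapse = "x"))
    pmax(image - background, 0)
}

#' Per-ROI mean intensities
#'
#' Means of one or two channel images over labeled regions of interest;
#' cytoplasm ROIs additionally report the 490/440 ratio of channel means.
#'
#' @param channels named list of 2-D matrices; for ratio reporting use
#'   names `ch490` and `ch440`.
#' @param roiMasks named list of logical masks (same shape as the images).
#' @param kind character vector per ROI, `"cytoplasm"` or `"phagosome"`
#'   (recycled).
#' @return data.frame: `roi`, `kind`, one `mean_<channel>` column per
#'   channel, and `ratio` (ch490/ch440 means) for cytoplasm ROIs.
#' @export
roiMeans <- function(channels, roiMasks, kind = "cytoplasm") {
    if (is.matrix(channels)) channels <- list(intensity = channels)
    if (is.null(names(roiMasks)))
        names(roiMasks) <- sprintf("roi%d", seq_along(roiMasks))
    kind <- rep_len(kind, length(roiMasks))
    dims <- dim(channels[[1L]])
    rows <- lapply(seq_along(roiMasks), function(i) {
        mask <- roiMasks[[i]]
        if (!all(dim(mask) == dims))
            stop("ROI '", names(roiMasks)[i], "' mask shape mismatch")
        if (!any(mask))
            stop("ROI '", names(roiMasks)[i], "' has an empty mask")
        means <- vapply(channels, function(ch) mean(ch[mask]), numeric(1L))
        row <- c(list(roi = names(roiMasks)[i], kind = kind[i]),
                 as.list(stats::setNames(means,
                                         paste0("mean_", names(channels)))))
        if (kind[i] == "cytoplasm" &&
            all(c("ch490", "ch440") %in% names(channels))) {
            if (means[["ch440"]] <= 0)
                stop("ROI '", names(roiMasks)[i],
                     "': zero 440 nm denominator, ratio undefined")
            row$ratio <- means[["ch490"]] / means[["ch440"]]
        } else {
            row$ratio <- NA_real_
        }
        as.data.frame(row, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
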