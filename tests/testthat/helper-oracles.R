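# Independent brute-force oracles used to cross-check the implementation.
# Each is written from the definition, not from the package code paths.

# median-of-ratios, written longhand
bruteSizeFactors <- function(mat) {
    ref <- numeric(nrow(mat))
    for (i in seq_len(nrow(mat))) {
        if (all(mat[i, ] > 0)) ref[i] <- prod(mat[i, ])^(1 / ncol(mat))
        else ref[i] <- NA
    }
    sf <- numeric(ncol(mat))
    for (j in seq_len(ncol(mat))) {
        r <- mat[, j] / ref
        sf[j] <- median(r[!is.na(r)])
    }
    sf
}

# Benjamini-Hochberg by the double-loop definition
bruteBH <- function(p) {
    m <- length(p)
    ord <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
        best <- Inf
        for (k in i:m) best <- min(best, p[ord[k]] * m / k)
        q[ord[i]] <- min(best, 1)
    }
    q
}

# weighted KS running sum, full O(N) walk
bruteES <- function(rankedIds, metric, memberIds, q) {
    N <- length(rankedIds)
    isMember <- rankedIds %in% memberIds
    w <- abs(metric)^q
    wm <- w[isMember]
    denom <- sum(wm)
    hitStep <- if (denom > 0) wm / denom else rep(1 / sum(isMember),
                                                 sum(isMember))
    missStep <- 1 / (N - sum(isMember))
    running <- 0; best <- 0; hi <- 0L
    for (i in seq_len(N)) {
        if (isMember[i]) {
            hi <- hi + 1L
            running <- running + hitStep[hi]
        } else {
            running <- running - missStep
        }
        if (abs(running) > abs(best) ||
            (abs(running) == abs(best) && running > best))
            best <- running
    }
    best
}

# Welch's t from the textbook formulas
bruteWelch <- function(a, b) {
    va <- var(a) / length(a); vb <- var(b) / length(b)
    t <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    p <- 2 * pt(-abs(t), df)
    list(t = t, df = df, p = p)
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
bruteMannWhitneyP <- function(a, b) {
    n <- length(a); m <- length(b)
    pool <- c(a, b)
    uObs <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    combos <- combn(n + m, n)
    us <- apply(combos, 2L, function(idx) {
        x <- pool[idx]; y <- pool[-idx]
        sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    })
    mu <- n * m / 2
    mean(abs(us - mu) >= abs(uObs - mu))
}

# per-pixel loops
bruteMaxProject <- function(stack) {
    out <- matrix(-Inf, dim(stack)[1L], dim(stack)[2L])
    for (x in seq_len(dim(stack)[1L]))
        for (y in seq_len(dim(stack)[2L]))
            for (z in seq_len(dim(stack)[3L]))
                out[x, y] <- max(out[x, y], stack[x, y, z])
    out
}

bruteMaskedMean <- function(img, mask) {
    tot <- 0; n <- 0L
    for (x in seq_len(nrow(img)))
        for (y in seq_len(ncol(img)))
            if (mask[x, y]) { tot <- tot + img[x, y]; n <- n + 1L }
    tot / n
}

# small library used across tests
tinyLibrary <- function(nGenes = 10L, nPerGene = 6L, nEssential = 2L,
                        nNt = 6L, seed = 42L) {
    defaultScreenLibrary(seed = seed, nSlcGenes = nGenes,
                         nSgPerGene = nPerGene,
                         nEssentialGenes = nEssential, nNonTargeting = nNt)
}
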