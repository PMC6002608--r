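#' Rank sgRNAs for gene aggregation
#'
#' Default metric: `sign(LFC) * (-log10(p_adj + 1e-300))`, sorted
#' descending, so strongly enriched sgRNAs head the list and strongly
#' depleted ones tail it. Ties break deterministically by |LFC| descending
#' then sgRNA id. sgRNAs with undefined statistics (all-zero counts) are
#' excluded. `metric = "padj_only"` ranks by `-log10(p_adj)` unsigned.
#'
#' @param stats data.frame from [guideWaldTest()].
#' @param metric `"signed_padj"` (default) or `"padj_only"`.
#' @return data.frame `sgrna_id`, `gene`, `metric`, ordered.
#' @export
rankGuides <- function(stats, metric = c("signed_padj", "padj_only")) {
    metric <- match.arg(metric)
    if (!nrow(stats)) stop("empty statistics table")
    keep <- !is.na(stats$p_adj) & !is.na(stats$log2_fold_change)
    st <- stats[keep, , drop = FALSE]
    mlp <- -log10(st$p_adj + 1e-300)
    r <- if (metric == "signed_padj") sign(st$log2_fold_change) * mlp else mlp
    ord <- order(-r, -abs(st$log2_fold_change), st$sgrna_id)
    data.frame(sgrna_id = st$sgrna_id[ord], gene = st$gene[ord],
               metric = r[ord], row.names = NULL, stringsAsFactors = FALSE)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list; at each member ("hit") the running sum rises by
#' `|r_i|^q / sum_members |r|^q` (uniform `1/m` when all member metrics are
#' zero), at each non-member it falls by `1/(N - m)`. The score is the
#' extremum of the running sum (the maximum if `|max| >= |min|`, else the
#' minimum); positive scores mean the members concentrate at the top
#' (enriched), negative at the bottom (depleted).
#'
#' @param ranked data.frame from [rankGuides()] (columns `sgrna_id`,
#'   `metric`).
#' @param memberIds sgRNA ids of the gene; must be a non-empty proper
#'   subset of the ranked list.
#' @param q weight exponent on the metric (default 1; 0 gives the classic
#'   unweighted KS statistic).
#' @return Enrichment score in `[-1, 1]`.
#' @export
enrichmentScore <- function(ranked, memberIds, q = 1) {
    pos <- match(memberIds, ranked$sgrna_id)
    if (anyNA(pos)) stop("memberIds absent from the ranked list: ",
                         paste(memberIds[is.na(pos)], collapse = ", "))
    N <- nrow(ranked)
    m <- length(pos)
    if (m == 0L) stop("member set is empty")
    if (m >= N) stop("member set must be a proper subset of the ranked list")
    esFromPositions(sort(pos), abs(ranked$metric), q, N)
}

# O(m) running-sum extremum given sorted hit positions
esFromPositions <- function(pos, absMetric, q, N) {
    m <- length(pos)
    w <- absMetric[pos]^q
    sw <- sum(w)
    w <- if (sw > 0) w / sw else rep(1 / m, m)
    cumw <- cumsum(w)
    d <- 1 / (N - m)
    atHit <- cumw - (pos - seq_len(m)) * d           # just after each hit
    beforeHit <- c(0, cumw[-m]) - (pos - seq_len(m)) * d  # just before
    esMax <- max(atHit)
    esMin <- min(beforeHit, 0)
    if (abs(esMax) >= abs(esMin)) esMax else esMin
}

#' Permutation p-value for a gene's enrichment score
#'
#' Null scores are enrichment scores of `nPerm` uniformly drawn same-size
#' sgRNA sets (without replacement within each draw). The null is
#' competitive: draws avoid the tested gene's own sgRNAs, so a genuinely
#' affected gene cannot contaminate its own reference distribution. The
#' p-value is sign-matched:
#' `p = (1 + #(|es_null| >= |es_obs| & sign match)) / (1 + #(sign match))`.
#'
#' @param ranked data.frame from [rankGuides()].
#' @param memberIds the gene's sgRNA ids.
#' @param q weight exponent.
#' @param nPerm number of permutations (>= 100).
#' @param seed integer seed.
#' @return list with `p_perm`, `es`, and `null` (summary of the null
#'   scores: mean, sd, quantiles).
#' @export
permutationPvalue <- function(ranked, memberIds, q = 1, nPerm = 10000L,
                              seed = 1L) {
    if (nPerm < 100L) stop("nPerm must be at least 100")
    es <- enrichmentScore(ranked, memberIds, q)
    pos <- match(memberIds, ranked$sgrna_id)
    nulls <- nullScores(ranked, length(pos), q, nPerm, seed, exclude = pos)
    list(p_perm = signMatchedP(es, nulls), es = es,
         null = c(mean = mean(nulls), sd = stats::sd(nulls),
                  stats::quantile(nulls, c(0.025, 0.5, 0.975))))
}

# null ES values for same-size sets drawn from the ranked list; positions in
# `exclude` (the tested gene's own sgRNAs) never enter a draw
nullScores <- function(ranked, m, q, nPerm, seed, exclude = integer(0L)) {
    draws <- nullDraws(nrow(ranked), m, nPerm, seed)
    absMetric <- abs(ranked$metric)
    N <- nrow(ranked)
    es <- vapply(seq_len(nPerm), function(i)
        esFromPositions(draws$pos[, i], absMetric, q, N), numeric(1L))
    if (length(exclude)) {
        bad <- unique(unlist(draws$byPos[exclude]))
        if (length(bad)) es <- es[-bad]
    }
    es
}

# shared pool of null sets: sorted position matrix plus an index mapping
# each ranked-list position to the draws containing it
nullDraws <- function(N, m, nPerm, seed) {
    state <- localSeed(seed)
    on.exit(restoreSeed(state))
    pos <- vapply(seq_len(nPerm), function(i) sort(sample.int(N, m)),
                  integer(m))
    pos <- matrix(pos, nrow = m)
    byPos <- vector("list", N)
    grp <- split(rep(seq_len(nPerm), each = m), as.vector(pos))
    byPos[as.integer(names(grp))] <- grp
    list(pos = pos, byPos = byPos)
}

signMatchedP <- function(es, nulls) {
    side <- if (es >= 0) nulls >= 0 else nulls < 0
    (1 + sum(abs(nulls[side]) >= abs(es))) / (1 + sum(side))
}

#' Aggregate sgRNA statistics to genes
#'
#' Step two of the screen analysis: each targeting gene (SLC and
#' essential-control categories; non-targeting sgRNAs stay in the ranked
#' list but form no gene) is scored by the enrichment of its sgRNAs in the
#' ranked list, with a competitive permutation null shared across genes of
#' equal sgRNA count (each gene uses the null draws that avoid its own
#' sgRNAs). Output is the volcano table: mean LFC (x axis), BH-adjusted
#' permutation p (y axis) and the number of individually significant
#' sgRNAs (dot size).
#'
#' @param stats data.frame from [guideWaldTest()].
#' @param library a [GuideLibrary-class].
#' @param q weight exponent (default 1).
#' @param nPerm permutations per null (default 10000).
#' @param seed integer seed.
#' @param sigLevel sgRNA-level `p_adj` threshold counted in
#'   `n_sig_sgrnas` (default 0.05).
#' @param metric ranking metric passed to [rankGuides()].
#' @return data.frame sorted by `p_adj`: `gene`, `category`, `n_sgrnas`,
#'   `mean_lfc`, `es`, `p_perm`, `p_adj`, `n_sig_sgrnas`, `direction`.
#' @export
aggregateGenes <- function(stats, library, q = 1, nPerm = 10000L, seed = 1L,
                           sigLevel = 0.05,
                           metric = c("signed_padj", "padj_only")) {
    stopifnot(is(library, "GuideLibrary"))
    ranked <- rankGuides(stats, metric = match.arg(metric))
    rec <- guides(library)
    rec <- rec[rec$category != NT_SENTINEL, , drop = FALSE]
    geneTab <- split(rec$sgrna_id, rec$gene)
    inList <- lapply(geneTab, function(ids)
        ids[ids %in% ranked$sgrna_id])
    sizes <- lengths(inList)
    empty <- names(inList)[sizes == 0L]
    if (length(empty)) {
        warning("dropping gene(s) with no ranked sgRNAs: ",
                paste(empty, collapse = ", "))
        inList <- inList[sizes > 0L]
        sizes <- sizes[sizes > 0L]
    }
    if (!length(inList)) stop("no gene has ranked sgRNAs")
    absMetric <- abs(ranked$metric)
    N <- nrow(ranked)
    # one shared pool of null sets per guide-set size; each gene then uses
    # the draws that avoid its own sgRNAs (competitive null)
    poolBySize <- lapply(stats::setNames(nm = sort(unique(sizes))),
                         function(m) {
        draws <- nullDraws(N, as.integer(m), nPerm,
                           deriveSeed(seed, as.integer(m)))
        draws$es <- vapply(seq_len(nPerm), function(i)
            esFromPositions(draws$pos[, i], absMetric, q, N), numeric(1L))
        draws
    })
    lfcOf <- stats::setNames(stats$log2_fold_change, stats$sgrna_id)
    padjOf <- stats::setNames(stats$p_adj, stats$sgrna_id)
    catOf <- stats::setNames(rec$category, rec$gene)[names(inList)]
    es <- numeric(length(inList)); pperm <- numeric(length(inList))
    meanLfc <- numeric(length(inList)); nSig <- integer(length(inList))
    for (i in seq_along(inList)) {
        ids <- inList[[i]]
        pos <- sort(match(ids, ranked$sgrna_id))
        es[i] <- esFromPositions(pos, absMetric, q, N)
        pool <- poolBySize[[as.character(length(ids))]]
        bad <- unique(unlist(pool$byPos[pos]))
        nulls <- if (length(bad)) pool$es[-bad] else pool$es
        pperm[i] <- signMatchedP(es[i], nulls)
        meanLfc[i] <- mean(lfcOf[ids])
        nSig[i] <- sum(padjOf[ids] < sigLevel, na.rm = TRUE)
    }
    out <- data.frame(gene = names(inList),
                      category = unname(catOf),
                      n_sgrnas = as.integer(sizes),
                      mean_lfc = meanLfc, es = es, p_perm = pperm,
                      p_adj = bhAdjust(pperm),
                      n_sig_sgrnas = nSig,
                      direction = ifelse(es < 0, "depleted", "enriched"),
                      row.names = NULL, stringsAsFactors = FALSE)
    # order by adjusted significance, then effect size: genes tied at the
    # permutation floor are resolved by |es| rather than by the noise in
    # the sign-split null denominators
    out[order(out$p_adj, -abs(out$es), out$p_perm, out$gene), ,
        drop = FALSE]
}

#' Volcano plot of gene-level results
#'
#' Mean LFC against `-log10(p_adj)`, point area scaled by the number of
#' individually significant sgRNAs.
#'
#' @param geneResults data.frame from [aggregateGenes()].
#' @param sigLevel horizontal reference line (default 0.05).
#' @export
plotVolcano <- function(geneResults, sigLevel = 0.05) {
    x <- geneResults$mean_lfc
    y <- -log10(pmax(geneResults$p_adj, 1e-300))
    cex <- 0.5 + geneResults$n_sig_sgrnas / max(1, max(geneResults$n_sig_sgrnas))
    plot(x, y, cex = cex, pch = 19,
         col = ifelse(geneResults$p_adj < sigLevel, "firebrick", "grey40"),
         xlab = expression(mean ~ log[2] ~ fold ~ change),
         ylab = expression(-log[10] ~ p[adj]))
    graphics::abline(h = -log10(sigLevel), lty = 2)
    lab <- geneResults$p_adj < sigLevel
    if (any(lab))
        graphics::text(x[lab], y[lab], geneResults$gene[lab],
                       pos = 3, cex = 0.7)
    invisible(NULL)
}
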