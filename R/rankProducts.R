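## core: given a features x pairs matrix of log-ratios (NA allowed), compute
## normalized rank products and one/two-sided p-values.
.rankProductCore <- function(D) {
    nFeat <- nrow(D)
    nPairs <- ncol(D)
    logUp <- numeric(nFeat)     # sum of log(rank/n_obs), "up" orientation
    logDown <- numeric(nFeat)
    keff <- integer(nFeat)
    for (j in seq_len(nPairs)) {
        d <- D[, j]
        obs <- which(!is.na(d))
        nObs <- length(obs)
        if (nObs == 0L) next
        rDown <- rank(d[obs])            # rank 1 = most negative ratio
        rUp <- nObs + 1 - rDown          # rank 1 = most positive ratio
        logDown[obs] <- logDown[obs] + log(rDown / nObs)
        logUp[obs] <- logUp[obs] + log(rUp / nObs)
        keff[obs] <- keff[obs] + 1L
    }
    ## null: product of k_eff independent Uniform(0,1]; P(prod <= rho) is the
    ## upper Gamma(k_eff, 1) tail of -log(rho)
    pUp <- ifelse(keff > 0,
                  pgamma(-logUp, shape = keff, rate = 1, lower.tail = FALSE),
                  1)
    pDown <- ifelse(keff > 0,
                    pgamma(-logDown, shape = keff, rate = 1,
                           lower.tail = FALSE),
                    1)
    p <- pmin(1, 2 * pmin(pUp, pDown))
    data.frame(rhoUp = exp(logUp), rhoDown = exp(logDown), kEff = keff,
               pUp = pUp, pDown = pDown, p = p, row.names = rownames(D))
}

#' Rank-product test
#'
#' `pairedRankProduct` computes, for each replicate pair (matched by
#' replicate index), the per-feature log-ratio treatment minus reference,
#' ranks the observed ratios within each pair (rank 1 = most negative for
#' the "down" list, most positive for the "up" list, ranks relative to the
#' features observed in that pair), and forms the normalized rank product
#' rho = prod(rank/n_obs) over the pairs in which the feature is observed.
#' One-sided p-values come from the null distribution of a product of
#' independent uniforms (Gamma tail); the two-sided p is
#' min(1, 2 min(p_up, p_down)). Features with no observed ratio get p = 1.
#'
#' `unpairedRankProduct` handles unpaired designs by averaging the paired
#' p-values over `nPairings` uniformly random bijections between the
#' replicates of the two conditions (when counts differ, min(rA, rB)
#' randomly chosen columns are matched).
#'
#' @param x a log-scale [QuantExperiment-class].
#' @param comparison a [Comparison-class].
#' @return `pairedRankProduct`: data.frame with columns `rhoUp`, `rhoDown`,
#'   `kEff`, `pUp`, `pDown`, `p`. `unpairedRankProduct`: named numeric
#'   vector of p-values.
#' @rdname rankProductTest
#' @export
setMethod("pairedRankProduct", "QuantExperiment", function(x, comparison) {
    cols <- .comparisonColumns(x, comparison)
    if (length(cols$a) != length(cols$b))
        stop("unequal replicate counts; use unpairedRankProduct()")
    v <- quantValues(x)
    D <- v[, cols$b, drop = FALSE] - v[, cols$a, drop = FALSE]
    rownames(D) <- rownames(v)
    .rankProductCore(D)
})

#' @param nPairings number of random pairings to average over (default 100).
#' @param seed optional integer seed for the random pairings.
#' @rdname rankProductTest
#' @export
setMethod("unpairedRankProduct", "QuantExperiment",
          function(x, comparison, nPairings = 100L, seed = NULL) {
    cols <- .comparisonColumns(x, comparison)
    if (!is.null(seed)) set.seed(seed)
    v <- quantValues(x)
    rA <- length(cols$a); rB <- length(cols$b)
    nMatch <- min(rA, rB)
    acc <- numeric(nrow(v))
    for (it in seq_len(nPairings)) {
        ia <- cols$a[sample.int(rA, nMatch)]
        ib <- cols$b[sample.int(rB, nMatch)]
        D <- v[, ib, drop = FALSE] - v[, ia, drop = FALSE]
        acc <- acc + .rankProductCore(D)$p
    }
    stats::setNames(acc / nPairings, rownames(v))
})
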