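#' Permutation-test statistic
#'
#' The effect-size statistic of the permutation test. Paired:
#' u = |mean(d)/sd(d)| * n over the n complete-pair differences d. Unpaired:
#' u = |mean(b) - mean(a)| / sqrt(var(a) + var(b)) * n with n the total
#' number of non-missing values, so low replicate numbers are penalized
#' through the multiplier. A zero denominator gives u = 0 when the numerator
#' is also zero and u = Inf otherwise.
#'
#' @param aValues,bValues observed values of the two groups; for paired
#'   designs the vectors are aligned by pair and pairs with a missing member
#'   are dropped.
#' @param paired logical.
#' @return list with `u` (the statistic) and `nObs` (the multiplier: total
#'   non-missing count, or number of complete pairs).
#' @export
permStatistic <- function(aValues, bValues, paired = FALSE) {
    if (paired) {
        if (length(aValues) != length(bValues))
            stop("paired vectors must be aligned")
        d <- bValues - aValues
        d <- d[!is.na(d)]
        n <- length(d)
        if (n == 0) return(list(u = 0, nObs = 0L))
        num <- abs(mean(d))
        den <- if (n > 1) sd(d) else 0
        u <- if (den == 0) (if (num == 0) 0 else Inf) else num / den * n
        list(u = u, nObs = n)
    } else {
        a <- aValues[!is.na(aValues)]
        b <- bValues[!is.na(bValues)]
        n <- length(a) + length(b)
        if (length(a) == 0 || length(b) == 0) return(list(u = 0, nObs = n))
        va <- if (length(a) > 1) var(a) else 0
        vb <- if (length(b) > 1) var(b) else 0
        num <- abs(mean(b) - mean(a))
        den <- sqrt(va + vb)
        u <- if (den == 0) (if (num == 0) 0 else Inf) else num / den * n
        list(u = u, nObs = n)
    }
}

#' Permutation test with low-replicate augmentation
#'
#' `augmentReplicates` brings both compared conditions up to `target`
#' replicates by appending pseudo-replicate columns whose per-feature values
#' are drawn uniformly (with replacement) from the pool of all non-missing
#' values of the compared columns; original columns are unchanged. The
#' permutation test needs this minimum number of replicates for its
#' randomization null to have enough resolution.
#'
#' `permutationTest` computes, per feature, the observed statistic
#' ([permStatistic()]) on the augmented data and compares it with `nRand`
#' randomizations of that feature's values (unpaired: random re-partitions
#' of the pooled observed values into the two group sizes; paired: random
#' sign flips of the pair differences). The p-value is the exceedance
#' fraction (#\{u_r >= u_obs\} + 1)/(nRand + 1), so it lies in
#' \[1/(nRand+1), 1\]. Features with fewer than 2 observed values in either
#' group before augmentation get p = 1.
#'
#' @param x a log-scale [QuantExperiment-class].
#' @param comparison a [Comparison-class].
#' @param target minimum replicates per condition after augmentation
#'   (default 7).
#' @param seed optional integer seed (augmentation and randomizations).
#' @return `augmentReplicates`: a [QuantExperiment-class] restricted to the
#'   compared conditions with >= `target` replicates each.
#'   `permutationTest`: named numeric vector of p-values.
#' @rdname permutationTest
#' @export
setMethod("augmentReplicates", "QuantExperiment",
          function(x, comparison, target = 7L, seed = NULL) {
    cols <- .comparisonColumns(x, comparison)
    if (!is.null(seed)) set.seed(seed)
    v <- quantValues(x)
    pool <- v[, c(cols$a, cols$b), drop = FALSE]
    pool <- pool[!is.na(pool)]
    nA <- length(cols$a); nB <- length(cols$b)
    needA <- max(0L, target - nA); needB <- max(0L, target - nB)
    if ((needA > 0 || needB > 0) && length(pool) == 0L)
        stop("cannot augment: no non-missing values in the compared columns")
    keep <- c(cols$a, cols$b)
    newV <- v[, keep, drop = FALSE]
    cond <- sampleConditions(x)[keep]
    nFeat <- nrow(v)
    addCols <- function(m, cn, need, haveN) {
        if (need == 0) return(m)
        add <- matrix(pool[sample.int(length(pool), nFeat * need,
                                      replace = TRUE)], nFeat,
                      dimnames = list(rownames(v),
                                      paste0(cn, "_aug", seq_len(need) + haveN)))
        cbind(m, add)
    }
    outA <- addCols(newV[, seq_len(nA), drop = FALSE],
                    comparison@conditionA, needA, nA)
    outB <- addCols(newV[, nA + seq_len(nB), drop = FALSE],
                    comparison@conditionB, needB, nB)
    QuantExperiment(cbind(outA, outB),
                    condition = c(rep(comparison@conditionA, nA + needA),
                                  rep(comparison@conditionB, nB + needB)))
})

#' @param nRand number of randomizations (default 1000).
#' @rdname permutationTest
#' @export
setMethod("permutationTest", "QuantExperiment",
          function(x, comparison, nRand = 1000L, target = 7L, seed = NULL) {
    ## the statistic is symmetric in the two groups; canonicalize the
    ## condition order so relabeling a<->b gives identical p-values under
    ## the same seed
    if (comparison@conditionA > comparison@conditionB)
        comparison <- Comparison(comparison@conditionB,
                                 comparison@conditionA, comparison@paired)
    cols <- .comparisonColumns(x, comparison)
    v <- quantValues(x)
    obsA <- rowSums(!is.na(v[, cols$a, drop = FALSE]))
    obsB <- rowSums(!is.na(v[, cols$b, drop = FALSE]))
    if (!is.null(seed)) set.seed(seed)
    aug <- augmentReplicates(x, comparison, target = target)
    augCols <- .comparisonColumns(aug, comparison)
    av <- quantValues(aug)
    if (comparison@paired) {
        D <- av[, augCols$b, drop = FALSE] - av[, augCols$a, drop = FALSE]
        p <- .permNullPaired(D, as.integer(nRand))
    } else {
        p <- .permNullUnpaired(av[, augCols$a, drop = FALSE],
                               av[, augCols$b, drop = FALSE],
                               as.integer(nRand))
    }
    p[obsA < 2 | obsB < 2] <- 1
    stats::setNames(p, rownames(v))
})
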