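#' Binomial distribution of missing-value counts
#'
#' Probability of observing i = 0..r missing values among r replicates when
#' each value is missing independently with probability `pNA`:
#' b_i = C(r,i) pNA^i (1-pNA)^(r-i).
#'
#' @param r replicates per condition (>= 1).
#' @param pNA missingness probability in \[0, 1\].
#' @return numeric vector of length r + 1 (i = 0..r), summing to 1.
#' @examples
#' binomMissing(3, 0.5)   # 1/8 3/8 3/8 1/8
#' @export
binomMissing <- function(r, pNA) {
    if (length(pNA) != 1 || is.na(pNA) || pNA < 0 || pNA > 1)
        stop("'pNA' must be a single probability in [0, 1]")
    if (r < 1) stop("'r' must be >= 1")
    dbinom(0:r, size = r, prob = pNA)
}

#' Distribution of the missing-count difference between two groups
#'
#' Probability that the numbers of missing values in two groups of replicates
#' differ by k = |X - Y|, with X ~ Binomial(rA, pNA) and Y ~ Binomial(rB,
#' pNA) independent. For equal group sizes r this is
#' P_0 = sum_j b_j^2 and P_k = 2 sum_j b_(j+k) b_j for k >= 1; the k = 0
#' term is self-symmetric and is not doubled, so the vector sums to 1.
#' Unequal group sizes are handled by direct convolution of the two
#' binomials.
#'
#' @param r,rB replicate counts of the two groups (`rB` defaults to `r`).
#' @param pNA missingness probability in \[0, 1\].
#' @return numeric vector of length max(r, rB) + 1, entry k + 1 holding
#'   P(|X - Y| = k); sums to 1.
#' @examples
#' diffProbabilities(3, pNA = 0.5)   # 5/16 15/32 3/16 1/32
#' @export
diffProbabilities <- function(r, pNA, rB = r) {
    bA <- binomMissing(r, pNA)
    bB <- if (rB == r) bA else binomMissing(rB, pNA)
    kmax <- max(r, rB)
    P <- numeric(kmax + 1)
    ## P(|X - Y| = k) by convolution over the joint i x j grid
    for (k in 0:kmax) {
        s <- 0
        for (j in 0:rB) {
            i <- j + k
            if (i <= r) s <- s + bA[i + 1] * bB[j + 1]
        }
        if (k >= 1) {
            for (i in 0:r) {
                j <- i + k
                if (j <= rB) s <- s + bA[i + 1] * bB[j + 1]
            }
        }
        P[k + 1] <- s
    }
    P
}

#' Detection-limit scenario scan
#'
#' Builds the censoring scenarios of the missingness test: the distribution
#' of all non-missing values in the matrix is divided into `nQuantiles`
#' quantiles (q/nQuantiles for q = 0..nQuantiles-1); for each threshold,
#' values strictly below it are treated as missing (q = 0 reproduces the
#' unthresholded data). Each scenario records the effective missingness
#' probability p_NA (fraction of missing plus censored cells over the whole
#' matrix) and, per feature, the absolute difference k of missing counts
#' between the compared groups.
#'
#' @param x a [QuantExperiment-class] with at least one non-missing value.
#' @param comparison a [Comparison-class].
#' @param nQuantiles number of abundance thresholds (default 100).
#' @return list with `thresholds` (length `nQuantiles`), `pNA` (length
#'   `nQuantiles`, non-decreasing), `k` (features x scenarios integer
#'   matrix), `rA`, `rB`.
#' @export
scenarioScan <- function(x, comparison, nQuantiles = 100L) {
    v <- quantValues(x)
    obs <- v[!is.na(v)]
    if (length(obs) == 0L) stop("matrix has no non-missing values")
    cols <- .comparisonColumns(x, comparison)
    thr <- quantile(obs, probs = seq(0, nQuantiles - 1) / nQuantiles,
                    names = FALSE)
    nCells <- length(v)
    isna <- is.na(v)
    va <- v[, cols$a, drop = FALSE]
    vb <- v[, cols$b, drop = FALSE]
    k <- matrix(0L, nrow(v), nQuantiles)
    pNA <- numeric(nQuantiles)
    for (s in seq_len(nQuantiles)) {
        censored <- isna | (v < thr[s])     # strict: value == threshold survives
        pNA[s] <- sum(censored) / nCells
        ca <- rowSums(is.na(va) | (va < thr[s]))
        cb <- rowSums(is.na(vb) | (vb < thr[s]))
        k[, s] <- as.integer(abs(ca - cb))
    }
    list(thresholds = thr, pNA = pNA, k = k,
         rA = length(cols$a), rB = length(cols$b))
}

#' Missingness test (detection-limit scan)
#'
#' Tests each feature for a difference between two conditions by combining
#' the binomial statistics of missing-value counts with a scan over
#' abundance detection limits. For every censoring scenario from
#' [scenarioScan()], the probability P_k of the observed missing-count
#' difference k is computed under missing-at-random with the scenario's
#' p_NA; the per-feature p-value is the smallest P_k over all scenarios
#' multiplied by r + 1 (r = replicates per condition; max of the two counts
#' if unequal), capped at 1. Fully observed features still receive a valid
#' p-value because the scan introduces abundance-driven missingness.
#'
#' @param x a log-scale [QuantExperiment-class].
#' @param comparison a [Comparison-class].
#' @param nQuantiles number of detection-limit thresholds (default 100).
#' @return named numeric vector of two-group p-values, one per feature.
#' @examples
#' set.seed(1)
#' sim <- simulateDataset(nFeatures = 200, nReplicates = 3,
#'                        fracRegulated = 10, delta = 3, fracMissing = 20,
#'                        mu = 10, seed = 7)
#' p <- missTest(sim$data, Comparison("c1", "c2"))
#' head(p)
#' @rdname missTest
#' @export
setMethod("missTest", "QuantExperiment",
          function(x, comparison, nQuantiles = 100L) {
    scan <- scenarioScan(x, comparison, nQuantiles)
    nFeat <- nrow(scan$k)
    pmin_ <- rep(Inf, nFeat)
    for (s in seq_len(nQuantiles)) {
        P <- diffProbabilities(scan$rA, scan$pNA[s], scan$rB)
        pmin_ <- pmin(pmin_, P[scan$k[, s] + 1L])
    }
    p <- pmin(1, pmin_ * (max(scan$rA, scan$rB) + 1))
    stats::setNames(p, rownames(x))
})
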