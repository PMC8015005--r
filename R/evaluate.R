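#' Confusion counts at an FDR threshold
#'
#' A feature is called differentially regulated when its FDR is strictly
#' below the threshold. The true FDR is FP/(FP + TP) measured against the
#' simulation ground truth (0 by convention when nothing is detected);
#' sensitivity is TP/(TP + FN) (`NA` when there are no true positives to
#' find).
#'
#' @param fdr per-feature FDR vector (`NA` treated as 1).
#' @param truth ground-truth labels: the `regulated` column of
#'   [simulateDataset()]'s truth (non-zero = regulated), or a logical
#'   vector.
#' @param threshold FDR cutoff (strict `<`).
#' @return list with `threshold`, `TP`, `FP`, `FN`, `TN`, `trueFDR`,
#'   `sensitivity`.
#' @export
confusion <- function(fdr, truth, threshold) {
    truth <- .truthVector(truth)
    if (length(fdr) != length(truth))
        stop("'fdr' and 'truth' must have equal length")
    fdr[is.na(fdr)] <- 1
    det <- fdr < threshold
    TP <- sum(det & truth); FP <- sum(det & !truth)
    FN <- sum(!det & truth); TN <- sum(!det & !truth)
    list(threshold = threshold, TP = TP, FP = FP, FN = FN, TN = TN,
         trueFDR = if (TP + FP == 0) 0 else FP / (TP + FP),
         sensitivity = if (TP + FN == 0) NA_real_ else TP / (TP + FN))
}

.truthVector <- function(truth) {
    if (is.data.frame(truth)) truth <- truth$regulated
    if (is.numeric(truth)) truth <- truth != 0
    as.logical(truth)
}

#' ROC points from an FDR (or score) vector
#'
#' Sweeps the detection threshold over the sorted unique FDR values
#' (smaller = more significant) and reports the (FPR, TPR) path, including
#' the (0, 0) and (1, 1) endpoints; both coordinates are non-decreasing
#' along the sweep.
#'
#' @param fdr per-feature FDR vector.
#' @param truth ground-truth labels as in [confusion()]; needs at least one
#'   positive and one negative.
#' @return data.frame with columns `fpr`, `tpr`.
#' @export
rocPoints <- function(fdr, truth) {
    truth <- .truthVector(truth)
    if (length(fdr) != length(truth))
        stop("'fdr' and 'truth' must have equal length")
    nPos <- sum(truth); nNeg <- sum(!truth)
    if (nPos == 0 || nNeg == 0)
        stop("truth must contain at least one positive and one negative")
    fdr[is.na(fdr)] <- 1
    cuts <- sort(unique(fdr))
    tpr <- vapply(cuts, function(ct) sum(fdr <= ct & truth) / nPos,
                  numeric(1))
    fpr <- vapply(cuts, function(ct) sum(fdr <= ct & !truth) / nNeg,
                  numeric(1))
    data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Trapezoidal area under a ROC path
#'
#' @param roc data.frame from [rocPoints()].
#' @return AUC in \[0, 1\].
#' @export
rocAUC <- function(roc) {
    sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}

#' Null-data calibration of the missingness test
#'
#' Runs the full simulate-test-correct pipeline over a grid of pure-noise
#' datasets (no regulated features) and counts, per dataset, how many
#' features fall below the FDR threshold. Under correct calibration such
#' false positives should be rare.
#'
#' @param grid data.frame with columns `nFeatures`, `nReplicates`,
#'   `fracMissing`, `mu` and `seed` (one row per dataset).
#' @param fdrThreshold FDR cutoff (default 0.1).
#' @param nQuantiles detection-limit thresholds for the missingness test.
#' @return list with `fpCounts` (per-dataset false-positive counts),
#'   `fracAnyFP` (fraction of datasets with at least one false positive),
#'   `maxFP`, and `ksPass` (per-dataset uniformity of the raw p-values at
#'   alpha = 0.01).
#' @export
nullCalibration <- function(grid, fdrThreshold = 0.1, nQuantiles = 100L) {
    need <- c("nFeatures", "nReplicates", "fracMissing", "mu", "seed")
    if (!all(need %in% colnames(grid)))
        stop("grid must have columns ", paste(need, collapse = ", "))
    fp <- integer(nrow(grid))
    ksPass <- logical(nrow(grid))
    for (i in seq_len(nrow(grid))) {
        sim <- simulateDataset(nFeatures = grid$nFeatures[i],
                               nReplicates = grid$nReplicates[i],
                               fracRegulated = 0,
                               fracMissing = grid$fracMissing[i],
                               mu = grid$mu[i], seed = grid$seed[i])
        p <- missTest(sim$data, Comparison("c1", "c2"),
                      nQuantiles = nQuantiles)
        fp[i] <- sum(bhAdjust(p) < fdrThreshold)
        ksPass[i] <- uniformityCheck(p)$pass
    }
    list(fpCounts = fp, fracAnyFP = mean(fp > 0), maxFP = max(fp),
         ksPass = ksPass)
}

#' Kolmogorov-Smirnov uniformity check for p-values
#'
#' One-sample KS test of the p-values against Uniform(0, 1). Pure-noise
#' data should give a near-uniform p-value distribution; the check passes
#' when uniformity is not rejected at `alpha`.
#'
#' @param p vector of p-values (n >= 100).
#' @param alpha significance level of the KS test (default 0.01).
#' @return list with `statistic` (KS D), `pValue`, `pass`.
#' @export
uniformityCheck <- function(p, alpha = 0.01) {
    if (length(p) < 100)
        stop("need at least 100 p-values")
    ks <- suppressWarnings(stats::ks.test(p, "punif", exact = FALSE))
    list(statistic = unname(ks$statistic), pValue = ks$p.value,
         pass = ks$p.value >= alpha)
}
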