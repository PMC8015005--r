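#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjusted p-values (monotone, capped at 1). Features
#' carrying the p = 1 sentinel (too few observations for a test) simply
#' stay at FDR 1.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return vector of adjusted values (FDRs).
#' @export
bhAdjust <- function(p) {
    if (anyNA(p) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Storey q-values
#'
#' Adjusted p-values incorporating an estimate of the proportion of true
#' nulls pi0, estimated by the smoother method: pi0(lambda) =
#' #\{p > lambda\} / (m (1 - lambda)) over lambda = 0.05, ..., 0.95 is
#' smoothed by a cubic smoothing spline (df = 3) and evaluated at the
#' largest lambda. Falls back to pi0 = 1 (plain Benjamini-Hochberg) when
#' fewer than 100 p-values are supplied or the estimate is degenerate
#' (pi0 <= 0 or > 1); the fallback is messaged.
#'
#' @param p vector of p-values in \[0, 1\].
#' @param lambda grid for the pi0 smoother.
#' @return vector of q-values; the pi0 estimate is attached as attribute
#'   `"pi0"`.
#' @export
qvalueAdjust <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
    if (anyNA(p) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    m <- length(p)
    pi0 <- 1
    if (m >= 100) {
        pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
        fit <- try(smooth.spline(lambda, pi0l, df = 3), silent = TRUE)
        est <- if (inherits(fit, "try-error")) NA_real_ else
            predict(fit, x = max(lambda))$y
        if (is.na(est) || est <= 0 || est > 1) {
            message("degenerate pi0 estimate; falling back to pi0 = 1 (BH)")
        } else {
            pi0 <- est
        }
    } else {
        message("fewer than 100 p-values; falling back to pi0 = 1 (BH)")
    }
    q <- pmin(1, pi0 * p.adjust(p, method = "BH"))
    attr(q, "pi0") <- pi0
    q
}

#' Hommel adjustment of a small family
#'
#' Hommel's multiple-testing adjustment, valid under positive dependence;
#' equals the closed-testing procedure with Simes local tests. Used here on
#' the four per-test FDR values of one feature.
#'
#' @param p vector of at most 10 values in \[0, 1\].
#' @return adjusted vector.
#' @export
hommelAdjust <- function(p) {
    if (length(p) > 10)
        stop("hommelAdjust is meant for small families (length <= 10)")
    if (anyNA(p) || any(p < 0 | p > 1))
        stop("values must lie in [0, 1]")
    p.adjust(p, method = "hommel")
}

#' Unified FDR across the four missing-value-aware tests
#'
#' Per feature, the four per-test FDR values (moderated t, missingness
#' test, rank products, permutation test) are corrected for the four-fold
#' testing by Hommel's method and the smallest corrected value is reported.
#' The plain t-test never participates (it underestimates the FDR at low
#' replicate numbers).
#'
#' @param fdrModerated,fdrMiss,fdrRank,fdrPerm equal-length vectors of
#'   per-feature FDRs in \[0, 1\].
#' @return numeric vector of unified per-feature FDRs.
#' @export
unifiedFDR <- function(fdrModerated, fdrMiss, fdrRank, fdrPerm) {
    n <- length(fdrModerated)
    if (length(fdrMiss) != n || length(fdrRank) != n || length(fdrPerm) != n)
        stop("the four FDR vectors must have equal length")
    mat <- cbind(fdrModerated, fdrMiss, fdrRank, fdrPerm)
    if (anyNA(mat) || any(mat < 0 | mat > 1))
        stop("FDR values must lie in [0, 1]")
    vapply(seq_len(n), function(i)
        min(p.adjust(mat[i, ], method = "hommel")), numeric(1))
}

#' Route per-test corrections and build the unified FDR
#'
#' Applies the per-test multiple-testing correction (Benjamini-Hochberg for
#' the missingness, rank-product and permutation tests; Storey q-values for
#' the plain and moderated t) and, when the four non-t tests are all
#' present, adds the unified FDR column.
#'
#' @param pTables named list of per-feature p-value vectors; recognized
#'   names: `miss`, `moderated`, `rankprod`, `permutation`, `ttest`.
#' @return data.frame with one `<test>_p` and `<test>_FDR` column pair per
#'   supplied test, plus `unified_FDR` when all four non-t tests are
#'   present.
#' @export
assignCorrections <- function(pTables) {
    stopifnot(is.list(pTables), length(pTables) > 0)
    bhTests <- c("miss", "rankprod", "permutation")
    out <- list()
    fdr <- list()
    for (nm in names(pTables)) {
        p <- pTables[[nm]]
        f <- if (nm %in% bhTests) bhAdjust(p) else as.numeric(qvalueAdjust(p))
        out[[paste0(nm, "_p")]] <- p
        out[[paste0(nm, "_FDR")]] <- f
        fdr[[nm]] <- f
    }
    df <- data.frame(out, check.names = FALSE)
    four <- c("moderated", "miss", "rankprod", "permutation")
    if (all(four %in% names(fdr)))
        df$unified_FDR <- unifiedFDR(fdr$moderated, fdr$miss, fdr$rankprod,
                                     fdr$permutation)
    rownames(df) <- names(pTables[[1]])
    df
}
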