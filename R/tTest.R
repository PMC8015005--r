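#' Plain per-feature t-test
#'
#' Welch two-sample t-test on observed values (unpaired) or one-sample
#' t-test on complete-pair differences (paired), two-sided, vectorized over
#' features. Features with fewer than 2 observations in either group
#' (unpaired) or fewer than 2 complete pairs (paired) get p = 1. A feature
#' with zero variance but non-zero mean difference gets the smallest
#' positive representable p (with a warning); zero variance and zero
#' difference gives p = 1.
#'
#' This reference test is reported alongside the others but is excluded
#' from the unified FDR (it underestimates the FDR at low replicate
#' numbers).
#'
#' @param x a log-scale [QuantExperiment-class].
#' @param comparison a [Comparison-class].
#' @return named numeric vector of two-sided p-values, one per feature.
#' @rdname tTest
#' @export
setMethod("tTest", "QuantExperiment", function(x, comparison) {
    cols <- .comparisonColumns(x, comparison)
    v <- quantValues(x)
    if (comparison@paired) {
        d <- v[, cols$b, drop = FALSE] - v[, cols$a, drop = FALSE]
        n <- rowSums(!is.na(d))
        m <- .rowMeansNA(d)
        s2 <- .rowVarsNA(d)
        tt <- m / sqrt(s2 / n)
        df <- n - 1
        usable <- n >= 2
    } else {
        va <- v[, cols$a, drop = FALSE]
        vb <- v[, cols$b, drop = FALSE]
        na <- rowSums(!is.na(va)); nb <- rowSums(!is.na(vb))
        sa2 <- .rowVarsNA(va) / na
        sb2 <- .rowVarsNA(vb) / nb
        tt <- (.rowMeansNA(vb) - .rowMeansNA(va)) / sqrt(sa2 + sb2)
        ## Welch-Satterthwaite degrees of freedom
        df <- (sa2 + sb2)^2 / (sa2^2 / (na - 1) + sb2^2 / (nb - 1))
        usable <- na >= 2 & nb >= 2
    }
    p <- rep(1, nrow(v))
    ok <- usable & is.finite(tt)
    p[ok] <- 2 * pt(-abs(tt[ok]), df[ok])
    degenerate <- usable & !is.finite(tt) & !is.na(tt) # 0-variance cases
    nz <- degenerate & is.infinite(tt)                 # non-zero difference
    if (any(nz, na.rm = TRUE)) {
        warning(sum(nz), " feature(s) with zero variance and non-zero ",
                "difference; p set to smallest positive value")
        p[nz] <- .Machine$double.xmin
    }
    ## 0/0 (NaN t): identical constant groups -> no evidence
    p[usable & is.nan(tt)] <- 1
    stats::setNames(p, rownames(v))
})
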