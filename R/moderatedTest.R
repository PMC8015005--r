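#' Empirical-Bayes variance prior
#'
#' Estimates the hyperparameters (d0, s0^2) of a scaled inverse-chi-square
#' prior on per-feature variances by moment matching on the log scale:
#' under the hierarchical model s2_g ~ s0^2 F(d_g, d0), the pivot
#' e_g = log(s2_g) - digamma(d_g/2) + log(d_g/2) has mean
#' log(s0^2) + digamma(d0/2) - log(d0/2) and excess variance
#' trigamma(d0/2) beyond the sampling term trigamma(d_g/2); d0 is obtained
#' by Newton inversion of the trigamma function. When the empirical
#' variance of e_g does not exceed its expected sampling variance, the
#' variances are consistent with a common value and d0 = Inf.
#'
#' @param sampleVars per-feature sample variances (log2-abundance^2 units).
#' @param dfs per-feature residual degrees of freedom.
#' @return list with `d0` (prior degrees of freedom, possibly `Inf`) and
#'   `s0sq` (prior variance).
#' @seealso [moderatedTest()]
#' @export
fitVariancePrior <- function(sampleVars, dfs) {
    ok <- !is.na(sampleVars) & !is.na(dfs) & dfs >= 1 & sampleVars > 0
    s2 <- sampleVars[ok]
    df <- dfs[ok]
    n <- length(s2)
    if (n < 2)
        stop("need at least 2 features with df >= 1 and positive variance")
    s2 <- pmax(s2, 1e-5 * median(s2))   # guard against log of ~0 variances
    e <- log(s2) - digamma(df / 2) + log(df / 2)
    emean <- mean(e)
    evar <- sum((e - emean)^2) / (n - 1)
    excess <- evar - mean(trigamma(df / 2))
    if (is.finite(excess) && excess > 0) {
        d0 <- 2 * .trigammaInverse(excess)
        s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
        ## variances consistent with a single common value
        d0 <- Inf
        s0sq <- mean(s2)
    }
    list(d0 = d0, s0sq = s0sq)
}

## Newton inversion of trigamma on (0, Inf); vectorized
.trigammaInverse <- function(x) {
    out <- x
    lo <- x > 1e7          # y -> 0: trigamma(y) ~ 1/y^2
    out[lo] <- 1 / sqrt(x[lo])
    hi <- x < 1e-6         # y -> Inf: trigamma(y) ~ 1/y
    out[hi] <- 1 / x[hi]
    mid <- which(!lo & !hi)
    if (length(mid)) {
        y <- 0.5 + 1 / x[mid]
        for (i in 1:50) {
            tri <- trigamma(y)
            dif <- tri * (1 - tri / x[mid]) / psigamma(y, deriv = 2)
            y <- y + dif
            if (max(abs(dif / y)) < 1e-10) break
        }
        out[mid] <- y
    }
    out
}

#' Moderated t-test with variance shrinkage
#'
#' Per-feature two-group test whose variance is shrunk toward an
#' empirical-Bayes prior fitted across features: the posterior variance is
#' (d0 s0^2 + d_g s2_g)/(d0 + d_g) and the statistic
#' t = delta / (s_post * u) is referred to a t-distribution with d_g + d0
#' degrees of freedom (u = sqrt(1/n_a + 1/n_b) unpaired over observed
#' counts, sqrt(1/n_pairs) paired). Means and variances use observed values
#' only; features with residual df < 1 or an undefined effect get p = 1 so
#' the output always has one entry per feature.
#'
#' @param x a log-scale [QuantExperiment-class].
#' @param comparison a [Comparison-class].
#' @param prior optional list (d0, s0sq) from [fitVariancePrior()]; fitted
#'   from this comparison's residual variances when `NULL`.
#' @return data.frame with columns `t`, `df` (posterior), `p`, rownames =
#'   feature ids.
#' @rdname moderatedTest
#' @export
setMethod("moderatedTest", "QuantExperiment",
          function(x, comparison, prior = NULL) {
    cols <- .comparisonColumns(x, comparison)
    v <- quantValues(x)
    if (comparison@paired) {
        d <- v[, cols$b, drop = FALSE] - v[, cols$a, drop = FALSE]
        n <- rowSums(!is.na(d))
        delta <- .rowMeansNA(d)
        s2 <- .rowVarsNA(d)
        df <- n - 1
        u <- sqrt(1 / n)
    } else {
        va <- v[, cols$a, drop = FALSE]
        vb <- v[, cols$b, drop = FALSE]
        na <- rowSums(!is.na(va)); nb <- rowSums(!is.na(vb))
        delta <- .rowMeansNA(vb) - .rowMeansNA(va)
        ## pooled (equal-variance) residual variance over observed values
        ssa <- .rowVarsNA(va) * (na - 1)
        ssb <- .rowVarsNA(vb) * (nb - 1)
        ssa[na < 2] <- 0
        ssb[nb < 2] <- 0
        df <- na + nb - 2
        df[na < 1 | nb < 1] <- 0
        s2 <- ifelse(df > 0, (ssa + ssb) / df, NA_real_)
        u <- sqrt(1 / na + 1 / nb)
    }
    if (is.null(prior))
        prior <- fitVariancePrior(s2, df)
    d0 <- prior$d0; s0sq <- prior$s0sq
    usable <- df >= 1 & !is.na(delta) & is.finite(u)
    s2u <- ifelse(is.na(s2), 0, s2)
    s2post <- if (is.infinite(d0)) rep(s0sq, length(s2u)) else
        (d0 * s0sq + df * s2u) / (d0 + df)
    tt <- delta / (sqrt(s2post) * u)
    ## posterior df, capped at the pooled residual df (finite-sample guard)
    dfTotal <- pmin(df + d0, sum(df[df > 0]))
    p <- rep(1, nrow(v))
    ok <- usable & is.finite(tt)
    p[ok] <- 2 * pt(-abs(tt[ok]), dfTotal[ok])
    data.frame(t = ifelse(usable, tt, NA_real_),
               df = ifelse(usable, dfTotal, NA_real_), p = p,
               row.names = rownames(v))
})
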