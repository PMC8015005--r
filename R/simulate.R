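#' Simulate a two-condition dataset with known ground truth
#'
#' All cells are drawn i.i.d. Normal(0, 1) on the log2 scale; a fraction of
#' features ("regulated") has all replicate values of the second condition
#' shifted by +delta or -delta (direction chosen per feature with
#' probability 1/2). Abundance-dependent missingness is then introduced
#' with [removeValues()]. The defaults mirror a typical benchmark setting;
#' parameter ranges outside N 500-10000, R 3-10, regulated 0-50%, delta
#' 1-5, missing 0-50%, mu 0-100 trigger a warning (not an error).
#'
#' @param nFeatures number of features N.
#' @param nReplicates replicates per condition R.
#' @param fracRegulated percentage of regulated features (0-50).
#' @param delta displacement magnitude (log2 units).
#' @param fracMissing percentage of values removed (0-50).
#' @param mu abundance-dependence exponent of the removal weights (0 =
#'   missing at random, large = strongly low-abundance missing).
#' @param seed integer seed; the dataset is a deterministic function of it.
#' @param conditions names of the two conditions.
#' @return list with `data` (a [QuantExperiment-class], conditions `c1`,
#'   `c2`) and `truth` (data.frame: `feature`, `regulated` in -1/0/+1 --
#'   sign of the shift applied to condition 2).
#' @examples
#' sim <- simulateDataset(nFeatures = 500, nReplicates = 5,
#'                        fracRegulated = 5, delta = 2, fracMissing = 20,
#'                        mu = 10, seed = 42)
#' table(sim$truth$regulated)
#' @export
simulateDataset <- function(nFeatures = 1000, nReplicates = 5,
                            fracRegulated = 0, delta = 1.5,
                            fracMissing = 0, mu = 0, seed = NULL,
                            conditions = c("c1", "c2")) {
    if (nFeatures < 500 || nFeatures > 10000)
        warning("nFeatures outside the benchmark range 500-10000")
    if (nReplicates < 3 || nReplicates > 10)
        warning("nReplicates outside the benchmark range 3-10")
    if (fracRegulated < 0 || fracRegulated > 50)
        warning("fracRegulated outside the benchmark range 0-50%")
    if (fracRegulated > 0 && (delta < 1 || delta > 5))
        warning("delta outside the benchmark range 1-5")
    if (fracMissing < 0 || fracMissing > 50)
        warning("fracMissing outside the benchmark range 0-50%")
    if (mu < 0 || mu > 100)
        warning("mu outside the benchmark range 0-100")
    if (!is.null(seed)) set.seed(seed)
    nSamples <- 2L * nReplicates
    v <- matrix(rnorm(nFeatures * nSamples), nFeatures, nSamples)
    rownames(v) <- sprintf("F%04d", seq_len(nFeatures))
    colnames(v) <- paste0(rep(conditions, each = nReplicates), "_",
                          rep(seq_len(nReplicates), 2))
    nReg <- round(nFeatures * fracRegulated / 100)
    regulated <- integer(nFeatures)
    if (nReg > 0) {
        idx <- seq_len(nReg)   # first nReg features; labels carry the truth
        sign <- ifelse(runif(nReg) < 0.5, -1, 1)
        regulated[idx] <- sign
        cond2 <- nReplicates + seq_len(nReplicates)
        v[idx, cond2] <- v[idx, cond2] + sign * delta
    }
    qe <- QuantExperiment(v, condition = rep(conditions, each = nReplicates))
    if (fracMissing > 0)
        qe <- removeValues(qe, fracMissing, mu)
    list(data = qe,
         truth = data.frame(feature = rownames(v), regulated = regulated,
                            stringsAsFactors = FALSE))
}

#' Remove values with abundance-dependent weights
#'
#' Within each sample column, values are ranked ascending by abundance
#' (rank 1 = lowest); a cell's removal weight is (1 - rank/N)^mu, so for
#' mu > 0 low-abundance values are preferentially removed and the single
#' top-ranked value of a column is never removed. Exactly
#' round(fracMissing% of all cells) cells are removed over the whole
#' matrix by weighted sampling without replacement (exponential-key
#' sampling, distributionally identical to sequential weighted draws);
#' mu = 0 gives uniform removal. Ranks are computed once, before any
#' removal.
#'
#' @param x a [QuantExperiment-class].
#' @param fracMissing percentage of cells to remove, in \[0, 100).
#' @param mu abundance-dependence exponent (>= 0).
#' @param seed optional integer seed.
#' @return the [QuantExperiment-class] with removed cells set to missing.
#' @export
removeValues <- function(x, fracMissing, mu, seed = NULL) {
    if (fracMissing >= 100) stop("fracMissing must be < 100")
    if (fracMissing < 0) stop("fracMissing must be >= 0")
    if (fracMissing == 0) return(x)
    if (!is.null(seed)) set.seed(seed)
    v <- quantValues(x)
    n <- nrow(v)
    w <- matrix(0, n, ncol(v))
    for (j in seq_len(ncol(v))) {
        obs <- !is.na(v[, j])
        r <- rank(v[obs, j], ties.method = "first")
        w[obs, j] <- (1 - r / n)^mu     # mu = 0: 0^0 = 1, uniform
    }
    size <- round(fracMissing / 100 * length(v))
    ## exponential-key weighted sampling without replacement
    keys <- rep(-Inf, length(v))
    pos <- w > 0
    keys[pos] <- log(runif(sum(pos))) / w[pos]
    drop <- order(keys, decreasing = TRUE)[seq_len(size)]
    v[drop] <- NA_real_
    assay(x, "quant") <- v
    x
}
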