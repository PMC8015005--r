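## rowwise means/vars over observed values only (NA-aware, vectorized)
.rowMeansNA <- function(v) {
    n <- rowSums(!is.na(v))
    out <- rowSums(v, na.rm = TRUE) / n
    out[n == 0] <- NA_real_
    out
}

.rowVarsNA <- function(v) {
    n <- rowSums(!is.na(v))
    s1 <- rowSums(v, na.rm = TRUE)
    s2 <- rowSums(v * v, na.rm = TRUE)
    out <- (s2 - s1 * s1 / n) / (n - 1)
    out[n < 2] <- NA_real_
    pmax(out, 0)
}

#' Pool technical replicates by summation
#'
#' Sums quantifications of technical replicates into one column per
#' biological sample. Sums are over non-missing values; a biological sample
#' whose technical replicates are all missing stays missing. Input must be on
#' the raw (not log) scale for sums to be meaningful.
#'
#' @param x a [QuantExperiment-class] with raw-scale values.
#' @param groups named character vector or factor mapping each sample label
#'   to a biological-sample id; all members of a group must share a
#'   condition.
#' @return a [QuantExperiment-class] with one column per biological sample.
#' @rdname sumTechnicalReplicates
#' @export
setMethod("sumTechnicalReplicates", "QuantExperiment", function(x, groups) {
    groups <- stats::setNames(as.character(groups),
                              names(groups) %||% colnames(x))
    groups <- groups[colnames(x)]
    if (anyNA(groups))
        stop("every sample must be assigned to a group")
    gids <- unique(groups)
    v <- quantValues(x)
    cond <- sampleConditions(x)
    out <- matrix(NA_real_, nrow(v), length(gids),
                  dimnames = list(rownames(v), gids))
    newCond <- character(length(gids))
    for (gi in seq_along(gids)) {
        cols <- which(groups == gids[gi])
        if (length(cols) == 0L)
            stop("group '", gids[gi], "' has zero members")
        if (length(unique(cond[cols])) != 1L)
            stop("group '", gids[gi], "' spans multiple conditions")
        sub <- v[, cols, drop = FALSE]
        s <- rowSums(sub, na.rm = TRUE)
        s[rowSums(!is.na(sub)) == 0] <- NA_real_
        out[, gi] <- s
        newCond[gi] <- cond[cols[1]]
    }
    QuantExperiment(out, condition = newCond, featureMeta = rowData(x))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Log2-transform a raw-scale matrix
#'
#' @param x a [QuantExperiment-class] with raw-scale values.
#' @param nonpositive what to do with zero or negative cells: convert to
#'   missing (default, with a message) or raise an error.
#' @return a [QuantExperiment-class] on the log2 scale.
#' @rdname log2Transform
#' @export
setMethod("log2Transform", "QuantExperiment",
          function(x, nonpositive = c("missing", "error")) {
    nonpositive <- match.arg(nonpositive)
    v <- quantValues(x)
    bad <- !is.na(v) & v <= 0
    if (any(bad)) {
        if (nonpositive == "error")
            stop(sum(bad), " zero/negative cell(s); cannot log-transform")
        message(sum(bad), " zero/negative cell(s) set to missing")
        v[bad] <- NA_real_
    }
    assay(x, "quant") <- log2(v)
    x
})

#' Median-center each sample column
#'
#' Subtracts from each column the median of its observed (non-missing)
#' values, so every column's observed median becomes 0. Operates on the log
#' scale.
#'
#' @param x a log-scale [QuantExperiment-class].
#' @return the normalized [QuantExperiment-class].
#' @rdname medianNormalize
#' @export
setMethod("medianNormalize", "QuantExperiment", function(x) {
    v <- quantValues(x)
    meds <- apply(v, 2, median, na.rm = TRUE)
    if (anyNA(meds))
        stop("column(s) with zero non-missing values: ",
             paste(colnames(v)[is.na(meds)], collapse = ", "))
    assay(x, "quant") <- sweep(v, 2, meds)
    x
})

#' Filter features by observation count and metadata
#'
#' Keeps features with at least `minTotal` non-missing cells across all
#' samples and, optionally, a per-feature annotation at or above a threshold
#' (e.g. at least 2 unique peptides per protein).
#'
#' @param x a [QuantExperiment-class].
#' @param minTotal minimum number of non-missing cells over all samples.
#' @param metaKey optional column name of `rowData(x)`.
#' @param metaThreshold minimum value of `metaKey` (kept if `>=`).
#' @return the row-subset [QuantExperiment-class] (input order preserved).
#' @rdname filterMinObserved
#' @export
setMethod("filterMinObserved", "QuantExperiment",
          function(x, minTotal, metaKey = NULL, metaThreshold = NULL) {
    keep <- rowSums(!is.na(quantValues(x))) >= minTotal
    if (!is.null(metaKey)) {
        if (!(metaKey %in% colnames(rowData(x))))
            stop("no feature annotation '", metaKey, "'")
        keep <- keep & (rowData(x)[[metaKey]] >= metaThreshold)
    }
    message(sum(!keep), " of ", length(keep), " features removed")
    x[keep, ]
})

#' Per-feature mean log-ratio between two conditions
#'
#' Unpaired: mean of observed treatment values minus mean of observed
#' reference values. Paired: mean of per-pair differences over pairs with
#' both members observed. `NA` where undefined (no observations on one side,
#' or no complete pair).
#'
#' @param x a log-scale [QuantExperiment-class].
#' @param comparison a [Comparison-class]; positive values mean higher in
#'   `conditionB`.
#' @return named numeric vector, one entry per feature.
#' @rdname meanLogRatio
#' @export
setMethod("meanLogRatio", "QuantExperiment", function(x, comparison) {
    cols <- .comparisonColumns(x, comparison)
    v <- quantValues(x)
    if (comparison@paired) {
        d <- v[, cols$b, drop = FALSE] - v[, cols$a, drop = FALSE]
        out <- .rowMeansNA(d)
    } else {
        out <- .rowMeansNA(v[, cols$b, drop = FALSE]) -
            .rowMeansNA(v[, cols$a, drop = FALSE])
    }
    stats::setNames(out, rownames(v))
})
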