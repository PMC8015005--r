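#' Accessors for QuantExperiment
#'
#' `quantValues()` returns the quantification matrix (features x samples,
#' `NA` = missing); `sampleConditions()` and `sampleReplicates()` return the
#' per-sample design.
#'
#' @param x a [QuantExperiment-class].
#' @return `quantValues`: numeric matrix.
#' @rdname quantValues
#' @export
setMethod("quantValues", "QuantExperiment",
          function(x) assay(x, "quant"))

#' @rdname sampleConditions
#' @return character vector (conditions) / integer vector (replicates).
#' @param x a [QuantExperiment-class].
#' @export
setMethod("sampleConditions", "QuantExperiment",
          function(x) as.character(colData(x)$condition))

#' @rdname sampleConditions
#' @export
setMethod("sampleReplicates", "QuantExperiment",
          function(x) as.integer(colData(x)$replicate))

setMethod("show", "QuantExperiment", function(object) {
    v <- quantValues(object)
    cond <- sampleConditions(object)
    cat("QuantExperiment with", nrow(object), "features and",
        ncol(object), "samples\n")
    tab <- table(cond)
    cat("conditions:",
        paste(sprintf("%s (r=%d)", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
    cat(sprintf("missing values: %d / %d cells (%.1f%%)\n",
                sum(is.na(v)), length(v), 100 * mean(is.na(v))))
})

setMethod("show", "Comparison", function(object) {
    cat(sprintf("Comparison: %s vs %s (%s)\n",
                object@conditionB, object@conditionA,
                if (object@paired) "paired" else "unpaired"))
})

#' Label of a comparison used in output column names
#'
#' @param comparison a [Comparison-class].
#' @return character scalar `"<B>.vs.<A>"`.
#' @export
comparisonLabel <- function(comparison) {
    paste0(comparison@conditionB, ".vs.", comparison@conditionA)
}

## columns of one condition, ordered by replicate index
.columnsFor <- function(x, condition) {
    idx <- which(sampleConditions(x) == condition)
    if (length(idx) == 0L)
        stop("condition '", condition, "' not present in the design")
    idx[order(sampleReplicates(x)[idx])]
}

## check a comparison against a design; returns list(a = cols, b = cols)
.comparisonColumns <- function(x, comparison) {
    a <- .columnsFor(x, comparison@conditionA)
    b <- .columnsFor(x, comparison@conditionB)
    if (comparison@paired && length(a) != length(b))
        stop("paired comparison requires equal replicate counts (",
             length(a), " vs ", length(b), ")")
    list(a = a, b = b)
}
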