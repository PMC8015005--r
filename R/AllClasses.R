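#' QuantExperiment: a quantification matrix with a two-level design
#'
#' `QuantExperiment` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' and holds a single assay `"quant"` of (typically log2-scale) feature
#' abundances in which `NA` marks a missing quantification. Zero is a
#' legitimate log-abundance and is never treated as missing. The column data
#' must carry a `condition` and a `replicate` for every sample; replicate
#' indices within a condition run 1..r without gaps, which is what paired
#' analyses pair on.
#'
#' @slot .. see SummarizedExperiment; no additional slots.
#'
#' @seealso [QuantExperiment()] the constructor, [Comparison()]
#' @export
setClass("QuantExperiment", contains = "SummarizedExperiment")

setValidity("QuantExperiment", function(object) {
    msg <- NULL
    if (!("quant" %in% assayNames(object)))
        msg <- c(msg, "assay 'quant' is required")
    ids <- rownames(object)
    if (is.null(ids) || anyDuplicated(ids) > 0)
        msg <- c(msg, "feature ids (rownames) must be present and unique")
    cd <- colData(object)
    if (!all(c("condition", "replicate") %in% colnames(cd))) {
        msg <- c(msg, "colData must contain 'condition' and 'replicate'")
    } else {
        cond <- as.character(cd$condition)
        repl <- cd$replicate
        if (anyNA(cond) || anyNA(repl))
            msg <- c(msg, "'condition' and 'replicate' must not contain NA")
        else {
            for (cn in unique(cond)) {
                ri <- sort(as.integer(repl[cond == cn]))
                if (!identical(ri, seq_along(ri)))
                    msg <- c(msg, sprintf(
                        "replicate indices of condition '%s' must be 1..r with no gaps",
                        cn))
            }
        }
    }
    if ("quant" %in% assayNames(object)) {
        v <- assay(object, "quant")
        if (!is.numeric(v))
            msg <- c(msg, "assay 'quant' must be numeric")
        else if (any(is.infinite(v)))
            msg <- c(msg, "assay 'quant' must not contain infinite values")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a QuantExperiment
#'
#' @param values numeric matrix, features in rows (rownames = unique feature
#'   ids), samples in columns; `NA` = missing quantification.
#' @param condition character/factor of length `ncol(values)` assigning each
#'   sample to a condition.
#' @param replicate optional integer replicate index within condition; by
#'   default samples are numbered 1..r in column order within each condition.
#' @param featureMeta optional data.frame/DataFrame of per-feature annotations
#'   (e.g. unique-peptide counts), one row per feature.
#'
#' @return a [QuantExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(24), nrow = 4,
#'             dimnames = list(paste0("P", 1:4), paste0("s", 1:6)))
#' qe <- QuantExperiment(m, condition = rep(c("A", "B"), each = 3))
#' qe
#' @export
QuantExperiment <- function(values, condition, replicate = NULL,
                            featureMeta = NULL) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (is.null(rownames(values)))
        stop("'values' must have rownames (feature ids)")
    if (is.null(colnames(values)))
        colnames(values) <- paste0("sample", seq_len(ncol(values)))
    if (anyDuplicated(rownames(values)))
        stop("duplicate feature ids: ",
             paste(unique(rownames(values)[duplicated(rownames(values))]),
                   collapse = ", "))
    condition <- as.character(condition)
    if (length(condition) != ncol(values))
        stop("'condition' must have one entry per sample column")
    if (is.null(replicate)) {
        replicate <- integer(length(condition))
        for (cn in unique(condition)) {
            idx <- which(condition == cn)
            replicate[idx] <- seq_along(idx)
        }
    }
    cd <- DataFrame(condition = condition, replicate = as.integer(replicate),
                    row.names = colnames(values))
    rd <- if (is.null(featureMeta)) NULL else DataFrame(featureMeta)
    se <- SummarizedExperiment(assays = list(quant = values), colData = cd,
                               rowData = rd)
    new("QuantExperiment", se)
}

#' Comparison: an ordered pair of conditions
#'
#' Defines one two-group contrast: `conditionB` (treatment) versus
#' `conditionA` (reference). Positive log-ratios mean higher abundance in
#' `conditionB`. Paired comparisons pair samples by replicate index and
#' require equal replicate counts.
#'
#' @slot conditionA character, the reference condition.
#' @slot conditionB character, the treatment condition.
#' @slot paired logical, pair samples by replicate index?
#' @export
setClass("Comparison",
         representation(conditionA = "character", conditionB = "character",
                        paired = "logical"))

setValidity("Comparison", function(object) {
    msg <- NULL
    if (length(object@conditionA) != 1L || length(object@conditionB) != 1L)
        msg <- c(msg, "conditionA and conditionB must be single strings")
    else if (object@conditionA == object@conditionB)
        msg <- c(msg, "conditionA and conditionB must differ")
    if (length(object@paired) != 1L || is.na(object@paired))
        msg <- c(msg, "'paired' must be TRUE or FALSE")
    if (is.null(msg)) TRUE else msg
})

#' @param conditionA,conditionB condition names (reference, treatment).
#' @param paired logical; pair samples by replicate index.
#' @return a [Comparison-class] object.
#' @examples
#' Comparison("ctrl", "treat")
#' @rdname Comparison-class
#' @export
Comparison <- function(conditionA, conditionB, paired = FALSE) {
    new("Comparison", conditionA = as.character(conditionA),
        conditionB = as.character(conditionB), paired = as.logical(paired))
}
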