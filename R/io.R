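#' Read a quantification matrix from delimited text
#'
#' Reads a TSV/CSV file whose first (or named) column holds feature ids and
#' whose remaining columns hold one sample each. Empty cells and the tokens
#' `NA`, `NaN` or anything non-numeric parse as missing. The design maps every
#' quantitative column to a condition (and optionally a replicate index).
#'
#' @param path file path; extension `.csv` selects comma separation,
#'   anything else tab.
#' @param design a data.frame with columns `sample`, `condition` and
#'   optionally `replicate` (and `group` for technical-replicate pooling),
#'   or the path to a YAML file with a top-level `samples:` map
#'   (`sample: {condition: ..., replicate: ...}`).
#' @param idColumn name or index of the feature-id column (default first).
#'
#' @return a [QuantExperiment-class] containing exactly the samples named in
#'   the design, in design order.
#' @seealso [writeQuantMatrix()], [readDesign()]
#' @export
readQuantMatrix <- function(path, design, idColumn = 1L) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                      colClasses = "character", na.strings = c())
    if (is.character(idColumn))
        idColumn <- match(idColumn, colnames(raw))
    ids <- raw[[idColumn]]
    if (anyDuplicated(ids))
        stop("duplicate feature ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    if (is.character(design) && length(design) == 1L)
        design <- readDesign(design)
    missingCols <- setdiff(design$sample, colnames(raw)[-idColumn])
    if (length(missingCols) > 0)
        stop("design references column(s) not found in ", path, ": ",
             paste(missingCols, collapse = ", "))
    vals <- vapply(design$sample, function(s)
        suppressWarnings(as.numeric(raw[[s]])), numeric(nrow(raw)))
    vals <- matrix(vals, nrow = nrow(raw),
                   dimnames = list(ids, design$sample))
    QuantExperiment(vals, condition = design$condition,
                    replicate = design$replicate)
}

#' Read a sample design from YAML
#'
#' @param path YAML file with a top-level `samples:` map; each entry is
#'   `sample: {condition: ..., replicate: ..., group: ...}` (replicate and
#'   group optional).
#' @return data.frame with columns `sample`, `condition`, `replicate` and,
#'   if present, `group`.
#' @export
readDesign <- function(path) {
    y <- yaml::read_yaml(path)
    if (is.null(y$samples))
        stop("design YAML must have a top-level 'samples:' map")
    s <- y$samples
    d <- data.frame(sample = names(s),
                    condition = vapply(s, function(e)
                        as.character(e$condition), character(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
    repl <- vapply(s, function(e)
        if (is.null(e$replicate)) NA_integer_ else as.integer(e$replicate),
        integer(1))
    if (!anyNA(repl)) d$replicate <- repl
    grp <- vapply(s, function(e)
        if (is.null(e$group)) NA_character_ else as.character(e$group),
        character(1))
    if (!anyNA(grp)) d$group <- grp
    d
}

#' Write a quantification matrix as TSV
#'
#' Missing cells are written as empty strings, so a
#' [readQuantMatrix()] round trip preserves values, missingness pattern and
#' ordering exactly.
#'
#' @param x a [QuantExperiment-class].
#' @param path output file.
#' @param idHeader header of the feature-id column.
#' @return invisibly, `path`.
#' @export
writeQuantMatrix <- function(x, path, idHeader = "feature") {
    v <- quantValues(x)
    ch <- formatC(v, format = "g", digits = 17)   # exact double round trip
    df <- data.frame(id = rownames(v), ch,
                     check.names = FALSE, stringsAsFactors = FALSE)
    df[-1][is.na(v)] <- ""
    colnames(df)[1] <- idHeader
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a test-result table as TSV
#'
#' @param results data.frame as returned by [runTests()].
#' @param path output file.
#' @param idHeader header of the feature-id column.
#' @return invisibly, `path`.
#' @export
writeResults <- function(results, path, idHeader = "feature") {
    df <- data.frame(id = rownames(results), results, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1] <- idHeader
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
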