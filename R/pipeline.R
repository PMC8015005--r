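#' Run the full test battery on one comparison
#'
#' Executes the enabled tests, applies the per-test multiple-testing
#' corrections (Benjamini-Hochberg for the missingness, rank-product and
#' permutation tests, Storey q-values for the plain and moderated t) and,
#' when the four non-t tests are all enabled, the unified FDR. A single
#' seed is expanded into fixed per-test sub-seeds (drawn once from the
#' seeded RNG in a canonical test order), so enabling or disabling one test
#' does not change another's randomness.
#'
#' @param x a log-scale [QuantExperiment-class].
#' @param comparison a [Comparison-class].
#' @param tests subset of `c("miss", "moderated", "rankprod",
#'   "permutation", "ttest")`.
#' @param seed integer seed governing all randomized tests.
#' @param nQuantiles detection-limit thresholds of the missingness test.
#' @param nPairings random pairings of the unpaired rank product.
#' @param nRand randomizations of the permutation test.
#' @param targetReps minimum replicates after permutation-test
#'   augmentation.
#' @return data.frame, one row per feature: `log_ratio_<B.vs.A>`, then
#'   `<test>_p_<B.vs.A>` and `<test>_FDR_<B.vs.A>` per test, and
#'   `unified_FDR_<B.vs.A>` when available.
#' @examples
#' sim <- simulateDataset(nFeatures = 500, nReplicates = 3,
#'                        fracRegulated = 10, delta = 3, seed = 1)
#' res <- runTests(sim$data, Comparison("c1", "c2"), seed = 1,
#'                 nRand = 100)
#' head(res[order(res[["unified_FDR_c2.vs.c1"]]), ])
#' @export
runTests <- function(x, comparison,
                     tests = c("miss", "moderated", "rankprod",
                               "permutation", "ttest"),
                     seed = NULL, nQuantiles = 100L, nPairings = 100L,
                     nRand = 1000L, targetReps = 7L) {
    allTests <- c("miss", "moderated", "rankprod", "permutation", "ttest")
    tests <- match.arg(tests, allTests, several.ok = TRUE)
    if (length(tests) == 0) stop("at least one test must be enabled")
    subSeeds <- NULL
    if (!is.null(seed)) {
        set.seed(seed)
        subSeeds <- stats::setNames(sample.int(.Machine$integer.max - 1,
                                               length(allTests)), allTests)
    }
    pT <- list()
    if ("miss" %in% tests)
        pT$miss <- missTest(x, comparison, nQuantiles = nQuantiles)
    if ("moderated" %in% tests)
        pT$moderated <- stats::setNames(moderatedTest(x, comparison)$p,
                                        rownames(x))
    if ("rankprod" %in% tests)
        pT$rankprod <- if (comparison@paired)
            stats::setNames(pairedRankProduct(x, comparison)$p, rownames(x))
        else unpairedRankProduct(x, comparison, nPairings = nPairings,
                                 seed = .subSeed(subSeeds, "rankprod"))
    if ("permutation" %in% tests)
        pT$permutation <- permutationTest(x, comparison, nRand = nRand,
                                          target = targetReps,
                                          seed = .subSeed(subSeeds,
                                                          "permutation"))
    if ("ttest" %in% tests)
        pT$ttest <- tTest(x, comparison)
    res <- assignCorrections(pT)
    four <- c("miss", "moderated", "rankprod", "permutation")
    if (!all(four %in% tests))
        warning("unified FDR requires the miss, moderated, rankprod and ",
                "permutation tests; column omitted")
    lab <- comparisonLabel(comparison)
    out <- data.frame(log_ratio = meanLogRatio(x, comparison), res,
                      check.names = FALSE)
    colnames(out) <- paste0(colnames(out), "_", lab)
    rownames(out) <- rownames(x)
    out
}

.subSeed <- function(subSeeds, nm)
    if (is.null(subSeeds)) NULL else unname(subSeeds[nm])

#' Run a configured analysis end to end
#'
#' Thin driver over the package functions: optional preprocessing (log2
#' transform, median normalization, minimum-observation filter), then
#' [runTests()] per comparison, written as one TSV. Intended for scripted
#' use; the `exec/polyda` command line wraps it.
#'
#' @param x a [QuantExperiment-class] (raw or log scale, see `log2`).
#' @param comparisons list of [Comparison-class] objects.
#' @param tests,seed,nQuantiles,nPairings,nRand,targetReps see
#'   [runTests()].
#' @param log2 log2-transform first (input on raw scale)?
#' @param normalize median-center each sample column?
#' @param minObserved drop features with fewer non-missing cells.
#' @param output optional path; when given, the table is written as TSV.
#' @return the combined results data.frame (one row per retained feature),
#'   invisibly when `output` is given.
#' @export
runPipeline <- function(x, comparisons,
                        tests = c("miss", "moderated", "rankprod",
                                  "permutation", "ttest"),
                        seed = NULL, log2 = FALSE, normalize = FALSE,
                        minObserved = 0L, nQuantiles = 100L,
                        nPairings = 100L, nRand = 1000L, targetReps = 7L,
                        output = NULL) {
    if (inherits(comparisons, "Comparison")) comparisons <- list(comparisons)
    if (length(comparisons) == 0) stop("at least one comparison is required")
    if (log2) x <- log2Transform(x)
    if (normalize) x <- medianNormalize(x)
    if (minObserved > 0) x <- filterMinObserved(x, minObserved)
    parts <- lapply(comparisons, function(cmp)
        runTests(x, cmp, tests = tests, seed = seed,
                 nQuantiles = nQuantiles, nPairings = nPairings,
                 nRand = nRand, targetReps = targetReps))
    res <- do.call(cbind, parts)
    if (!is.null(output)) {
        writeResults(res, output)
        return(invisible(res))
    }
    res
}
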