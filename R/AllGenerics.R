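#' @rdname quantValues
#' @export
setGeneric("quantValues", function(x) standardGeneric("quantValues"))

#' @rdname sampleConditions
#' @export
setGeneric("sampleConditions", function(x) standardGeneric("sampleConditions"))

#' @rdname sampleConditions
#' @export
setGeneric("sampleReplicates", function(x) standardGeneric("sampleReplicates"))

#' @rdname sumTechnicalReplicates
#' @export
setGeneric("sumTechnicalReplicates",
           function(x, groups) standardGeneric("sumTechnicalReplicates"))

#' @rdname log2Transform
#' @export
setGeneric("log2Transform", function(x, nonpositive = c("missing", "error"))
    standardGeneric("log2Transform"))

#' @rdname medianNormalize
#' @export
setGeneric("medianNormalize", function(x) standardGeneric("medianNormalize"))

#' @rdname filterMinObserved
#' @export
setGeneric("filterMinObserved",
           function(x, minTotal, metaKey = NULL, metaThreshold = NULL)
    standardGeneric("filterMinObserved"))

#' @rdname meanLogRatio
#' @export
setGeneric("meanLogRatio",
           function(x, comparison) standardGeneric("meanLogRatio"))

#' @rdname missTest
#' @export
setGeneric("missTest", function(x, comparison, nQuantiles = 100L)
    standardGeneric("missTest"))

#' @rdname tTest
#' @export
setGeneric("tTest", function(x, comparison) standardGeneric("tTest"))

#' @rdname moderatedTest
#' @export
setGeneric("moderatedTest", function(x, comparison, prior = NULL)
    standardGeneric("moderatedTest"))

#' @rdname rankProductTest
#' @export
setGeneric("pairedRankProduct",
           function(x, comparison) standardGeneric("pairedRankProduct"))

#' @rdname rankProductTest
#' @export
setGeneric("unpairedRankProduct",
           function(x, comparison, nPairings = 100L, seed = NULL)
    standardGeneric("unpairedRankProduct"))

#' @rdname permutationTest
#' @export
setGeneric("augmentReplicates",
           function(x, comparison, target = 7L, seed = NULL)
    standardGeneric("augmentReplicates"))

#' @rdname permutationTest
#' @export
setGeneric("permutationTest",
           function(x, comparison, nRand = 1000L, target = 7L, seed = NULL)
    standardGeneric("permutationTest"))
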