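test_that("matrix IO round-trips values, missingness and ordering", {
    m <- matrix(c(1.5, NA, 3.25, 0, -2.75, 1e-3), nrow = 3,
                dimnames = list(c("P1", "P2", "P3"), c("s1", "s2")))
    qe <- QuantExperiment(m, condition = c("A", "B"))
    f <- tempfile(fileext = ".tsv")
    writeQuantMatrix(qe, f)
    design <- data.frame(sample = c("s1", "s2"), condition = c("A", "B"))
    qe2 <- readQuantMatrix(f, design)
    expect_identical(quantValues(qe2), quantValues(qe))
    expect_identical(rownames(qe2), rownames(qe))
    # one empty cell in the file parses as exactly one missing cell
    expect_identical(sum(is.na(quantValues(qe2))), 1L)
})

test_that("non-numeric tokens parse as missing; bad input errors", {
    f <- tempfile(fileext = ".tsv")
    writeLines(c("feature\tr1\tr2\tr3",
                 "P1\t1.0\tNaN\t2.0",
                 "P2\tNA\t3.0\t4.0",
                 "P3\t5.0\t6.0\t"), f)
    design <- data.frame(sample = c("r1", "r2", "r3"),
                         condition = c("A", "A", "B"))
    qe <- readQuantMatrix(f, design)
    v <- quantValues(qe)
    expect_identical(unname(which(is.na(v))), c(2L, 4L, 9L))
    expect_identical(sum(is.na(v)), 3L)
    expect_true(all(is.finite(v[!is.na(v)])))

    # design referencing a nonexistent sample column
    bad <- data.frame(sample = c("r1", "rep4"), condition = c("A", "B"))
    expect_error(readQuantMatrix(f, bad), "rep4")

    # duplicated feature ids are named in the error
    writeLines(c("feature\tr1", "P1\t1", "P1\t2"), f)
    expect_error(readQuantMatrix(f, data.frame(sample = "r1",
                                               condition = "A")), "P1")
})

test_that("design YAML maps samples to condition and replicate", {
    f <- tempfile(fileext = ".yaml")
    writeLines(c("samples:",
                 "  s1: {condition: ctrl, replicate: 1}",
                 "  s2: {condition: ctrl, replicate: 2}",
                 "  s3: {condition: treat, replicate: 1}"), f)
    d <- readDesign(f)
    expect_identical(d$sample, c("s1", "s2", "s3"))
    expect_identical(d$condition, c("ctrl", "ctrl", "treat"))
    expect_identical(d$replicate, c(1L, 2L, 1L))
})

test_that("technical-replicate summation ignores missing and keeps shape", {
    m <- matrix(c(2, 4, NA,  NA, NA, NA,  1, 1, 1), nrow = 3, byrow = TRUE,
                dimnames = list(c("P1", "P2", "P3"),
                                c("t1", "t2", "t3")))
    m <- cbind(m, m + 1)
    colnames(m) <- paste0("t", 1:6)
    qe <- QuantExperiment(m, condition = rep(c("A", "B"), each = 3))
    groups <- c(t1 = "b1", t2 = "b1", t3 = "b1",
                t4 = "b2", t5 = "b2", t6 = "b2")
    out <- sumTechnicalReplicates(qe, groups)
    expect_identical(ncol(out), 2L)
    v <- quantValues(out)
    expect_identical(unname(v["P1", "b1"]), 6)        # 2 + 4, NA ignored
    expect_true(is.na(v["P2", "b1"]))                 # all-missing group
    expect_identical(unname(v["P3", "b2"]), 6)        # 2 + 2 + 2
    expect_error(sumTechnicalReplicates(qe, groups[1:5]), "group")
})

test_that("log2 transform maps known points and zeros per configuration", {
    m <- matrix(c(8, 1, 0, 4), 2,
                dimnames = list(c("P1", "P2"), c("s1", "s2")))
    qe <- QuantExperiment(m, condition = c("A", "B"))
    expect_message(out <- log2Transform(qe), "missing")
    v <- quantValues(out)
    expect_identical(unname(v["P1", "s1"]), 3)
    expect_identical(unname(v["P2", "s1"]), 0)
    expect_true(is.na(v["P1", "s2"]))                 # 0 -> missing
    expect_identical(unname(v["P2", "s2"]), 2)
    expect_error(log2Transform(qe, nonpositive = "error"), "negative")
})

test_that("median normalization centers observed medians and is idempotent", {
    m <- matrix(c(1, 2, 3,   1, NA, 3), ncol = 2,
                dimnames = list(paste0("P", 1:3), c("s1", "s2")))
    qe <- QuantExperiment(m, condition = c("A", "B"))
    out <- medianNormalize(qe)
    v <- quantValues(out)
    expect_equal(unname(v[, "s1"]), c(-1, 0, 1))
    expect_equal(unname(v[, "s2"]), c(-1, NA, 1))     # observed median = 2
    expect_true(all(abs(apply(v, 2, median, na.rm = TRUE)) < 1e-12))
    expect_equal(quantValues(medianNormalize(out)), v)

    qe2 <- QuantExperiment(matrix(NA_real_, 2, 2,
                                  dimnames = list(c("a", "b"), c("s1", "s2"))),
                           condition = c("A", "B"))
    expect_error(medianNormalize(qe2), "non-missing")
})

test_that("minimum-observation filter keeps order and is monotone", {
    set.seed(11)
    v <- matrix(rnorm(10 * 18), 10,
                dimnames = list(paste0("P", 1:10), paste0("s", 1:18)))
    v[1, 1:13] <- NA      # 5 observed of 18 -> removed at minTotal = 6
    v[4, 1:14] <- NA
    v[8, 1:16] <- NA
    qe <- QuantExperiment(v, condition = rep(c("A", "B", "C"), each = 6))
    suppressMessages({
        out <- filterMinObserved(qe, minTotal = 6)
        expect_identical(rownames(out), paste0("P", c(2, 3, 5, 6, 7, 9, 10)))
        expect_identical(nrow(filterMinObserved(qe, 0)), 10L)
        # monotone: raising the cutoff never adds features
        sizes <- vapply(c(0, 6, 12, 18, 19), function(k)
            nrow(filterMinObserved(qe, k)), integer(1))
    })
    expect_true(all(diff(sizes) <= 0))
})

test_that("feature-meta filter combines with the observation filter", {
    v <- matrix(1, 4, 6, dimnames = list(paste0("P", 1:4), paste0("s", 1:6)))
    qe <- QuantExperiment(v, condition = rep(c("A", "B"), 3),
                          featureMeta = data.frame(peptides = c(1, 2, 3, 1)))
    suppressMessages(
        out <- filterMinObserved(qe, 0, metaKey = "peptides",
                                 metaThreshold = 2))
    expect_identical(rownames(out), c("P2", "P3"))
})

test_that("mean log-ratio follows the sign convention and pairing", {
    qe <- makeQE(matrix(c(1, 1, 1, 2, 2, 2), nrow = 1), r = 3)
    expect_equal(unname(meanLogRatio(qe, cmpAB)), 1)
    # antisymmetric under swapping the conditions
    expect_equal(meanLogRatio(qe, Comparison("B", "A")),
                 -meanLogRatio(qe, cmpAB))
    # paired: mean over complete pairs only
    qe2 <- makeQE(matrix(c(1, 2, NA, 2, 4, 5), nrow = 1), r = 3)
    expect_equal(unname(meanLogRatio(qe2, cmpABp)), 1.5)
    # undefined when one side has no observations
    qe3 <- makeQE(matrix(c(NA, NA, NA, 1, 2, 3), nrow = 1), r = 3)
    expect_true(is.na(meanLogRatio(qe3, cmpAB)))
})

test_that("QuantExperiment validity enforces the design invariants", {
    v <- matrix(1, 2, 4, dimnames = list(c("a", "b"), paste0("s", 1:4)))
    expect_error(QuantExperiment(rbind(v, v), condition = rep("A", 4)),
                 "duplicate")
    expect_error(QuantExperiment(v, condition = rep(c("A", "B"), 2),
                                 replicate = c(1, 1, 2, 3)),
                 "replicate")
    v[1, 1] <- Inf
    expect_error(QuantExperiment(v, condition = rep(c("A", "B"), 2)),
                 "infinite")
    # paired comparisons need equal replicate counts
    v2 <- matrix(1, 2, 5, dimnames = list(c("a", "b"), paste0("s", 1:5)))
    qe <- QuantExperiment(v2, condition = c("A", "A", "A", "B", "B"))
    expect_error(meanLogRatio(qe, cmpABp), "equal replicate")
    expect_error(Comparison("A", "A"), "differ")
})
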