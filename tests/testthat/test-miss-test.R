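test_that("binomial missing-count probabilities match closed forms", {
    expect_equal(binomMissing(3, 0.5), c(1, 3, 3, 1) / 8)
    expect_equal(binomMissing(3, 0), c(1, 0, 0, 0))
    expect_error(binomMissing(3, 1.2), "probability")
})

test_that("binomial probabilities match enumeration over all patterns", {
    # weight every 2^r missing/present pattern and bin by missing count
    r <- 5; pNA <- 0.2
    b <- numeric(r + 1)
    for (code in 0:(2^r - 1)) {
        bits <- as.integer(intToBits(code))[seq_len(r)]
        b[sum(bits) + 1] <- b[sum(bits) + 1] +
            prod(ifelse(bits == 1, pNA, 1 - pNA))
    }
    expect_equal(binomMissing(r, pNA), b, tolerance = 1e-12)
})

test_that("missing-count-difference distribution matches known values", {
    expect_equal(diffProbabilities(3, 0.5),
                 c(5 / 16, 15 / 32, 3 / 16, 1 / 32))
    expect_equal(diffProbabilities(3, 0), c(1, 0, 0, 0))
    expect_equal(diffProbabilities(2, 0.5), c(3 / 8, 1 / 2, 1 / 8))
    expect_equal(sum(diffProbabilities(7, 0.31)), 1, tolerance = 1e-12)
})

test_that("difference distribution agrees with exhaustive enumeration", {
    for (r in 1:5) {
        for (pNA in seq(0.1, 0.9, by = 0.2)) {
            expect_equal(diffProbabilities(r, pNA), enumDiffProbs(r, pNA),
                         tolerance = 1e-12,
                         info = sprintf("r=%d pNA=%.1f", r, pNA))
        }
    }
})

test_that("unequal group sizes reduce to the equal case and sum to one", {
    expect_equal(diffProbabilities(4, 0.3, rB = 4), diffProbabilities(4, 0.3))
    P <- diffProbabilities(3, 0.4, rB = 5)
    expect_length(P, 6)
    expect_equal(sum(P), 1, tolerance = 1e-12)
    # oracle: direct convolution of the two binomials
    bA <- dbinom(0:3, 3, 0.4); bB <- dbinom(0:5, 5, 0.4)
    Pref <- numeric(6)
    for (i in 0:3) for (j in 0:5)
        Pref[abs(i - j) + 1] <- Pref[abs(i - j) + 1] + bA[i + 1] * bB[j + 1]
    expect_equal(P, Pref, tolerance = 1e-12)
})

test_that("scenario scan reproduces a brute-force mask-and-recount", {
    v <- matrix(c(1, 2, 3, 4,
                  2, NA, 4, 5,
                  NA, NA, 1, 9,
                  5, 6, 7, 8), nrow = 4, byrow = TRUE,
                dimnames = list(paste0("f", 1:4), paste0("s", 1:4)))
    qe <- QuantExperiment(v, condition = c("A", "A", "B", "B"))
    nq <- 10L
    scan <- scenarioScan(qe, cmpAB, nQuantiles = nq)
    obs <- v[!is.na(v)]
    thr <- quantile(obs, probs = (0:(nq - 1)) / nq, names = FALSE)
    for (s in seq_len(nq)) {
        masked <- v
        masked[!is.na(masked) & masked < thr[s]] <- NA
        expect_equal(scan$pNA[s], mean(is.na(masked)))
        kRef <- abs(rowSums(is.na(masked[, 1:2, drop = FALSE])) -
                    rowSums(is.na(masked[, 3:4, drop = FALSE])))
        expect_equal(unname(scan$k[, s]), unname(kRef))
    }
    expect_true(all(diff(scan$pNA) >= 0))     # censoring only grows
    # first scenario reproduces the unthresholded data
    expect_equal(scan$pNA[1], mean(is.na(v)))
    # a complete matrix has pNA = 0 in the first scenario
    qe2 <- makeQE(matrix(1:8 + 0, 2), r = 2)
    expect_equal(scenarioScan(qe2, cmpAB, 4L)$pNA[1], 0)
    # all-missing input is rejected
    qe3 <- QuantExperiment(matrix(NA_real_, 2, 2,
                                  dimnames = list(c("a", "b"), NULL)),
                           condition = c("A", "B"))
    expect_error(scenarioScan(qe3, cmpAB), "non-missing")
})

test_that("all-missing-versus-complete feature hits the 1/32 scenario", {
    # overall missing fraction 1/2 at the unthresholded scenario, r = 3;
    # a feature missing in all of A and observed in all of B has k = 3 with
    # P_3 = 2 * (1/2)^6 = 1/32 there
    set.seed(21)
    n <- 16
    v <- matrix(rnorm(n * 6) + 10, n,
                dimnames = list(paste0("f", 1:n), paste0("s", 1:6)))
    v[1, 1:3] <- NA                        # f1: absent in A, present in B
    nMissTotal <- 6 * n / 2
    pool <- which(!is.na(v) & row(v) > 1)
    v[sample(pool, nMissTotal - 3)] <- NA  # pad to exactly 50% missing
    qe <- QuantExperiment(v, condition = rep(c("A", "B"), each = 3))
    scan <- scenarioScan(qe, cmpAB, nQuantiles = 100L)
    expect_equal(scan$pNA[1], 0.5)
    expect_identical(scan$k[1, 1], 3L)
    P <- diffProbabilities(3, scan$pNA[1])
    expect_equal(P[4], 1 / 32)
    # the reported p is at most (r+1) times that scenario probability
    p <- missTest(qe, cmpAB)
    expect_lte(p[["f1"]], 4 * (1 / 32))
})

test_that("missingness test matches a naive per-scenario loop oracle", {
    set.seed(22)
    v <- matrix(rnorm(6 * 6), 6,
                dimnames = list(paste0("f", 1:6), paste0("s", 1:6)))
    v[1, 4:6] <- v[1, 4:6] + 6            # strongly separated feature
    v[2, 1] <- NA
    v[5, c(2, 5)] <- NA
    qe <- QuantExperiment(v, condition = rep(c("A", "B"), each = 3))
    nq <- 100L
    p <- missTest(qe, cmpAB, nQuantiles = nq)

    obs <- v[!is.na(v)]
    thr <- quantile(obs, probs = (0:(nq - 1)) / nq, names = FALSE)
    pRef <- rep(Inf, nrow(v))
    for (s in seq_len(nq)) {
        masked <- v
        masked[!is.na(masked) & masked < thr[s]] <- NA
        pna <- mean(is.na(masked))
        for (f in seq_len(nrow(v))) {
            k <- abs(sum(is.na(masked[f, 1:3])) - sum(is.na(masked[f, 4:6])))
            pRef[f] <- min(pRef[f], diffProbabilities(3, pna)[k + 1])
        }
    }
    pRef <- pmin(1, pRef * 4)
    expect_equal(unname(p), pRef, tolerance = 1e-12)
    expect_lt(p[["f1"]], min(p[-1]))      # the separated feature wins
})

test_that("identical fully observed groups are forced through k = 0", {
    v <- matrix(rep(c(3, 4, 7, 9), each = 6), 4, byrow = TRUE,
                dimnames = list(paste0("f", 1:4), paste0("s", 1:6)))
    qe <- QuantExperiment(v, condition = rep(c("A", "B"), each = 3))
    scan <- scenarioScan(qe, cmpAB)
    expect_true(all(scan$k == 0))
    p <- missTest(qe, cmpAB)
    pRef <- pmin(1, vapply(scan$pNA, function(q)
        diffProbabilities(3, q)[1], numeric(1)) * 4)
    expect_equal(unname(p), rep(min(pRef), 4))
})

test_that("p-values are invariant under reordering and global shifts", {
    set.seed(23)
    sim <- simulateDataset(nFeatures = 500, nReplicates = 4,
                           fracRegulated = 10, delta = 2, fracMissing = 25,
                           mu = 5, seed = 31)
    qe <- sim$data
    cmp <- Comparison("c1", "c2")
    p <- missTest(qe, cmp)
    # feature reordering
    perm <- sample(nrow(qe))
    expect_equal(missTest(qe[perm, ], cmp), p[perm])
    # adding a constant to the whole matrix
    qe2 <- qe
    SummarizedExperiment::assay(qe2, "quant") <-
        quantValues(qe) + 7.5
    expect_equal(missTest(qe2, cmp), p)
})

test_that("raising one group's values never increases its p-value", {
    set.seed(24)
    v <- matrix(rnorm(200 * 6), 200,
                dimnames = list(sprintf("f%03d", 1:200), paste0("s", 1:6)))
    v[7, 1:2] <- NA
    qe <- QuantExperiment(v, condition = rep(c("A", "B"), each = 3))
    p0 <- missTest(qe, cmpAB)[7]
    # push the feature's B values above every threshold
    v2 <- v
    v2[7, 4:6] <- max(v, na.rm = TRUE) + 1:3
    p1 <- missTest(QuantExperiment(v2, condition = rep(c("A", "B"), each = 3)),
                   cmpAB)[7]
    expect_lte(p1, p0)
})
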