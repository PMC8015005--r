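# small in-code fixtures shared across tests

## a features x (2*r) matrix wrapped as QuantExperiment, conditions A/B
makeQE <- function(values, r = ncol(values) / 2,
                   conditions = c("A", "B")) {
    values <- as.matrix(values)
    if (is.null(rownames(values)))
        rownames(values) <- paste0("f", seq_len(nrow(values)))
    if (is.null(colnames(values)))
        colnames(values) <- paste0(rep(conditions, each = r), seq_len(r))
    QuantExperiment(values, condition = rep(conditions, each = r))
}

cmpAB <- Comparison("A", "B")
cmpABp <- Comparison("A", "B", paired = TRUE)

## exhaustive-enumeration oracle for the missing-count-difference
## distribution: every 2^(2r) missing/present pattern over two groups of r
## replicates, weighted by pNA^(#miss) (1-pNA)^(#present)
enumDiffProbs <- function(r, pNA) {
    P <- numeric(r + 1)
    for (code in 0:(2^(2 * r) - 1)) {
        bits <- as.integer(intToBits(code))[seq_len(2 * r)]
        w <- prod(ifelse(bits == 1, pNA, 1 - pNA))
        k <- abs(sum(bits[seq_len(r)]) - sum(bits[r + seq_len(r)]))
        P[k + 1] <- P[k + 1] + w
    }
    P
}

## closed-testing oracle for the Hommel adjustment: adjusted p of hypothesis
## i is the largest Simes p over all subsets containing i
closedTestingSimes <- function(p) {
    m <- length(p)
    adj <- numeric(m)
    subsets <- unlist(lapply(seq_len(m), function(k)
        utils::combn(m, k, simplify = FALSE)), recursive = FALSE)
    simes <- function(ps) min(length(ps) * sort(ps) / seq_along(ps))
    for (i in seq_len(m)) {
        adj[i] <- max(vapply(subsets, function(S)
            if (i %in% S) simes(p[S]) else -Inf, numeric(1)))
    }
    pmin(1, adj)
}

## exact null p-value of a normalized rank product: product over k pairs of
## (R_j / n) with R_j iid uniform on 1..n, P(prod <= rho); full enumeration
exactRankProductP <- function(rho, n, k) {
    grids <- rep(list(seq_len(n)), k)
    ranks <- as.matrix(expand.grid(grids))
    prods <- apply(ranks / n, 1, prod)
    mean(prods <= rho + 1e-12)
}
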