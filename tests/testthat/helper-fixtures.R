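## Fixtures are built in code; no binary files.

## Small expression matrix with mixed biotypes and reproducible values.
makeExpr <- function(nPCG = 4, nLnc = 2, nMir = 2, nSamples = 10,
                     seed = 42) {
    set.seed(seed)
    ids <- c(sprintf("pcg%02d", seq_len(nPCG)),
             sprintf("lnc%02d", seq_len(nLnc)),
             sprintf("mir%02d", seq_len(nMir)))
    bt <- setNames(rep(c("PCG", "lncRNA", "miRNA"), c(nPCG, nLnc, nMir)),
                   ids)
    m <- matrix(rnorm(length(ids) * nSamples), length(ids), nSamples,
                dimnames = list(ids, sprintf("s%02d", seq_len(nSamples))))
    StemnessExperiment(m, bt)
}

## Erdos-Renyi G(n, p) graph as a StemNetwork (independent edge coin
## flips over all unordered pairs).
erdosRenyi <- function(n, p, seed, connectedRetry = FALSE) {
    set.seed(seed)
    repeat {
        ids <- sprintf("n%03d", seq_len(n))
        cmb <- t(utils::combn(ids, 2))
        keep <- stats::runif(nrow(cmb)) < p
        if (!any(keep)) next
        net <- stemNetwork(data.frame(a = cmb[keep, 1], b = cmb[keep, 2]),
                           nodes = ids)
        if (!connectedRetry || isConnected(net))
            return(net)
    }
}

## Connectivity by breadth-first search over the edge list.
isConnected <- function(net) {
    nodes <- nodeIds(net)
    e <- edgeTable(net)
    if (!nrow(e)) return(length(nodes) <= 1)
    adj <- split(c(e$node_b, e$node_a), c(e$node_a, e$node_b))
    seen <- nodes[1]
    frontier <- nodes[1]
    while (length(frontier)) {
        nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)),
                       seen)
        seen <- c(seen, nxt)
        frontier <- nxt
    }
    length(seen) == length(nodes)
}

## Textbook Pearson correlation, written independently of stats::cor.
pccOracle <- function(x, y) {
    n <- length(x)
    sx <- sum(x); sy <- sum(y)
    num <- n * sum(x * y) - sx * sy
    den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
    num / den
}

## Exhaustive hypergeometric upper tail: enumerate all C(N, n) draws of
## the predicted set and count overlaps >= k.
hyperOracle <- function(N, K, n, k) {
    universe <- seq_len(N)
    de <- seq_len(K)
    draws <- utils::combn(universe, n)
    mean(colSums(matrix(draws %in% de, nrow = n)) >= k)
}

expect_l1_close <- function(a, b, tol) {
    expect_lt(sum(abs(a - b)), tol)
}
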