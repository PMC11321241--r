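test_that("variance filter follows the quantile rule", {
    ## 4 genes with variances {0, ~1, ~2, ~3}: bottom-25% removal drops
    ## exactly the variance-0 gene
    m <- rbind(g1 = rep(5, 8),
               g2 = sqrt(1) * scale(rnorm(8))[, 1],
               g3 = sqrt(2) * scale(rnorm(8))[, 1],
               g4 = sqrt(3) * scale(rnorm(8))[, 1])
    colnames(m) <- paste0("s", 1:8)
    se <- StemnessExperiment(m, setNames(rep("PCG", 4), rownames(m)))
    out <- suppressMessages(filterLowVariance(se, 0.25))
    expect_identical(rownames(out), c("g2", "g3", "g4"))
    ## dropFraction 0 is the identity
    expect_identical(rownames(suppressMessages(filterLowVariance(se, 0))),
                     rownames(se))
    expect_error(filterLowVariance(se, 1), "must lie in")
})

test_that("variance filter retains exactly the genes above the quantile (brute force)", {
    se <- makeExpr(nPCG = 60, nLnc = 20, nMir = 20, nSamples = 12, seed = 3)
    v <- apply(exprValues(se), 1, var)
    for (f in c(0.1, 0.25, 0.5)) {
        out <- suppressMessages(filterLowVariance(se, f))
        expected <- names(v)[v > quantile(v, f, names = FALSE)]
        expect_identical(rownames(out), intersect(rownames(se), expected))
    }
    ## 100 distinct variances, dropFraction 0.25 -> exactly 75 retained
    expect_identical(nrow(suppressMessages(filterLowVariance(se, 0.25))), 75L)
})

test_that("pair PCCs match an independent textbook computation", {
    se <- makeExpr(nPCG = 10, nLnc = 5, nMir = 5, nSamples = 15, seed = 11)
    rp <- computePairs(se)
    p <- pairTable(rp)
    m <- exprValues(se)
    oracle <- mapply(function(a, b) pccOracle(m[a, ], m[b, ]),
                     p$gene_a, p$gene_b)
    expect_lt(max(abs(p$pcc - oracle)), 1e-12)
})

test_that("pair enumeration covers exactly the four categories, each unordered pair once", {
    se <- makeExpr(nPCG = 4, nLnc = 3, nMir = 2, nSamples = 8, seed = 5)
    rp <- computePairs(se)
    p <- pairTable(rp)
    expect_setequal(unique(p$category),
                    c("PCG-PCG", "PCG-lncRNA", "miRNA-PCG", "miRNA-lncRNA"))
    expect_identical(unname(pairTotals(rp)[c("PCG-PCG", "PCG-lncRNA",
                                             "miRNA-PCG", "miRNA-lncRNA")]),
                     as.integer(c(choose(4, 2), 4 * 3, 2 * 4, 2 * 3)))
    key <- paste(pmin(p$gene_a, p$gene_b), pmax(p$gene_a, p$gene_b),
                 p$category)
    expect_false(anyDuplicated(key) > 0)
    ## no lncRNA-lncRNA or miRNA-miRNA pairs
    bt <- biotype(se)
    expect_false(any(bt[p$gene_a] == "lncRNA" & bt[p$gene_b] == "lncRNA"))
    expect_false(any(bt[p$gene_a] == "miRNA" & bt[p$gene_b] == "miRNA"))
})

test_that("category rank rules: |pcc| descending vs signed ascending", {
    se <- makeExpr(nPCG = 6, nLnc = 4, nMir = 4, nSamples = 10, seed = 9)
    p <- pairTable(computePairs(se))
    for (cc in c("PCG-PCG", "PCG-lncRNA")) {
        sub <- p[p$category == cc, ]
        sub <- sub[order(sub$rank), ]
        expect_true(all(diff(abs(sub$pcc)) <= 1e-15))
    }
    for (cc in c("miRNA-PCG", "miRNA-lncRNA")) {
        sub <- p[p$category == cc, ]
        sub <- sub[order(sub$rank), ]
        expect_true(all(diff(sub$pcc) >= -1e-15))
    }
})

test_that("TF genes join the PCG side of co-expression categories", {
    se <- makeExpr(nPCG = 3, nLnc = 2, nMir = 2, nSamples = 8, seed = 13)
    bt <- biotype(se)
    bt["pcg01"] <- "TF"
    se2 <- StemnessExperiment(exprValues(se), bt)
    p <- pairTable(computePairs(se2))
    expect_true("pcg01" %in% c(p$gene_a, p$gene_b))
    expect_setequal(unique(p$category[p$gene_a == "pcg01" |
                                      p$gene_b == "pcg01"]),
                    c("PCG-PCG", "PCG-lncRNA", "miRNA-PCG"))
})

test_that("zero-variance genes and too few samples are rejected", {
    m <- rbind(g1 = c(1, 1, 1, 1), g2 = c(1, 2, 3, 4), g3 = c(2, 1, 4, 3))
    colnames(m) <- paste0("s", 1:4)
    se <- StemnessExperiment(m, setNames(rep("PCG", 3), rownames(m)))
    expect_error(computePairs(se), "zero-variance")
})

test_that("thresholding keeps ceil(k% of category count) top pairs", {
    se <- makeExpr(nPCG = 10, nLnc = 5, nMir = 5, nSamples = 10, seed = 21)
    rp <- computePairs(se)
    for (co in c(0.1, 1, 5, 10, 20, 100)) {
        th <- thresholdPairs(rp, co)
        p <- pairTable(th)
        for (cc in names(pairTotals(rp))) {
            expected <- ceiling(co / 100 * pairTotals(rp)[[cc]])
            expect_identical(sum(p$category == cc), as.integer(expected))
            expect_identical(sort(p$rank[p$category == cc]),
                             seq_len(expected))
        }
    }
    ## 7-pair category at 20% -> ceil(1.4) = 2
    expect_identical(as.integer(ceiling(0.2 * 7)), 2L)
    sub <- rp
    sub@pairs <- sub@pairs[sub@pairs$category == "miRNA-lncRNA" &
                           sub@pairs$rank <= 7, ]
    sub@totals <- c(`miRNA-lncRNA` = 7L)
    expect_identical(nrow(pairTable(thresholdPairs(sub, 20))), 2L)
    expect_error(thresholdPairs(rp, 0), "percent")
    expect_error(thresholdPairs(rp, 101), "percent")
    ## cutoff 100% is the identity
    expect_identical(nrow(pairTable(thresholdPairs(rp, 100))),
                     nrow(pairTable(rp)))
})

test_that("edge sets are nested and monotone across increasing cutoffs", {
    se <- makeExpr(nPCG = 12, nLnc = 6, nMir = 6, nSamples = 12, seed = 31)
    rp <- computePairs(se)
    edgeKey <- function(th) {
        p <- pairTable(th)
        paste(pmin(p$gene_a, p$gene_b), pmax(p$gene_a, p$gene_b), p$category)
    }
    cuts <- c(0.1, 1, 5, 10, 20)
    keys <- lapply(cuts, function(co) edgeKey(thresholdPairs(rp, co)))
    for (i in seq_len(length(cuts) - 1)) {
        expect_true(all(keys[[i]] %in% keys[[i + 1]]))
        expect_lte(length(keys[[i]]), length(keys[[i + 1]]))
    }
})

test_that("seed-edge retention equals the brute-force membership filter", {
    se <- makeExpr(nPCG = 8, nLnc = 4, nMir = 4, nSamples = 10, seed = 17)
    rp <- computePairs(se)
    seeds <- c("pcg01", "pcg02", "lnc01")
    kept <- pairTable(retainSeedEdges(rp, seeds))
    p <- pairTable(rp)
    brute <- p[p$gene_a %in% seeds | p$gene_b %in% seeds, ]
    expect_identical(kept$gene_a, brute$gene_a)
    expect_identical(kept$gene_b, brute$gene_b)
    expect_warning(retainSeedEdges(rp, character()), "no pair contains")
})

test_that("network assembly merges duplicate unordered pairs and unions endpoints", {
    pairs <- data.frame(
        gene_a = c("p1", "p1", "m1", "m1"),
        gene_b = c("p2", "l1", "p1", "l1"),
        category = c("PCG-PCG", "PCG-lncRNA", "miRNA-PCG", "miRNA-lncRNA"),
        pcc = c(0.9, -0.8, -0.7, -0.6),
        rank = c(1L, 1L, 1L, 1L), stringsAsFactors = FALSE)
    rp <- new("RankedPairSet", pairs = pairs,
              totals = c(`PCG-PCG` = 1L, `PCG-lncRNA` = 1L,
                         `miRNA-PCG` = 1L, `miRNA-lncRNA` = 1L),
              provenance = list(cutoff = NA_real_, seedFiltered = FALSE))
    net <- buildNetwork(rp)
    expect_setequal(nodeIds(net), c("p1", "p2", "l1", "m1"))
    expect_identical(nrow(edgeTable(net)), 4L)
    ## same unordered pair in two categories collapses to one edge with
    ## both labels
    pairs2 <- rbind(pairs,
                    data.frame(gene_a = "l1", gene_b = "m1",
                               category = "PCG-lncRNA", pcc = -0.6,
                               rank = 2L, stringsAsFactors = FALSE))
    rp2 <- rp; rp2@pairs <- pairs2
    net2 <- buildNetwork(rp2)
    expect_identical(nrow(edgeTable(net2)), 4L)
    e <- edgeTable(net2)
    lab <- e$category[e$node_a == "l1" & e$node_b == "m1"]
    expect_identical(lab, "PCG-lncRNA,miRNA-lncRNA")
    ## node set equals union of endpoints on random input
    se <- makeExpr(seed = 23)
    th <- thresholdPairs(computePairs(se), 10)
    nn <- buildNetwork(th, biotype = biotype(se))
    expect_setequal(nodeIds(nn),
                    unique(c(pairTable(th)$gene_a, pairTable(th)$gene_b)))
})
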