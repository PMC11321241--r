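test_that("median split sends ties high and guards degenerate sides", {
    m <- matrix(rnorm(4 * 6), 4, 6,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
    se <- StemnessExperiment(m, setNames(rep("PCG", 4), rownames(m)))
    idx <- setNames(c(0.1, 0.2, 0.5, 0.5, 0.8, 0.9), colnames(m))
    sp <- medianSplit(se, idx)
    expect_setequal(sp$low, c("s1", "s2"))
    expect_setequal(sp$high, c("s3", "s4", "s5", "s6"))
    ## odd count: median sample itself goes high, leaving one low sample
    m3 <- m[, 1:3]
    se3 <- StemnessExperiment(m3, setNames(rep("PCG", 4), rownames(m)))
    expect_error(medianSplit(se3, setNames(c(0.1, 0.5, 0.9), colnames(m3))),
                 "degenerate median split")
})

test_that("group sizes differ by at most one when indices are distinct", {
    set.seed(5)
    for (n in c(6, 9, 12, 15)) {
        m <- matrix(rnorm(2 * n), 2, n,
                    dimnames = list(c("g1", "g2"), paste0("s", 1:n)))
        se <- StemnessExperiment(m, c(g1 = "PCG", g2 = "PCG"))
        idx <- setNames(sample(seq_len(n)) / (n + 1), colnames(m))
        sp <- medianSplit(se, idx)
        expect_lte(abs(length(sp$low) - length(sp$high)), 1)
        expect_identical(sort(c(sp$low, sp$high)), sort(colnames(m)))
    }
})

test_that("log2 fold-change boundary is strict and null data are never flagged", {
    ## mean ratio exactly 2 after pseudocount: log2fc = 1, NOT DE
    lowVals <- c(2, 3, 4, 3, 2, 4)   # mean 3 -> 3 + 1 = 4
    hiVals <- c(6, 8, 7, 7, 6, 8)    # mean 7 -> 7 + 1 = 8
    m <- rbind(gBoundary = c(lowVals, hiVals),
               gNull = rep(c(1, 2), 6))
    colnames(m) <- paste0("s", 1:12)
    se <- StemnessExperiment(m, c(gBoundary = "PCG", gNull = "PCG"))
    groups <- list(low = paste0("s", 1:6), high = paste0("s", 7:12))
    de <- differentialExpression(se, groups)
    expect_equal(de$log2fc[de$gene_id == "gBoundary"], 1)
    expect_false(de$is_de[de$gene_id == "gBoundary"])
    ## identical group distributions: nothing is DE
    set.seed(8)
    m2 <- matrix(rnorm(20 * 12, mean = 5), 20, 12,
                 dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:12)))
    se2 <- StemnessExperiment(m2, setNames(rep("lncRNA", 20), rownames(m2)))
    de2 <- differentialExpression(se2, groups)
    expect_false(any(de2$is_de))
    ## constant gene gets p = 1 and the flag
    m3 <- rbind(m2, gConst = rep(4, 12))
    se3 <- StemnessExperiment(m3, setNames(rep("PCG", 21), rownames(m3)))
    de3 <- differentialExpression(se3, groups)
    expect_equal(de3$p_value[de3$gene_id == "gConst"], 1)
    expect_true(de3$constant[de3$gene_id == "gConst"])
})

test_that("BH adjustment is monotone and never below the raw p", {
    set.seed(12)
    m <- matrix(rnorm(50 * 10, mean = 5), 50, 10,
                dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:10)))
    m[1:5, 6:10] <- m[1:5, 6:10] + 4
    se <- StemnessExperiment(m, setNames(rep("PCG", 50), rownames(m)))
    de <- differentialExpression(se, list(low = paste0("s", 1:5),
                                          high = paste0("s", 6:10)))
    expect_true(all(de$fdr >= de$p_value - 1e-12))
    ord <- order(de$p_value)
    expect_true(all(diff(de$fdr[ord]) >= -1e-12))
    expect_equal(de$fdr, p.adjust(de$p_value, "BH"))
})

test_that("DE flags are invariant to sample and gene order", {
    set.seed(33)
    m <- matrix(rnorm(30 * 14, mean = 6), 30, 14,
                dimnames = list(sprintf("g%02d", 1:30), paste0("s", 1:14)))
    m[1:4, 8:14] <- m[1:4, 8:14] + 5
    bt <- setNames(rep("PCG", 30), rownames(m))
    groups <- list(low = paste0("s", 1:7), high = paste0("s", 8:14))
    de1 <- differentialExpression(StemnessExperiment(m, bt), groups)
    perm <- sample(nrow(m))
    spurl <- sample(ncol(m))
    de2 <- differentialExpression(
        StemnessExperiment(m[perm, spurl], bt), groups)
    de2 <- de2[match(de1$gene_id, de2$gene_id), ]
    expect_identical(de1$is_de, de2$is_de)
    expect_equal(de1$log2fc, de2$log2fc)
})

test_that("planted 4-fold genes are recovered with controlled false positives", {
    ## 10 planted 4-fold genes among 200 nulls, 20 samples per side
    recall <- numeric(3)
    fpr <- numeric(3)
    for (r in 1:3) {
        set.seed(400 + r)
        nLow <- 20; nHigh <- 20
        nulls <- matrix(rnorm(200 * 40, mean = 10, sd = 2), 200, 40)
        ## planted genes: low-group mean 10, high-group mean 40 (4-fold)
        planted <- cbind(matrix(rnorm(10 * 20, mean = 10, sd = 2), 10, 20),
                         matrix(rnorm(10 * 20, mean = 40, sd = 8), 10, 20))
        m <- rbind(planted, nulls)
        rownames(m) <- c(sprintf("de%02d", 1:10), sprintf("null%03d", 1:200))
        colnames(m) <- paste0("s", 1:40)
        se <- StemnessExperiment(m, setNames(rep("PCG", 210), rownames(m)))
        de <- differentialExpression(se, list(low = paste0("s", 1:20),
                                              high = paste0("s", 21:40)))
        recall[r] <- sum(de$is_de[1:10])
        fpr[r] <- mean(de$is_de[11:210])
    }
    expect_gte(median(recall), 9)
    expect_lte(median(fpr), 0.05)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
    ## N=10, K=5, n=5, k=5 -> 1 / C(10,5) = 1/252
    u <- sprintf("g%02d", 1:10)
    r <- enrichmentTest(u[1:5], u[1:5], u)
    expect_equal(r$p_value, 1 / choose(10, 5), tolerance = 1e-12)
    ## k = 0 with K, n > 0: upper tail is 1
    r0 <- enrichmentTest(u[1:3], u[4:6], u)
    expect_equal(r0$p_value, 1)
    ## exhaustive oracle over all C(N, n) draws for small universes
    cases <- expand.grid(N = c(8, 10, 12), K = c(3, 5), n = c(3, 4))
    for (i in seq_len(nrow(cases))) {
        N <- cases$N[i]; K <- cases$K[i]; n <- cases$n[i]
        uu <- sprintf("x%02d", seq_len(N))
        for (k in max(0, n - (N - K)):min(K, n)) {
            pred <- c(uu[seq_len(k)],
                      if (n > k) uu[(K + 1):(K + n - k)])
            r <- enrichmentTest(pred, uu[seq_len(K)], uu)
            expect_identical(r$k, k)
            expect_equal(r$p_value, hyperOracle(N, K, n, k),
                         tolerance = 1e-12)
        }
    }
    expect_error(enrichmentTest("a", "a", character()), "empty universe")
    expect_error(enrichmentTest("zz", u[1:2], u), "subset")
})
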