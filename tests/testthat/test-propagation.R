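test_that("transition matrix implements row normalization with the zero-row branch", {
    ## triangle: every row is (0, 1/2, 1/2) up to permutation
    tri <- stemNetwork(data.frame(a = c("a", "a", "b"),
                                  b = c("b", "c", "c")))
    W <- buildTransition(tri)@W
    expect_equal(unname(sort(W[1, ])), c(0, 0.5, 0.5))
    expect_equal(rowSums(W), c(a = 1, b = 1, c = 1))
    ## single edge
    ab <- stemNetwork(data.frame(a = "a", b = "b"))
    expect_equal(unname(buildTransition(ab)@W),
                 matrix(c(0, 1, 1, 0), 2, 2))
    ## isolated node gets an all-zero row
    iso <- stemNetwork(data.frame(a = "a", b = "b"), nodes = c("a", "b", "c"))
    Wi <- buildTransition(iso)@W
    expect_equal(unname(Wi["c", ]), c(0, 0, 0))
    expect_error(buildTransition(stemNetwork(
        data.frame(a = character(), b = character()))), "empty network")
})

test_that("restart vector puts 1/n on present seeds and renormalizes over dropped ones", {
    nodes <- c("a", "b", "c", "d", "e")
    p0 <- makeP0(nodes, c("a", "b"))
    expect_equal(unname(p0), c(0.5, 0.5, 0, 0, 0))
    expect_equal(sum(p0), 1)
    expect_warning(p1 <- makeP0(nodes, c("a", "b", "zz")), "absent")
    expect_equal(unname(p1[c("a", "b")]), c(0.5, 0.5))
    expect_error(makeP0(nodes, "zz"), "no seed is present")
})

test_that("two-node closed form: seed one end of a single edge at alpha 0.5", {
    net <- stemNetwork(data.frame(a = "a", b = "b"))
    W <- buildTransition(net)
    p0 <- makeP0(W@nodes, "a")
    sol <- rwrSolve(W, p0, alpha = 0.5)
    expect_equal(unname(sol), c(2 / 3, 1 / 3), tolerance = 1e-14)
    it <- rwrIterate(W, p0, alpha = 0.5, tol = 1e-12)
    expect_true(it@converged)
    expect_equal(unname(propScores(it)), c(2 / 3, 1 / 3), tolerance = 1e-10)
})

test_that("iteration matches the linear-solve oracle on random graphs", {
    for (i in 1:8) {
        net <- erdosRenyi(20 + 10 * i, 0.15, seed = 100 + i)
        W <- buildTransition(net)
        set.seed(200 + i)
        p0 <- makeP0(W@nodes, sample(nodeIds(net), 3))
        for (alpha in c(0.1, 0.5, 0.9)) {
            it <- rwrIterate(W, p0, alpha = alpha, tol = 1e-12)
            sol <- rwrSolve(W, p0, alpha = alpha)
            expect_l1_close(propScores(it), sol, 1e-9)
            ## fixed-point residual of the solve itself
            M <- t(W@W)
            resid <- sol - (1 - alpha) * as.numeric(M %*% sol) - alpha * p0
            expect_lt(sqrt(sum(resid^2)), 1e-10)
        }
    }
})

test_that("probability mass is conserved and contraction is geometric", {
    net <- erdosRenyi(40, 0.2, seed = 55, connectedRetry = TRUE)
    W <- buildTransition(net)
    set.seed(56)
    p0 <- makeP0(W@nodes, sample(nodeIds(net), 4))
    it <- rwrIterate(W, p0, alpha = 0.5, tol = 1e-10)
    expect_lt(it@details$massDrift, 1e-9)
    expect_lte(it@iterations, 40L)
    expect_true(it@converged)
    expect_equal(sum(propScores(it)), 1, tolerance = 1e-9)
})

test_that("restart-probability limits behave as expected", {
    net <- erdosRenyi(25, 0.25, seed = 61, connectedRetry = TRUE)
    W <- buildTransition(net)
    set.seed(62)
    seeds <- sample(nodeIds(net), 3)
    p0 <- makeP0(W@nodes, seeds)
    ## alpha -> 1: scores approach p0
    hi <- rwrSolve(W, p0, alpha = 0.999)
    expect_l1_close(hi, p0, 0.01)
    ## alpha -> 0+: scores approach the degree-proportional stationary
    ## distribution on a connected non-bipartite graph
    lo <- rwrSolve(W, p0, alpha = 1e-6)
    e <- edgeTable(net)
    deg <- table(factor(c(e$node_a, e$node_b), levels = nodeIds(net)))
    expect_l1_close(lo, as.numeric(deg) / sum(deg), 1e-3)
})

test_that("scores are equivariant under node relabeling", {
    net <- erdosRenyi(15, 0.3, seed = 71)
    e <- edgeTable(net)
    map <- setNames(sprintf("z%03d", rev(seq_along(nodeIds(net)))),
                    nodeIds(net))
    net2 <- stemNetwork(data.frame(a = map[e$node_a], b = map[e$node_b]),
                        nodes = unname(map))
    seeds <- nodeIds(net)[1:2]
    s1 <- propScores(rwrScore(net, seeds))
    s2 <- propScores(rwrScore(net2, map[seeds]))
    expect_equal(unname(s2[map[names(s1)]]), unname(s1), tolerance = 1e-12)
})

test_that("isolated seed leaks mass toward alpha * p0", {
    ## one-node no-edge graph: fixed point is alpha * p0
    net <- stemNetwork(data.frame(a = "a", b = "b"), nodes = c("a", "b", "s"))
    W <- buildTransition(net)
    p0 <- makeP0(W@nodes, "s")
    sol <- rwrSolve(W, p0, alpha = 0.5)
    expect_equal(unname(sol["s"]), 0.5)
    expect_equal(unname(sol[c("a", "b")]), c(0, 0))
})

test_that("literal (untransposed) update is available and agrees on symmetric-degree graphs", {
    ## on a regular graph W is symmetric, so both orientations coincide
    ring <- stemNetwork(data.frame(a = c("a", "b", "c", "d"),
                                   b = c("b", "c", "d", "a")))
    W <- buildTransition(ring)
    p0 <- makeP0(W@nodes, "a")
    expect_equal(rwrSolve(W, p0, literal = TRUE),
                 rwrSolve(W, p0, literal = FALSE), tolerance = 1e-12)
    ## on an irregular graph the literal form does not conserve mass
    star <- stemNetwork(data.frame(a = rep("h", 3),
                                   b = c("x", "y", "z")))
    Ws <- buildTransition(star)
    ps <- makeP0(Ws@nodes, "h")
    lit <- rwrIterate(Ws, ps, literal = TRUE)
    expect_gt(lit@details$massDrift, 1e-3)
    std <- rwrIterate(Ws, ps, literal = FALSE)
    expect_lt(std@details$massDrift, 1e-9)
})

test_that("non-convergence warns and flags instead of erroring", {
    net <- erdosRenyi(30, 0.2, seed = 81)
    W <- buildTransition(net)
    set.seed(82)
    p0 <- makeP0(W@nodes, sample(nodeIds(net), 3))
    expect_warning(out <- rwrIterate(W, p0, alpha = 0.5, tol = 1e-12,
                                     maxIter = 2), "did not converge")
    expect_false(out@converged)
    expect_identical(out@iterations, 2L)
})
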