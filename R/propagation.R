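## Random walk with restart on a gene network.
##
## The transition matrix row-normalizes the binary adjacency:
##   w(i,j) = A(i,j) / sum_j A(i,j)   if the row sum is nonzero
##   w(i,j) = 0                        otherwise.
## The update p_{t+1} = (1 - alpha) M p_t + alpha p_0 is applied with
## M = t(W) by default, the standard RWR convention under which
## probability mass flows OUT of each node in proportion to its
## normalized weights and is conserved on graphs without isolated
## nodes. On symmetric-degree graphs M = W and both conventions agree;
## the literal M = W form is available via `literal = TRUE`.

#' Build the probability transition matrix of a network
#'
#' Row-normalizes the binary adjacency matrix (edge present = 1) of an
#' undirected network; rows of isolated nodes are all zero. Node order
#' is the sorted gene id vector.
#'
#' @param net a \linkS4class{StemNetwork}; edge weights are ignored
#'   unless \code{weighted = TRUE}, in which case \code{|pcc|} is used.
#' @param weighted logical; default FALSE (binary adjacency).
#' @return A \linkS4class{TransitionMatrix}.
#' @export
buildTransition <- function(net, weighted = FALSE) {
    stopifnot(is(net, "StemNetwork"))
    nodes <- sort(net@nodes)
    n <- length(nodes)
    if (n == 0)
        stop("empty network")
    A <- matrix(0, n, n, dimnames = list(nodes, nodes))
    e <- net@edges
    if (nrow(e)) {
        w <- if (weighted) abs(e$pcc) else rep(1, nrow(e))
        A[cbind(e$node_a, e$node_b)] <- w
        A[cbind(e$node_b, e$node_a)] <- w
    }
    rs <- rowSums(A)
    nz <- rs > 0
    W <- A
    W[nz, ] <- A[nz, , drop = FALSE] / rs[nz]
    methods::new("TransitionMatrix", nodes = nodes, W = W)
}

#' Build the initial probability vector from seeds
#'
#' Each seed node present in the network receives probability 1/n
#' (n = number of present seeds); all other nodes 0. Seeds absent from
#' the network are dropped with a warning and n is recomputed over the
#' present ones, keeping the vector normalized.
#'
#' @param nodes node order (character), e.g. \code{nodeIds(W)}.
#' @param seeds character vector of seed ids.
#' @return Named numeric vector summing to 1.
#' @export
makeP0 <- function(nodes, seeds) {
    present <- intersect(seeds, nodes)
    if (!length(present))
        stop("no seed is present in the network")
    absent <- setdiff(seeds, nodes)
    if (length(absent))
        warning(length(absent), " seed(s) absent from the network dropped; ",
                "1/n recomputed over ", length(present), " present seeds")
    p0 <- stats::setNames(numeric(length(nodes)), nodes)
    p0[present] <- 1 / length(present)
    p0
}

.propagationOperator <- function(W, literal = FALSE) {
    if (literal) W@W else t(W@W)
}

.rankScores <- function(scores) {
    ord <- order(-scores, names(scores))
    r <- integer(length(scores))
    r[ord] <- seq_along(scores)
    stats::setNames(r, names(scores))
}

#' Iterate the random walk with restart to its stationary distribution
#'
#' Repeats \code{p <- (1 - alpha) * M p + alpha * p0} until the L1
#' change between successive iterates falls below \code{tol} or
#' \code{maxIter} is reached. Convergence is geometric with ratio at
#' most \code{1 - alpha}. Non-convergence yields a warning and
#' \code{converged = FALSE}, not an error.
#'
#' @param W a \linkS4class{TransitionMatrix}.
#' @param p0 initial probability vector in the node order of \code{W}
#'   (see \code{\link{makeP0}}).
#' @param alpha restart probability in (0, 1); default 0.5.
#' @param tol L1 convergence tolerance; default 1e-10.
#' @param maxIter iteration cap; default 1000.
#' @param literal apply the row-normalized matrix as written
#'   (\code{M = W}) instead of its transpose; default FALSE.
#' @return A \linkS4class{PropagationResult}; \code{x@details$massDrift}
#'   records the largest deviation of \code{sum(p_t)} from 1 seen
#'   across iterates.
#' @export
rwrIterate <- function(W, p0, alpha = 0.5, tol = 1e-10, maxIter = 1000,
                       literal = FALSE) {
    stopifnot(is(W, "TransitionMatrix"))
    .checkAlpha(alpha)
    if (tol <= 0) stop("'tol' must be > 0")
    p0 <- .alignP0(W, p0)
    M <- .propagationOperator(W, literal)
    p <- p0
    drift <- abs(sum(p) - 1)
    converged <- FALSE
    iter <- 0L
    while (iter < maxIter) {
        iter <- iter + 1L
        pn <- as.numeric((1 - alpha) * (M %*% p) + alpha * p0)
        drift <- max(drift, abs(sum(pn) - 1))
        delta <- sum(abs(pn - p))
        p <- pn
        if (delta < tol) {
            converged <- TRUE
            break
        }
    }
    if (!converged)
        warning("RWR did not converge within ", maxIter, " iterations")
    scores <- stats::setNames(p, W@nodes)
    methods::new("PropagationResult", scores = scores,
                 ranks = .rankScores(scores), iterations = iter,
                 converged = converged, alpha = alpha,
                 details = list(massDrift = drift, tol = tol,
                                literal = literal))
}

#' Solve the RWR fixed point exactly
#'
#' Computes the stationary distribution as the solution of
#' \code{(I - (1 - alpha) M) p = alpha p0} by a dense linear solve.
#' Intended as the exact oracle for small networks; for alpha in (0, 1)
#' and a (sub)stochastic operator the system is nonsingular.
#'
#' @inheritParams rwrIterate
#' @return Named numeric vector of stationary scores.
#' @export
rwrSolve <- function(W, p0, alpha = 0.5, literal = FALSE) {
    stopifnot(is(W, "TransitionMatrix"))
    .checkAlpha(alpha)
    p0 <- .alignP0(W, p0)
    M <- .propagationOperator(W, literal)
    n <- length(W@nodes)
    p <- solve(diag(n) - (1 - alpha) * M, alpha * p0)
    stats::setNames(as.numeric(p), W@nodes)
}

.checkAlpha <- function(alpha) {
    if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
        stop("'alpha' must lie in (0, 1)")
}

.alignP0 <- function(W, p0) {
    if (length(p0) != length(W@nodes))
        stop("p0 length does not match the transition matrix")
    if (!is.null(names(p0))) {
        if (!setequal(names(p0), W@nodes))
            stop("p0 names do not match the transition matrix nodes")
        p0 <- p0[W@nodes]
    }
    if (any(p0 < 0)) stop("p0 entries must be >= 0")
    as.numeric(p0)
}

#' Run RWR on a network from a seed set
#'
#' Convenience wrapper: builds the transition matrix, the seed restart
#' vector, and the stationary scores (exact solve for networks up to
#' \code{solveLimit} nodes, power iteration otherwise).
#'
#' @param net a \linkS4class{StemNetwork}.
#' @param seeds character vector of seed gene ids.
#' @param alpha restart probability; default 0.5.
#' @param tol,maxIter,literal passed to \code{\link{rwrIterate}}.
#' @param solveLimit use the dense linear solve when the network has at
#'   most this many nodes; default 2000.
#' @return A \linkS4class{PropagationResult}.
#' @export
rwrScore <- function(net, seeds, alpha = 0.5, tol = 1e-10, maxIter = 1000,
                     literal = FALSE, solveLimit = 2000) {
    W <- buildTransition(net)
    p0 <- makeP0(W@nodes, seeds)
    if (length(W@nodes) <= solveLimit) {
        scores <- rwrSolve(W, p0, alpha = alpha, literal = literal)
        methods::new("PropagationResult", scores = scores,
                     ranks = .rankScores(scores), iterations = 0L,
                     converged = TRUE, alpha = alpha,
                     details = list(method = "solve", literal = literal))
    } else {
        rwrIterate(W, p0, alpha = alpha, tol = tol, maxIter = maxIter,
                   literal = literal)
    }
}
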