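#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats cor var quantile median p.adjust phyper wilcox.test
#'   t.test rnorm plogis setNames
#' @importFrom utils read.delim write.table head
NULL

## Biotype vocabulary. TF is a distinct biotype for regulatory-category
## validation but collapses onto PCG for co-expression pair categories.
.BIOTYPES <- c("PCG", "TF", "lncRNA", "miRNA")

## The four co-expression pair categories; names encode the biotype of
## gene_a and gene_b respectively (TF counted as PCG).
.COEX_CATEGORIES <- c("PCG-PCG", "PCG-lncRNA", "miRNA-PCG", "miRNA-lncRNA")

## The eight regulatory interaction categories.
.REG_CATEGORIES <- c("TF-miRNA", "TF-lncRNA", "TF-PCG", "miRNA-lncRNA",
                     "miRNA-TF", "miRNA-PCG", "lncRNA-TF", "lncRNA-PCG")

#' StemnessExperiment: expression matrix with per-gene biotypes
#'
#' A \linkS4class{SummarizedExperiment} holding a genes x samples
#' expression matrix (assay \code{"expr"}) in which every gene carries a
#' biotype annotation (\code{rowData(x)$biotype}, one of \code{"PCG"},
#' \code{"TF"}, \code{"lncRNA"}, \code{"miRNA"}). An optional per-sample
#' stemness index in \code{[0, 1]} may be stored as
#' \code{colData(x)$stemnessIndex}.
#'
#' Expression units are taken as supplied and assumed comparable on a
#' log-like scale; no transformation is applied by the constructor.
#'
#' @slot .. inherited from \code{SummarizedExperiment}.
#' @seealso \code{\link{StemnessExperiment}} (constructor),
#'   \code{\link{biotype}}, \code{\link{stemnessIndex}}
#' @export
setClass("StemnessExperiment", contains = "SummarizedExperiment")

setValidity("StemnessExperiment", function(object) {
    msg <- character()
    if (!"expr" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'expr' is required")
    g <- rownames(object)
    s <- colnames(object)
    if (is.null(g) || anyDuplicated(g))
        msg <- c(msg, "gene ids must be present and unique")
    if (is.null(s) || anyDuplicated(s))
        msg <- c(msg, "sample ids must be present and unique")
    if (ncol(object) < 3L)
        msg <- c(msg, "at least 3 samples are required")
    bt <- SummarizedExperiment::rowData(object)$biotype
    if (is.null(bt)) {
        msg <- c(msg, "rowData column 'biotype' is required")
    } else if (!all(bt %in% .BIOTYPES)) {
        bad <- unique(bt[!bt %in% .BIOTYPES])
        msg <- c(msg, sprintf("unknown biotype(s): %s",
                              paste(bad, collapse = ", ")))
    }
    if ("expr" %in% SummarizedExperiment::assayNames(object) &&
        !all(is.finite(SummarizedExperiment::assay(object, "expr"))))
        msg <- c(msg, "expression values must be finite")
    si <- SummarizedExperiment::colData(object)$stemnessIndex
    if (!is.null(si) && any(!is.na(si) & (si < 0 | si > 1)))
        msg <- c(msg, "stemnessIndex values must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' RankedPairSet: scored gene pairs grouped and ranked by category
#'
#' Gene pairs with Pearson correlation coefficients, grouped into the
#' four co-expression categories and ranked within each category by the
#' category's rank rule (absolute PCC descending for PCG-PCG and
#' PCG-lncRNA; signed PCC ascending, i.e. most negative first, for
#' miRNA-PCG and miRNA-lncRNA).
#'
#' @slot pairs data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{category}, \code{pcc}, \code{rank}.
#' @slot totals named integer vector: per-category pair count before any
#'   thresholding.
#' @slot provenance list recording \code{cutoff} (percent, NA if
#'   unthresholded) and \code{seedFiltered} (logical).
#' @export
setClass("RankedPairSet",
    representation(pairs = "data.frame", totals = "integer",
                   provenance = "list"),
    prototype(pairs = data.frame(gene_a = character(), gene_b = character(),
                                 category = character(), pcc = numeric(),
                                 rank = integer(),
                                 stringsAsFactors = FALSE),
              totals = integer(),
              provenance = list(cutoff = NA_real_, seedFiltered = FALSE)))

setValidity("RankedPairSet", function(object) {
    p <- object@pairs
    msg <- character()
    need <- c("gene_a", "gene_b", "category", "pcc", "rank")
    if (!all(need %in% names(p)))
        return(sprintf("pairs must have columns %s",
                       paste(need, collapse = ", ")))
    if (any(p$gene_a == p$gene_b))
        msg <- c(msg, "self-pairs are not allowed")
    if (!all(p$category %in% .COEX_CATEGORIES))
        msg <- c(msg, "pair categories must be one of the four co-expression categories")
    if (any(!is.finite(p$pcc)))
        msg <- c(msg, "pcc values must be finite")
    for (cc in unique(p$category)) {
        r <- p$rank[p$category == cc]
        if (anyDuplicated(r) || any(r < 1L))
            msg <- c(msg, sprintf("ranks within %s must be unique positive integers", cc))
    }
    if (length(msg)) msg else TRUE
})

#' StemNetwork: undirected gene network with biotype-labeled nodes
#'
#' Undirected network used for random-walk propagation. Edges carry one
#' or more category labels (comma-separated when an unordered node pair
#' arises in several categories) and the PCC of the underlying
#' co-expression pair. Regulatory networks produced by
#' \code{\link{intersectRegulatory}} use the same class with the eight
#' regulatory categories and \code{provenance$kind == "regulatory"}.
#'
#' @slot nodes character vector of gene ids (unique).
#' @slot biotype named character vector over \code{nodes}.
#' @slot edges data.frame with columns \code{node_a}, \code{node_b},
#'   \code{category}, \code{pcc}; unordered pairs, no duplicates, no
#'   self-loops.
#' @slot provenance list: \code{kind}, \code{cutoff}, \code{seedFiltered}.
#' @export
setClass("StemNetwork",
    representation(nodes = "character", biotype = "character",
                   edges = "data.frame", provenance = "list"),
    prototype(nodes = character(), biotype = character(),
              edges = data.frame(node_a = character(), node_b = character(),
                                 category = character(), pcc = numeric(),
                                 stringsAsFactors = FALSE),
              provenance = list(kind = "coexpression", cutoff = NA_real_,
                                seedFiltered = FALSE)))

setValidity("StemNetwork", function(object) {
    msg <- character()
    if (anyDuplicated(object@nodes))
        msg <- c(msg, "duplicate node ids")
    if (!setequal(names(object@biotype), object@nodes))
        msg <- c(msg, "biotype must be named over exactly the node set")
    e <- object@edges
    if (nrow(e)) {
        if (any(e$node_a == e$node_b))
            msg <- c(msg, "self-loops are not allowed")
        key <- paste(pmin(e$node_a, e$node_b), pmax(e$node_a, e$node_b))
        if (anyDuplicated(key))
            msg <- c(msg, "duplicate edges (as unordered pairs)")
        if (!all(c(e$node_a, e$node_b) %in% object@nodes))
            msg <- c(msg, "edge endpoints must be nodes")
    }
    if (length(msg)) msg else TRUE
})

#' TransitionMatrix: row-normalized adjacency for random walks
#'
#' The probability transition matrix W with
#' \code{w(i,j) = A(i,j) / sum_j A(i,j)} when row i has nonzero sum and 0
#' otherwise, where A is the binary adjacency matrix of a
#' \linkS4class{StemNetwork}. Node order is the sorted node id vector.
#'
#' @slot nodes character vector giving the row/column order.
#' @slot W square numeric matrix; each row sums to 1 (degree > 0) or 0
#'   (isolated node).
#' @export
setClass("TransitionMatrix",
    representation(nodes = "character", W = "matrix"))

setValidity("TransitionMatrix", function(object) {
    msg <- character()
    n <- length(object@nodes)
    if (!all(dim(object@W) == c(n, n)))
        msg <- c(msg, "W dimensions must match node count")
    if (n > 0) {
        if (any(object@W < 0) || any(object@W > 1))
            msg <- c(msg, "entries must lie in [0, 1]")
        rs <- rowSums(object@W)
        if (!all(abs(rs - 1) < 1e-8 | abs(rs) < 1e-12))
            msg <- c(msg, "each row must sum to 1 or 0")
    }
    if (length(msg)) msg else TRUE
})

#' PropagationResult: stationary RWR scores and ranks
#'
#' @slot scores named numeric vector of stationary probabilities, in
#'   transition-matrix node order.
#' @slot ranks named integer vector; a permutation of 1..N, rank 1 =
#'   highest score, ties broken by lexicographic gene id.
#' @slot iterations integer; 0 for the direct linear solve.
#' @slot converged logical.
#' @slot alpha restart probability used.
#' @slot details list (e.g. \code{massDrift}: max deviation of
#'   \code{sum(p_t)} from 1 across iterates).
#' @export
setClass("PropagationResult",
    representation(scores = "numeric", ranks = "integer",
                   iterations = "integer", converged = "logical",
                   alpha = "numeric", details = "list"))

setValidity("PropagationResult", function(object) {
    msg <- character()
    n <- length(object@scores)
    if (length(object@ranks) != n)
        msg <- c(msg, "ranks and scores lengths differ")
    if (n && !setequal(object@ranks, seq_len(n)))
        msg <- c(msg, "ranks must be a permutation of 1..N")
    if (!identical(names(object@scores), names(object@ranks)))
        msg <- c(msg, "scores and ranks must share names")
    if (length(msg)) msg else TRUE
})

#' PermutationNull: pseudo-seed permutation null for RWR scores
#'
#' Per-node null score distributions from repeated RWR runs with
#' pseudo-seed sets of the same size as the real seed set, with add-one
#' empirical p-values and significance calls.
#'
#' @slot nodes node order (matches the propagation node order).
#' @slot trueScores named numeric vector of observed RWR scores.
#' @slot nullScores numeric matrix, nodes x permutations; NA where the
#'   node was itself a pseudo-seed in that draw (its score there is not
#'   a null observation).
#' @slot empiricalP named numeric vector in [1/(nPerm+1), 1].
#' @slot significant named logical; \code{empiricalP <= level}.
#' @slot seeds the real seed ids present in the network.
#' @slot level significance level (default 0.05).
#' @slot nPerm number of permutations.
#' @slot rngSeed integer seed governing the pseudo-seed draws.
#' @slot pooled logical; TRUE if p-values were computed against the
#'   pooled null rather than per-node nulls.
#' @export
setClass("PermutationNull",
    representation(nodes = "character", trueScores = "numeric",
                   nullScores = "matrix", empiricalP = "numeric",
                   significant = "logical", seeds = "character",
                   level = "numeric", nPerm = "integer",
                   rngSeed = "integer", pooled = "logical"))

setValidity("PermutationNull", function(object) {
    msg <- character()
    n <- length(object@nodes)
    if (length(object@empiricalP) != n || length(object@significant) != n)
        msg <- c(msg, "per-node vectors must match node count")
    if (nrow(object@nullScores) != n)
        msg <- c(msg, "nullScores rows must match node count")
    ## per-node nulls have at most nPerm observations per node; the
    ## pooled variant draws on every node's null scores, so its floor
    ## is lower
    lo <- if (object@pooled) 0 else 1 / (object@nPerm + 1)
    if (n && (any(object@empiricalP <= lo - 1e-12) ||
              any(object@empiricalP == 0) || any(object@empiricalP > 1)))
        msg <- c(msg, "empirical p-values must lie in (0, 1] and respect the add-one floor")
    if (length(msg)) msg else TRUE
})
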