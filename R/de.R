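## Median-split differential expression by stemness index and
## hypergeometric enrichment of predicted ncRNA sets in DE ncRNA sets.

#' Split samples at the median stemness index
#'
#' Samples with index strictly below the median form the low-stemness
#' group; samples at or above the median go to the high group (the tie
#' rule is deterministic and documented). Both sides must keep at least
#' 2 samples.
#'
#' @param x a \linkS4class{StemnessExperiment} (only its sample ids are
#'   used; the index may also live in \code{colData(x)$stemnessIndex}).
#' @param index named numeric vector of stemness indices in [0, 1];
#'   defaults to \code{stemnessIndex(x)}. Names must be a subset of the
#'   sample ids of \code{x}.
#' @return list with character vectors \code{low} and \code{high} of
#'   sample ids, and \code{median} (the threshold used).
#' @export
medianSplit <- function(x, index = stemnessIndex(x)) {
    stopifnot(is(x, "StemnessExperiment"))
    if (is.null(index))
        stop("no stemness index supplied and none stored in the object")
    index <- index[!is.na(index)]
    extra <- setdiff(names(index), colnames(x))
    if (length(extra))
        stop("index sample(s) absent from expression matrix: ",
             paste(extra, collapse = ", "))
    med <- stats::median(index)
    low <- names(index)[index < med]
    high <- names(index)[index >= med]
    if (length(low) < 2 || length(high) < 2)
        stop("degenerate median split: low side has ", length(low),
             " and high side ", length(high),
             " samples (both need >= 2)")
    list(low = low, high = high, median = med)
}

#' Differential expression between two sample groups
#'
#' Per gene: \code{log2fc = log2((mean_high + c) / (mean_low + c))}
#' with pseudocount \code{c}; a two-sided Wilcoxon rank-sum p-value
#' (Student's t by \code{test = "t"}); Benjamini-Hochberg FDR over all
#' tested genes; \code{is_de} when \code{|log2fc| > lfcThreshold}
#' (strict) and \code{fdr < fdrThreshold} (strict). A gene constant
#' across all samples gets p = 1 by convention and is flagged in the
#' \code{constant} column.
#'
#' @param x a \linkS4class{StemnessExperiment} or numeric matrix.
#' @param groups list with \code{low} and \code{high} sample id
#'   vectors, as from \code{\link{medianSplit}}; each side needs >= 2
#'   samples.
#' @param lfcThreshold absolute log2 fold-change threshold; default 1.
#' @param fdrThreshold FDR threshold; default 0.05.
#' @param pseudocount added to both group means before the ratio;
#'   default 1 expression unit.
#' @param test \code{"wilcox"} (default) or \code{"t"}.
#' @return data.frame with columns gene_id, log2fc, p_value, fdr,
#'   is_de, constant (one row per gene, input order).
#' @export
differentialExpression <- function(x, groups, lfcThreshold = 1,
                                   fdrThreshold = 0.05, pseudocount = 1,
                                   test = c("wilcox", "t")) {
    test <- match.arg(test)
    m <- if (is(x, "StemnessExperiment")) exprValues(x) else x
    if (!all(c(groups$low, groups$high) %in% colnames(m)))
        stop("group sample ids not all present in the expression matrix")
    if (length(groups$low) < 2 || length(groups$high) < 2)
        stop("both groups need at least 2 samples")
    lo <- m[, groups$low, drop = FALSE]
    hi <- m[, groups$high, drop = FALSE]
    meanLo <- rowMeans(lo)
    meanHi <- rowMeans(hi)
    ratio <- (meanHi + pseudocount) / (meanLo + pseudocount)
    if (any(ratio <= 0))
        stop("non-positive mean ratio after pseudocount; increase ",
             "'pseudocount' for data on this scale")
    log2fc <- log2(ratio)
    constant <- apply(m[, c(groups$low, groups$high), drop = FALSE], 1,
                      function(v) length(unique(v)) == 1L)
    p <- vapply(seq_len(nrow(m)), function(i) {
        if (constant[i]) return(1)
        if (test == "wilcox")
            suppressWarnings(stats::wilcox.test(hi[i, ], lo[i, ])$p.value)
        else
            stats::t.test(hi[i, ], lo[i, ])$p.value
    }, numeric(1))
    fdr <- stats::p.adjust(p, method = "BH")
    data.frame(gene_id = rownames(m), log2fc = log2fc, p_value = p,
               fdr = fdr,
               is_de = abs(log2fc) > lfcThreshold & fdr < fdrThreshold,
               constant = constant, row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Hypergeometric enrichment of a predicted set in a DE set
#'
#' One-sided (upper tail) hypergeometric test of the overlap k between
#' a predicted gene set (n draws) and a DE gene set (K successes) in a
#' universe of N genes: \code{P(X >= k)} with
#' X ~ Hypergeometric(N, K, n). The odds ratio comes from the 2x2
#' table, with a Haldane correction of 0.5 added to every cell when any
#' cell is zero.
#'
#' @param predicted character vector, subset of \code{universe}.
#' @param de character vector, subset of \code{universe}.
#' @param universe character vector of all eligible genes (e.g. all
#'   ncRNAs scored in the network and tested for DE).
#' @return list with \code{k}, \code{K}, \code{n}, \code{N},
#'   \code{odds_ratio} and \code{p_value}.
#' @export
enrichmentTest <- function(predicted, de, universe) {
    universe <- unique(universe)
    N <- length(universe)
    if (N == 0) stop("empty universe")
    predicted <- unique(predicted)
    de <- unique(de)
    if (!all(predicted %in% universe))
        stop("'predicted' must be a subset of 'universe'")
    if (!all(de %in% universe))
        stop("'de' must be a subset of 'universe'")
    n <- length(predicted)
    K <- length(de)
    k <- length(intersect(predicted, de))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    a <- k; b <- n - k; cc <- K - k; d <- N - K - n + k
    if (min(a, b, cc, d) == 0) {
        a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
    }
    list(k = k, K = K, n = n, N = N, odds_ratio = (a * d) / (b * cc),
         p_value = p)
}
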