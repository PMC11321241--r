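## Co-expression network construction: variance filter -> category-wise
## PCC ranking -> top-k% threshold -> seed-edge retention -> network.

## Collapse TF onto PCG for co-expression pair categorization.
.coexGroup <- function(bt) {
    out <- bt
    out[out == "TF"] <- "PCG"
    out
}

#' Drop low-variance genes
#'
#' Removes the genes in the bottom \code{dropFraction} of expression
#' variances: a gene is retained when its sample variance strictly
#' exceeds the empirical \code{dropFraction}-quantile (linear
#' interpolation, \code{\link[stats]{quantile}} type 7) of all gene
#' variances. With \code{dropFraction = 0} the matrix is returned
#' unchanged.
#'
#' @param x a \linkS4class{StemnessExperiment}.
#' @param dropFraction fraction in [0, 1); default 0.25 (bottom quarter
#'   removed).
#' @return A \linkS4class{StemnessExperiment} restricted to retained
#'   genes; the number dropped is reported via \code{message()} and in
#'   \code{metadata(x)$droppedLowVariance}.
#' @export
filterLowVariance <- function(x, dropFraction = 0.25) {
    stopifnot(is(x, "StemnessExperiment"))
    if (!is.numeric(dropFraction) || dropFraction < 0 || dropFraction >= 1)
        stop("'dropFraction' must lie in [0, 1)")
    if (dropFraction == 0) {
        message("variance filter: 0 of ", nrow(x), " genes dropped")
        return(x)
    }
    v <- apply(exprValues(x), 1, stats::var)
    thr <- stats::quantile(v, dropFraction, names = FALSE)
    keep <- v > thr
    if (!any(keep))
        stop("variance filter would drop all genes")
    message("variance filter: ", sum(!keep), " of ", length(keep),
            " genes dropped (variance <= ", format(thr), ")")
    out <- x[keep, ]
    S4Vectors::metadata(out)$droppedLowVariance <- sum(!keep)
    out
}

.rankWithinCategory <- function(df, category) {
    if (category %in% c("PCG-PCG", "PCG-lncRNA")) {
        ## highest to lowest absolute PCC
        ord <- order(-abs(df$pcc), df$gene_a, df$gene_b)
    } else {
        ## most negative to most positive signed PCC
        ord <- order(df$pcc, df$gene_a, df$gene_b)
    }
    df <- df[ord, , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    df
}

.crossPairs <- function(cm, ids_a, ids_b, category) {
    if (!length(ids_a) || !length(ids_b))
        return(NULL)
    df <- data.frame(gene_a = rep(ids_a, times = length(ids_b)),
                     gene_b = rep(ids_b, each = length(ids_a)),
                     stringsAsFactors = FALSE)
    df$category <- category
    df$pcc <- cm[cbind(df$gene_a, df$gene_b)]
    df
}

#' Compute and rank all co-expression pairs
#'
#' Enumerates every PCG-PCG, PCG-lncRNA, miRNA-PCG and miRNA-lncRNA
#' pair among the genes of \code{x} (TF counted as PCG), computes the
#' Pearson correlation coefficient across all samples, and ranks each
#' category independently: PCG-PCG and PCG-lncRNA from highest to
#' lowest absolute PCC, miRNA-PCG and miRNA-lncRNA from most negative
#' to most positive signed PCC (miRNAs repress their targets, so strong
#' negative correlations rank first). Ties are broken by lexicographic
#' (gene_a, gene_b). lncRNA-lncRNA and miRNA-miRNA pairs are not
#' generated.
#'
#' @param x a \linkS4class{StemnessExperiment} with at least 3 samples;
#'   zero-variance genes must have been removed beforehand (see
#'   \code{\link{filterLowVariance}}).
#' @return A \linkS4class{RankedPairSet}.
#' @export
computePairs <- function(x) {
    stopifnot(is(x, "StemnessExperiment"))
    m <- exprValues(x)
    if (ncol(m) < 3)
        stop("PCC requires at least 3 samples")
    v <- apply(m, 1, stats::var)
    if (any(v == 0))
        stop("zero-variance gene(s) (PCC undefined); filter first: ",
             paste(utils::head(rownames(m)[v == 0], 5), collapse = ", "))
    grp <- .coexGroup(biotype(x))
    ids <- split(names(grp), factor(grp, levels = c("PCG", "lncRNA", "miRNA")))
    cm <- stats::cor(t(m))
    blocks <- list()
    ## within-PCG pairs (unordered, gene_a < gene_b lexicographically)
    P <- sort(ids$PCG)
    if (length(P) >= 2) {
        idx <- which(upper.tri(matrix(0, length(P), length(P))), arr.ind = TRUE)
        df <- data.frame(gene_a = P[idx[, 1]], gene_b = P[idx[, 2]],
                         stringsAsFactors = FALSE)
        df$category <- "PCG-PCG"
        df$pcc <- cm[cbind(df$gene_a, df$gene_b)]
        blocks$`PCG-PCG` <- df
    }
    blocks$`PCG-lncRNA` <- .crossPairs(cm, ids$PCG, ids$lncRNA, "PCG-lncRNA")
    blocks$`miRNA-PCG` <- .crossPairs(cm, ids$miRNA, ids$PCG, "miRNA-PCG")
    blocks$`miRNA-lncRNA` <- .crossPairs(cm, ids$miRNA, ids$lncRNA,
                                         "miRNA-lncRNA")
    blocks <- Filter(Negate(is.null), blocks)
    if (!length(blocks))
        stop("no pair category has genes of both participating biotypes")
    ranked <- lapply(names(blocks), function(cc)
        .rankWithinCategory(blocks[[cc]], cc))
    pairs <- do.call(rbind, ranked)
    rownames(pairs) <- NULL
    totals <- vapply(blocks, nrow, integer(1))
    methods::new("RankedPairSet", pairs = pairs, totals = totals,
                 provenance = list(cutoff = NA_real_, seedFiltered = FALSE))
}

#' Threshold ranked pairs at a top percentage
#'
#' Per category, retains the top \code{ceiling(cutoff/100 * n)} pairs
#' by rank, where n is that category's pair count. The ceiling
#' convention guarantees a non-empty selection at small cutoffs such as
#' 0.1\%. Thresholding is per category, never global.
#'
#' @param x a \linkS4class{RankedPairSet}.
#' @param cutoff percent in (0, 100]; the study cutoffs are 0.1, 1, 5,
#'   10 and 20.
#' @return A thresholded \linkS4class{RankedPairSet} (totals keep the
#'   pre-threshold counts).
#' @export
thresholdPairs <- function(x, cutoff) {
    stopifnot(is(x, "RankedPairSet"))
    if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0 ||
        cutoff > 100)
        stop("'cutoff' must be a percent in (0, 100]")
    p <- x@pairs
    keep <- logical(nrow(p))
    for (cc in unique(p$category)) {
        sel <- p$category == cc
        k <- ceiling(cutoff / 100 * sum(sel))
        keep[sel] <- p$rank[sel] <= k
    }
    pv <- x@provenance
    pv$cutoff <- cutoff
    methods::new("RankedPairSet", pairs = p[keep, , drop = FALSE],
                 totals = x@totals, provenance = pv)
}

#' Retain pairs touching at least one seed gene
#'
#' @param x a \linkS4class{RankedPairSet}.
#' @param seeds character vector of seed gene ids.
#' @return A \linkS4class{RankedPairSet} with exactly the pairs whose
#'   gene_a or gene_b is a seed; an empty result is allowed with a
#'   warning.
#' @export
retainSeedEdges <- function(x, seeds) {
    stopifnot(is(x, "RankedPairSet"))
    p <- x@pairs
    keep <- p$gene_a %in% seeds | p$gene_b %in% seeds
    if (!any(keep))
        warning("no pair contains a seed gene; result is empty")
    pv <- x@provenance
    pv$seedFiltered <- TRUE
    methods::new("RankedPairSet", pairs = p[keep, , drop = FALSE],
                 totals = x@totals, provenance = pv)
}

#' Build an undirected network from retained pairs
#'
#' The node set is exactly the genes incident to the retained pairs.
#' The same unordered node pair arising in several categories becomes
#' one edge carrying all its category labels (comma-separated); its PCC
#' is shared by construction.
#'
#' @param x a \linkS4class{RankedPairSet} (typically thresholded and
#'   seed-filtered).
#' @param biotype optional named biotype vector; when NULL, node
#'   biotypes are inferred from the pair categories (TF reported as
#'   PCG).
#' @return A \linkS4class{StemNetwork}.
#' @export
buildNetwork <- function(x, biotype = NULL) {
    stopifnot(is(x, "RankedPairSet"))
    p <- x@pairs
    a <- pmin(p$gene_a, p$gene_b)
    b <- pmax(p$gene_a, p$gene_b)
    key <- paste(a, b, sep = "\r")
    first <- !duplicated(key)
    cats <- vapply(split(p$category, key), function(cc)
        paste(sort(unique(cc)), collapse = ","), character(1))
    edges <- data.frame(node_a = a[first], node_b = b[first],
                        category = unname(cats[key[first]]),
                        pcc = p$pcc[first], stringsAsFactors = FALSE)
    nodes <- sort(unique(c(p$gene_a, p$gene_b)))
    if (is.null(biotype)) {
        bt <- character()
        parts <- strsplit(p$category, "-", fixed = TRUE)
        bt[p$gene_a] <- vapply(parts, `[`, character(1), 1L)
        bt[p$gene_b] <- vapply(parts, `[`, character(1), 2L)
        bt <- bt[nodes]
    } else {
        missing_bt <- setdiff(nodes, names(biotype))
        if (length(missing_bt))
            stop("node(s) missing from biotype map: ",
                 paste(utils::head(missing_bt, 5), collapse = ", "))
        bt <- biotype[nodes]
    }
    pv <- x@provenance
    methods::new("StemNetwork", nodes = nodes, biotype = bt, edges = edges,
                 provenance = list(kind = "coexpression", cutoff = pv$cutoff,
                                   seedFiltered = pv$seedFiltered))
}
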