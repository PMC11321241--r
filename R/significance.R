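## Pseudo-seed permutation null for RWR scores.

#' Pseudo-seed permutation null
#'
#' Re-runs the random walk \code{nPerm} times from pseudo-seed sets of
#' the same size as the real seed set, sampled uniformly without
#' replacement from the network's nodes, and records the scores of the
#' nodes outside each draw's pseudo-seed set (a pseudo-seed holds
#' restart mass by construction, so its own score in that draw is not a
#' null observation for it; such entries are stored as NA). The
#' per-node add-one empirical p-value is
#' \code{(1 + #\{null scores >= true score\}) / (#null scores + 1)}; a
#' node is significant when its empirical p-value is at most
#' \code{level} (default 0.05) — i.e. its true score sits in the top
#' 5\% of its own null score distribution. A pooled variant compares
#' each true score against the null scores of all nodes pooled together
#' (\code{pooled = TRUE}).
#'
#' Null scores are computed from the exact fixed point: the resolvent
#' \code{alpha * (I - (1-alpha) M)^{-1}} is factorized once, and each
#' pseudo-seed draw is a column average, which equals running the
#' iteration to convergence for every draw.
#'
#' @param net a \linkS4class{StemNetwork}.
#' @param seeds real seed gene ids (those absent from the network are
#'   dropped with a warning; the pseudo-seed size matches the present
#'   ones).
#' @param alpha restart probability; default 0.5.
#' @param nPerm number of pseudo-seed draws; default 1000.
#' @param rngSeed integer seed governing all draws; required for
#'   reproducibility.
#' @param level significance level; default 0.05.
#' @param excludeSeedsFromDraws exclude the real seeds from the
#'   pseudo-seed sampling universe; default FALSE (all nodes eligible).
#' @param stratifyByBiotype preserve the real seed set's biotype
#'   composition in each pseudo-seed draw; default FALSE.
#' @param pooled use the pooled-null reading of the top-5\% rule;
#'   default FALSE (per-node null).
#' @param literal passed to the propagation operator (see
#'   \code{\link{rwrIterate}}).
#' @return A \linkS4class{PermutationNull}.
#' @export
permutationNull <- function(net, seeds, alpha = 0.5, nPerm = 1000,
                            rngSeed, level = 0.05,
                            excludeSeedsFromDraws = FALSE,
                            stratifyByBiotype = FALSE, pooled = FALSE,
                            literal = FALSE) {
    stopifnot(is(net, "StemNetwork"))
    if (missing(rngSeed) || !is.numeric(rngSeed))
        stop("'rngSeed' is required for reproducible pseudo-seed draws")
    if (nPerm < 1) stop("'nPerm' must be >= 1")
    W <- buildTransition(net)
    nodes <- W@nodes
    p0 <- makeP0(nodes, seeds)
    present <- nodes[p0 > 0]
    nSeed <- length(present)
    universe <- if (excludeSeedsFromDraws) setdiff(nodes, present) else nodes
    if (nSeed >= length(universe))
        stop("seed count (", nSeed, ") must be smaller than the ",
             "pseudo-seed sampling universe (", length(universe), " nodes)")
    M <- .propagationOperator(W, literal)
    n <- length(nodes)
    ## resolvent: p = alpha (I - (1-alpha) M)^{-1} p0 for any p0
    R <- alpha * solve(diag(n) - (1 - alpha) * M)
    dimnames(R) <- list(nodes, nodes)
    trueScores <- stats::setNames(as.numeric(R %*% p0), nodes)
    strata <- NULL
    if (stratifyByBiotype) {
        strata <- split(present, net@biotype[present])
        uniByBt <- split(universe, net@biotype[universe])
        short <- names(strata)[vapply(strata, length, integer(1)) >
                               vapply(uniByBt[names(strata)], length, integer(1))]
        if (length(short))
            stop("not enough nodes of biotype(s) ",
                 paste(short, collapse = ", "), " for stratified draws")
    }
    set.seed(as.integer(rngSeed))
    nullScores <- matrix(NA_real_, n, nPerm,
                         dimnames = list(nodes, NULL))
    for (b in seq_len(nPerm)) {
        idx <- if (is.null(strata)) {
            sample(universe, nSeed)
        } else {
            unlist(lapply(names(strata), function(bt)
                sample(uniByBt[[bt]], length(strata[[bt]]))),
                use.names = FALSE)
        }
        sc <- rowSums(R[, idx, drop = FALSE]) / nSeed
        sc[match(idx, nodes)] <- NA_real_
        nullScores[, b] <- sc
    }
    if (pooled) {
        pool <- sort(as.numeric(nullScores[!is.na(nullScores)]))
        nGE <- length(pool) - findInterval(trueScores, pool, left.open = TRUE)
        empP <- (1 + nGE) / (length(pool) + 1)
    } else {
        nNull <- rowSums(!is.na(nullScores))
        empP <- (1 + rowSums(nullScores >= trueScores, na.rm = TRUE)) /
            (nNull + 1)
    }
    empP <- stats::setNames(as.numeric(empP), nodes)
    methods::new("PermutationNull", nodes = nodes, trueScores = trueScores,
                 nullScores = nullScores, empiricalP = empP,
                 significant = empP <= level, seeds = present,
                 level = level, nPerm = as.integer(nPerm),
                 rngSeed = as.integer(rngSeed), pooled = pooled)
}

#' Call significant predictions
#'
#' Tabulates the nodes passing the permutation significance rule,
#' optionally excluding the seed nodes themselves (predictions are
#' non-seed genes) and restricting to chosen biotypes (e.g. the ncRNA
#' classes \code{c("lncRNA", "miRNA")}).
#'
#' @param result a \linkS4class{PropagationResult}.
#' @param null a \linkS4class{PermutationNull} over the same node set.
#' @param biotype named biotype vector covering the nodes (e.g.
#'   \code{biotype(net)}).
#' @param excludeSeeds drop seed nodes regardless of significance;
#'   default TRUE.
#' @param biotypeFilter optional character vector of biotypes to keep.
#' @param onlySignificant keep only significant nodes; default TRUE.
#' @return data.frame with columns gene_id, biotype, score, rank,
#'   empirical_p, significant, ordered by rank.
#' @export
callPredictions <- function(result, null, biotype, excludeSeeds = TRUE,
                            biotypeFilter = NULL, onlySignificant = TRUE) {
    nodes <- names(result@scores)
    if (!setequal(nodes, null@nodes))
        stop("propagation result and permutation null cover different node sets")
    df <- data.frame(gene_id = nodes,
                     biotype = unname(biotype[nodes]),
                     score = unname(result@scores),
                     rank = unname(result@ranks),
                     empirical_p = unname(null@empiricalP[nodes]),
                     significant = unname(null@significant[nodes]),
                     stringsAsFactors = FALSE)
    if (onlySignificant)
        df <- df[df$significant, , drop = FALSE]
    if (excludeSeeds)
        df <- df[!df$gene_id %in% null@seeds, , drop = FALSE]
    if (!is.null(biotypeFilter))
        df <- df[df$biotype %in% biotypeFilter, , drop = FALSE]
    df <- df[order(df$rank), , drop = FALSE]
    rownames(df) <- NULL
    df
}
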