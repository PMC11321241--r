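## Stage orchestration: each run* function chains the module operations
## with one structured log line per stage (to stderr via message), and
## is a pure function of (inputs, config, rngSeed).

.stageLog <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Build co-expression networks at one or more cutoffs
#'
#' Chains variance filtering, pair computation, per-cutoff
#' thresholding, optional seed-edge retention and network assembly.
#'
#' @param expr a \linkS4class{StemnessExperiment}.
#' @param seeds character vector of seed gene ids (used when
#'   \code{seedFilter = TRUE}).
#' @param cutoffs numeric vector of percents; default
#'   \code{c(0.1, 1, 5, 10, 20)}.
#' @param dropFraction variance-filter fraction; default 0.25.
#' @param seedFilter retain only pairs touching a seed; default TRUE.
#' @param outDir optional directory; networks are written as edge-list
#'   TSVs \code{coexpression_<cutoff>.tsv}.
#' @return Named list (one entry per cutoff) of lists with \code{pairs}
#'   (thresholded, possibly seed-filtered \linkS4class{RankedPairSet})
#'   and \code{network} (\linkS4class{StemNetwork}).
#' @export
runCoexpress <- function(expr, seeds = character(),
                         cutoffs = c(0.1, 1, 5, 10, 20),
                         dropFraction = 0.25, seedFilter = TRUE,
                         outDir = NULL) {
    if (!length(cutoffs))
        stop("at least one cutoff is required")
    filtered <- filterLowVariance(expr, dropFraction)
    .stageLog("filter", nrow(filtered), " of ", nrow(expr), " genes retained")
    ranked <- computePairs(filtered)
    .stageLog("pairs", nrow(pairTable(ranked)), " pairs in ",
              length(pairTotals(ranked)), " categories")
    bt <- biotype(filtered)
    out <- list()
    for (co in cutoffs) {
        keep <- thresholdPairs(ranked, co)
        if (seedFilter)
            keep <- retainSeedEdges(keep, seeds)
        net <- buildNetwork(keep, biotype = bt)
        .stageLog("network", "cutoff ", co, "%: ", length(nodeIds(net)),
                  " nodes, ", nrow(edgeTable(net)), " edges")
        if (!is.null(outDir)) {
            dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
            writeRankedPairs(keep, file.path(outDir,
                sprintf("coexpression_%s.tsv", format(co))))
        }
        out[[format(co)]] <- list(pairs = keep, network = net)
    }
    out
}

#' End-to-end prediction of stemness-associated genes
#'
#' Chains seed selection (when gene sets are supplied), co-expression
#' network construction at one cutoff, optional regulatory
#' intersection, RWR propagation from the seeds, the pseudo-seed
#' permutation null, and prediction calling.
#'
#' @param expr a \linkS4class{StemnessExperiment}.
#' @param seeds character vector of seed ids, or NULL to derive them
#'   from \code{geneSets}.
#' @param geneSets named list of gene sets for
#'   \code{\link{selectStemSeeds}} (used when \code{seeds} is NULL).
#' @param minSets,extraSeeds passed to \code{\link{selectStemSeeds}}.
#' @param interactions optional interaction data.frame; when supplied
#'   and \code{network = "regulatory"}, the co-expression pairs are
#'   intersected with it.
#' @param network \code{"coexpression"} (default) or
#'   \code{"regulatory"}.
#' @param cutoff single percent cutoff; default 5.
#' @param dropFraction variance-filter fraction; default 0.25.
#' @param seedFilterCoex apply seed-edge retention to the
#'   co-expression network; default TRUE. The regulatory intersection
#'   uses unfiltered pairs unless \code{seedFilterReg = TRUE}.
#' @param seedFilterReg default FALSE.
#' @param alpha restart probability; default 0.5.
#' @param nPerm permutations; default 1000.
#' @param level significance level; default 0.05.
#' @param rngSeed integer seed for the permutation draws.
#' @param biotypeFilter biotypes reported as predictions; default
#'   \code{c("lncRNA", "miRNA")}.
#' @param outPath optional results TSV path (see
#'   \code{\link{writeResults}}).
#' @return list with \code{seeds}, \code{network}, \code{result}
#'   (\linkS4class{PropagationResult}), \code{null}
#'   (\linkS4class{PermutationNull}) and \code{predictions}
#'   (data.frame).
#' @export
runPredict <- function(expr, seeds = NULL, geneSets = NULL, minSets = 3,
                       extraSeeds = character(), interactions = NULL,
                       network = c("coexpression", "regulatory"),
                       cutoff = 5, dropFraction = 0.25,
                       seedFilterCoex = TRUE, seedFilterReg = FALSE,
                       alpha = 0.5, nPerm = 1000, level = 0.05,
                       rngSeed = 1, biotypeFilter = c("lncRNA", "miRNA"),
                       outPath = NULL) {
    network <- match.arg(network)
    if (is.null(seeds)) {
        if (is.null(geneSets))
            stop("supply either 'seeds' or 'geneSets'")
        seeds <- selectStemSeeds(geneSets, minSets = minSets,
                                 extraSeeds = extraSeeds)
    }
    .stageLog("seeds", length(seeds), " seed genes")
    filtered <- filterLowVariance(expr, dropFraction)
    ranked <- computePairs(filtered)
    keep <- thresholdPairs(ranked, cutoff)
    if (network == "regulatory") {
        if (is.null(interactions))
            stop("network = 'regulatory' requires 'interactions'")
        if (seedFilterReg)
            keep <- retainSeedEdges(keep, seeds)
        net <- intersectRegulatory(interactions, keep,
                                   biotype = biotype(filtered))
    } else {
        if (seedFilterCoex)
            keep <- retainSeedEdges(keep, seeds)
        net <- buildNetwork(keep, biotype = biotype(filtered))
    }
    .stageLog("network", network, ": ", length(nodeIds(net)), " nodes, ",
              nrow(edgeTable(net)), " edges")
    result <- rwrScore(net, seeds, alpha = alpha)
    .stageLog("rwr", "alpha ", alpha, ", ",
              ifelse(result@iterations == 0, "direct solve",
                     paste0(result@iterations, " iterations")))
    null <- permutationNull(net, seeds, alpha = alpha, nPerm = nPerm,
                            rngSeed = rngSeed, level = level)
    preds <- callPredictions(result, null, biotype(net),
                             excludeSeeds = TRUE,
                             biotypeFilter = biotypeFilter)
    .stageLog("predict", sum(isSignificant(null)), " significant nodes, ",
              nrow(preds), " reported predictions")
    if (!is.null(outPath))
        writeResults(result, null, biotype(net), outPath)
    list(seeds = seeds, network = net, result = result, null = null,
         predictions = preds)
}

#' Validate predictions by median-split DE and enrichment
#'
#' Splits samples at the median stemness index, calls DE genes between
#' the low- and high-stemness groups, and tests whether the predicted
#' ncRNAs are enriched in the DE ncRNAs by a one-sided hypergeometric
#' test. The universe is the set of ncRNA genes tested for DE.
#'
#' @param expr a \linkS4class{StemnessExperiment}.
#' @param predicted character vector of predicted gene ids (e.g.
#'   \code{runPredict(...)$predictions$gene_id}).
#' @param index named stemness index vector; defaults to the one stored
#'   in \code{expr}.
#' @param lfcThreshold,fdrThreshold,pseudocount,test passed to
#'   \code{\link{differentialExpression}}.
#' @param biotypeFilter biotypes defining the ncRNA universe; default
#'   \code{c("lncRNA", "miRNA")}.
#' @return list with \code{groups}, \code{de} (full DE table),
#'   \code{deNcRNAs} (DE ncRNA ids) and \code{enrichment} (see
#'   \code{\link{enrichmentTest}}).
#' @export
runValidate <- function(expr, predicted, index = stemnessIndex(expr),
                        lfcThreshold = 1, fdrThreshold = 0.05,
                        pseudocount = 1, test = "wilcox",
                        biotypeFilter = c("lncRNA", "miRNA")) {
    groups <- medianSplit(expr, index)
    .stageLog("split", length(groups$low), " low / ", length(groups$high),
              " high stemness samples")
    de <- differentialExpression(expr, groups, lfcThreshold = lfcThreshold,
                                 fdrThreshold = fdrThreshold,
                                 pseudocount = pseudocount, test = test)
    bt <- biotype(expr)
    universe <- names(bt)[bt %in% biotypeFilter]
    deNc <- intersect(de$gene_id[de$is_de], universe)
    predNc <- intersect(predicted, universe)
    .stageLog("de", sum(de$is_de), " DE genes, ", length(deNc),
              " DE ncRNAs of ", length(universe), " in universe")
    enr <- enrichmentTest(predNc, deNc, universe)
    .stageLog("enrichment", "k=", enr$k, " K=", enr$K, " n=", enr$n,
              " N=", enr$N, " p=", format(enr$p_value, digits = 4))
    list(groups = groups, de = de, deNcRNAs = deNc, enrichment = enr)
}

#' Area under the ROC curve for a score vector against binary labels
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a randomly
#' chosen positive outscores a randomly chosen negative, with ties
#' counted 1/2. Used to quantify how well propagation scores separate
#' planted stemness-associated ncRNAs from background ncRNAs.
#'
#' @param scores numeric vector.
#' @param labels logical vector (TRUE = positive), same length.
#' @return AUROC in [0, 1].
#' @export
aurocScore <- function(scores, labels) {
    stopifnot(length(scores) == length(labels), is.logical(labels))
    nPos <- sum(labels)
    nNeg <- sum(!labels)
    if (nPos == 0 || nNeg == 0)
        stop("need at least one positive and one negative label")
    r <- rank(scores)
    (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}
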