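#' Accessors for stemwalk classes
#'
#' \code{biotype} returns the named per-gene biotype vector;
#' \code{stemnessIndex} the named per-sample stemness index (or NULL);
#' \code{exprValues} the expression matrix; \code{pairTable} the pair
#' data.frame of a \linkS4class{RankedPairSet}; \code{pairTotals} its
#' pre-threshold per-category counts; \code{nodeIds} and
#' \code{edgeTable} the node vector and edge data.frame of a
#' \linkS4class{StemNetwork}; \code{propScores} and \code{propRanks} the
#' score and rank vectors of a \linkS4class{PropagationResult};
#' \code{empiricalP} and \code{isSignificant} the per-node columns of a
#' \linkS4class{PermutationNull}.
#'
#' @param x an object of the documented class.
#' @return See details above; vectors are named by gene or sample id.
#' @name accessors
#' @aliases biotype stemnessIndex exprValues pairTable pairTotals nodeIds
#'   edgeTable propScores propRanks empiricalP isSignificant
NULL

#' @rdname accessors
#' @export
setGeneric("biotype", function(x) standardGeneric("biotype"))

#' @rdname accessors
#' @export
setGeneric("stemnessIndex", function(x) standardGeneric("stemnessIndex"))

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' @rdname accessors
#' @export
setGeneric("pairTotals", function(x) standardGeneric("pairTotals"))

#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setGeneric("propScores", function(x) standardGeneric("propScores"))

#' @rdname accessors
#' @export
setGeneric("propRanks", function(x) standardGeneric("propRanks"))

#' @rdname accessors
#' @export
setGeneric("empiricalP", function(x) standardGeneric("empiricalP"))

#' @rdname accessors
#' @export
setGeneric("isSignificant", function(x) standardGeneric("isSignificant"))

#' @rdname accessors
#' @export
setMethod("biotype", "StemnessExperiment", function(x)
    stats::setNames(as.character(SummarizedExperiment::rowData(x)$biotype),
                    rownames(x)))

#' @rdname accessors
#' @export
setMethod("biotype", "StemNetwork", function(x) x@biotype)

#' @rdname accessors
#' @export
setMethod("stemnessIndex", "StemnessExperiment", function(x) {
    si <- SummarizedExperiment::colData(x)$stemnessIndex
    if (is.null(si)) NULL else stats::setNames(as.numeric(si), colnames(x))
})

#' @rdname accessors
#' @export
setMethod("exprValues", "StemnessExperiment", function(x)
    SummarizedExperiment::assay(x, "expr"))

#' @rdname accessors
#' @export
setMethod("pairTable", "RankedPairSet", function(x) x@pairs)

#' @rdname accessors
#' @export
setMethod("pairTotals", "RankedPairSet", function(x) x@totals)

#' @rdname accessors
#' @export
setMethod("nodeIds", "StemNetwork", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("nodeIds", "TransitionMatrix", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("edgeTable", "StemNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("propScores", "PropagationResult", function(x) x@scores)

#' @rdname accessors
#' @export
setMethod("propRanks", "PropagationResult", function(x) x@ranks)

#' @rdname accessors
#' @export
setMethod("empiricalP", "PermutationNull", function(x) x@empiricalP)

#' @rdname accessors
#' @export
setMethod("isSignificant", "PermutationNull", function(x) x@significant)

setMethod("show", "RankedPairSet", function(object) {
    p <- object@pairs
    cat("RankedPairSet with", nrow(p), "pairs in",
        length(unique(p$category)), "categories\n")
    tot <- object@totals
    for (cc in names(tot))
        cat(sprintf("  %-13s %d kept of %d\n", cc,
                    sum(p$category == cc), tot[[cc]]))
    pv <- object@provenance
    cat(sprintf("  cutoff: %s%%  seed-filtered: %s\n",
                ifelse(is.na(pv$cutoff), "none", format(pv$cutoff)),
                pv$seedFiltered))
})

setMethod("show", "StemNetwork", function(object) {
    cat(sprintf("StemNetwork (%s): %d nodes, %d edges\n",
                object@provenance$kind, length(object@nodes),
                nrow(object@edges)))
    if (length(object@nodes)) {
        bt <- table(object@biotype)
        cat("  nodes by biotype:",
            paste(sprintf("%s=%d", names(bt), bt), collapse = ", "), "\n")
    }
})

setMethod("show", "TransitionMatrix", function(object) {
    iso <- sum(abs(rowSums(object@W)) < 1e-12)
    cat(sprintf("TransitionMatrix: %d nodes (%d isolated)\n",
                length(object@nodes), iso))
})

setMethod("show", "PropagationResult", function(object) {
    cat(sprintf("PropagationResult: %d nodes, alpha = %g, %s after %d iterations\n",
                length(object@scores), object@alpha,
                ifelse(object@converged, "converged", "NOT converged"),
                object@iterations))
    top <- names(sort(object@ranks))[seq_len(min(5, length(object@ranks)))]
    if (length(top))
        cat("  top nodes:", paste(top, collapse = ", "), "\n")
})

setMethod("show", "PermutationNull", function(object) {
    cat(sprintf("PermutationNull: %d nodes, %d permutations, level %g (%s)\n",
                length(object@nodes), object@nPerm, object@level,
                ifelse(object@pooled, "pooled", "per-node")))
    cat(sprintf("  significant nodes: %d\n", sum(object@significant)))
})
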