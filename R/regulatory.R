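## Seed selection and regulatory network assembly.

#' Select stemness seed genes from gene-set collections
#'
#' A gene is a seed when it appears in at least \code{minSets} of the
#' supplied gene sets (the stemness signature collections); curated
#' stemness-associated ncRNAs or other known genes can be appended via
#' \code{extraSeeds}.
#'
#' @param sets named list of character vectors (e.g. read with
#'   \code{\link{readGeneSets}}).
#' @param minSets minimum number of sets a gene must appear in
#'   (default 3).
#' @param extraSeeds character vector of additional seed ids, unioned
#'   with the set-derived seeds.
#' @return Sorted character vector of seed gene ids; errors when empty.
#' @export
selectStemSeeds <- function(sets, minSets = 3, extraSeeds = character()) {
    if (!is.list(sets) || (length(sets) && is.null(names(sets))))
        stop("'sets' must be a named list of gene id vectors")
    if (!is.numeric(minSets) || minSets < 1)
        stop("'minSets' must be >= 1")
    counts <- table(unlist(lapply(sets, unique), use.names = FALSE))
    seeds <- union(names(counts)[counts >= minSets], extraSeeds)
    if (!length(seeds))
        stop("no gene appears in at least ", minSets,
             " sets and no extra seeds were given")
    sort(seeds)
}

#' Intersect curated regulatory interactions with co-expression pairs
#'
#' Keeps the interaction records whose unordered endpoint pair occurs
#' among the co-expression pairs (at whatever cutoff \code{coexPairs}
#' was thresholded to), discarding direction: propagation runs on an
#' undirected network, but the regulatory category of each edge is
#' retained as annotation. Matching ignores the co-expression category
#' of the pair.
#'
#' @param interactions data.frame with columns source, target, category
#'   (one of the eight regulatory categories; see
#'   \code{\link{readInteractions}}).
#' @param coexPairs a \linkS4class{RankedPairSet}.
#' @param biotype optional named biotype vector for the node labels; if
#'   NULL, inferred from the regulatory categories.
#' @return A \linkS4class{StemNetwork} with
#'   \code{provenance$kind == "regulatory"}; empty intersections are
#'   allowed with a warning.
#' @export
intersectRegulatory <- function(interactions, coexPairs, biotype = NULL) {
    stopifnot(is(coexPairs, "RankedPairSet"))
    validateInteractions(interactions)
    p <- coexPairs@pairs
    coexKey <- paste(pmin(p$gene_a, p$gene_b), pmax(p$gene_a, p$gene_b),
                     sep = "\r")
    pccByKey <- stats::setNames(p$pcc, coexKey)
    ia <- pmin(interactions$source, interactions$target)
    ib <- pmax(interactions$source, interactions$target)
    ikey <- paste(ia, ib, sep = "\r")
    hit <- ikey %in% coexKey
    if (!any(hit)) {
        warning("regulatory interactions and co-expression pairs do not intersect")
        return(methods::new("StemNetwork",
                            provenance = list(kind = "regulatory",
                                              cutoff = coexPairs@provenance$cutoff,
                                              seedFiltered = coexPairs@provenance$seedFiltered)))
    }
    kept <- data.frame(node_a = ia[hit], node_b = ib[hit],
                       category = interactions$category[hit],
                       key = ikey[hit], stringsAsFactors = FALSE)
    ## merge records sharing an unordered pair, keeping all categories
    first <- !duplicated(kept$key)
    cats <- vapply(split(kept$category, kept$key), function(cc)
        paste(sort(unique(cc)), collapse = ","), character(1))
    edges <- data.frame(node_a = kept$node_a[first],
                        node_b = kept$node_b[first],
                        category = unname(cats[kept$key[first]]),
                        pcc = unname(pccByKey[kept$key[first]]),
                        stringsAsFactors = FALSE)
    nodes <- sort(unique(c(edges$node_a, edges$node_b)))
    if (is.null(biotype)) {
        parts <- strsplit(interactions$category[hit], "-", fixed = TRUE)
        bt <- character()
        bt[interactions$source[hit]] <- vapply(parts, `[`, character(1), 1L)
        bt[interactions$target[hit]] <- vapply(parts, `[`, character(1), 2L)
        bt <- bt[nodes]
    } else {
        bt <- biotype[nodes]
    }
    methods::new("StemNetwork", nodes = nodes, biotype = bt, edges = edges,
                 provenance = list(kind = "regulatory",
                                   cutoff = coexPairs@provenance$cutoff,
                                   seedFiltered = coexPairs@provenance$seedFiltered))
}
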