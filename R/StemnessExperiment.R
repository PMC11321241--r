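#' Construct a StemnessExperiment
#'
#' Bundles a genes x samples expression matrix with per-gene biotypes
#' (and optionally a per-sample stemness index) into a
#' \linkS4class{StemnessExperiment}. Values are used as supplied;
#' whether to log-transform beforehand is the caller's decision.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). All values finite.
#' @param biotype named character vector mapping every gene id to one of
#'   \code{"PCG"}, \code{"TF"}, \code{"lncRNA"}, \code{"miRNA"}.
#' @param stemnessIndex optional named numeric vector in [0, 1]; names
#'   must be a subset of the sample ids. Samples without an index get NA.
#' @return A \linkS4class{StemnessExperiment}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
#' se <- StemnessExperiment(m, c(g1 = "PCG", g2 = "lncRNA", g3 = "miRNA"))
#' biotype(se)
#' @export
StemnessExperiment <- function(values, biotype, stemnessIndex = NULL) {
    if (!is.matrix(values) || !is.numeric(values))
        stop("'values' must be a numeric matrix")
    g <- rownames(values)
    s <- colnames(values)
    if (is.null(g) || is.null(s))
        stop("'values' must have row (gene) and column (sample) names")
    if (anyDuplicated(g))
        stop("duplicate gene id(s): ",
             paste(unique(g[duplicated(g)]), collapse = ", "))
    if (anyDuplicated(s))
        stop("duplicate sample id(s): ",
             paste(unique(s[duplicated(s)]), collapse = ", "))
    missing_bt <- setdiff(g, names(biotype))
    if (length(missing_bt))
        stop("gene(s) missing from biotype map: ",
             paste(missing_bt, collapse = ", "))
    bad <- setdiff(unique(biotype[g]), .BIOTYPES)
    if (length(bad))
        stop("unknown biotype(s): ", paste(bad, collapse = ", "),
             "; valid biotypes are ", paste(.BIOTYPES, collapse = ", "))
    cd <- S4Vectors::DataFrame(row.names = s)
    if (!is.null(stemnessIndex)) {
        extra <- setdiff(names(stemnessIndex), s)
        if (length(extra))
            stop("stemness index sample(s) absent from expression matrix: ",
                 paste(extra, collapse = ", "))
        si <- rep(NA_real_, length(s))
        names(si) <- s
        si[names(stemnessIndex)] <- stemnessIndex
        cd$stemnessIndex <- unname(si)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(expr = values),
        rowData = S4Vectors::DataFrame(biotype = unname(biotype[g]),
                                       row.names = g),
        colData = cd)
    methods::new("StemnessExperiment", se)
}

#' Subset a StemnessExperiment to a gene set
#'
#' @param x a \linkS4class{StemnessExperiment}.
#' @param genes character vector of gene ids to keep (order preserved
#'   from \code{x}).
#' @return A \linkS4class{StemnessExperiment} restricted to \code{genes}.
#' @keywords internal
.subsetGenes <- function(x, genes) {
    x[rownames(x) %in% genes, ]
}
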