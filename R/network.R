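#' Construct a StemNetwork from an edge table
#'
#' Low-level constructor for users (and tests) bringing their own
#' networks: undirected edges are given as a two-column data.frame (or
#' one with columns node_a, node_b and optionally category and pcc);
#' duplicate unordered pairs and self-loops are rejected.
#'
#' @param edges data.frame; first two columns are the endpoints.
#' @param nodes optional character vector of node ids; defaults to the
#'   endpoints' union, but may add isolated nodes.
#' @param biotype optional named biotype vector; defaults to "PCG" for
#'   every node.
#' @param kind provenance label; default "custom".
#' @return A \linkS4class{StemNetwork}.
#' @examples
#' net <- stemNetwork(data.frame(a = c("g1", "g2"), b = c("g2", "g3")))
#' nodeIds(net)
#' @export
stemNetwork <- function(edges, nodes = NULL, biotype = NULL,
                        kind = "custom") {
    a <- as.character(edges[[1]])
    b <- as.character(edges[[2]])
    if (any(a == b))
        stop("self-loops are not allowed")
    e <- data.frame(node_a = pmin(a, b), node_b = pmax(a, b),
                    category = if ("category" %in% names(edges))
                        as.character(edges$category) else
                        rep("custom", length(a)),
                    pcc = if ("pcc" %in% names(edges))
                        as.numeric(edges$pcc) else
                        rep(NA_real_, length(a)),
                    stringsAsFactors = FALSE)
    if (anyDuplicated(paste(e$node_a, e$node_b)))
        stop("duplicate edges (as unordered pairs)")
    if (is.null(nodes))
        nodes <- sort(unique(c(e$node_a, e$node_b)))
    else
        nodes <- sort(unique(as.character(nodes)))
    if (is.null(biotype))
        biotype <- stats::setNames(rep("PCG", length(nodes)), nodes)
    methods::new("StemNetwork", nodes = nodes, biotype = biotype[nodes],
                 edges = e,
                 provenance = list(kind = kind, cutoff = NA_real_,
                                   seedFiltered = FALSE))
}
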