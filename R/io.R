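## File dialect shared by all readers/writers: tab-separated, UTF-8,
## '#'-prefixed comment lines ignored. Scores are serialized at 10
## significant digits so write/read round trips are stable.

.readTSV <- function(path, ...) {
    if (!file.exists(path))
        stop("file not found: ", path)
    utils::read.delim(path, comment.char = "#", check.names = FALSE,
                      stringsAsFactors = FALSE, ...)
}

.writeTSV <- function(df, path, comments = character()) {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    if (length(comments))
        writeLines(paste0("#", comments), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

.fmtScore <- function(x) sprintf("%.10g", x)

#' Read an expression matrix with biotype annotations
#'
#' Reads a genes x samples TSV (header row of sample ids, first column
#' gene ids) together with a two-column biotype map (gene_id, biotype)
#' and returns a \linkS4class{StemnessExperiment}. Row and column order
#' are preserved from the file. Lines starting with '#' are ignored.
#'
#' @param path expression TSV.
#' @param biotypePath biotype map TSV covering every gene in \code{path}.
#' @return A \linkS4class{StemnessExperiment}.
#' @export
readExpression <- function(path, biotypePath) {
    df <- .readTSV(path)
    if (ncol(df) < 2)
        stop("expression file needs a gene id column plus sample columns: ", path)
    genes <- as.character(df[[1]])
    if (anyDuplicated(genes))
        stop("duplicate gene id(s) in ", path, ": ",
             paste(unique(genes[duplicated(genes)]), collapse = ", "))
    samples <- colnames(df)[-1]
    m <- matrix(NA_real_, nrow(df), length(samples),
                dimnames = list(genes, samples))
    for (j in seq_along(samples)) {
        col <- df[[j + 1]]
        num <- suppressWarnings(as.numeric(col))
        bad <- which(is.na(num) & !is.na(col) & col != "NA")
        if (length(bad))
            stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s' in %s",
                         col[bad[1]], genes[bad[1]], samples[j], path))
        m[, j] <- num
    }
    bt <- readBiotypes(biotypePath)
    StemnessExperiment(m, bt)
}

#' Read a biotype map
#'
#' Two-column TSV (gene_id, biotype) with biotypes in
#' \{PCG, TF, lncRNA, miRNA\}.
#'
#' @param path biotype TSV.
#' @return Named character vector gene_id -> biotype.
#' @export
readBiotypes <- function(path) {
    df <- .readTSV(path)
    if (ncol(df) < 2)
        stop("biotype map needs two columns (gene_id, biotype): ", path)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
        stop("duplicate gene id(s) in biotype map: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    bt <- as.character(df[[2]])
    bad <- setdiff(unique(bt), .BIOTYPES)
    if (length(bad))
        stop("unknown biotype(s) in ", path, ": ",
             paste(bad, collapse = ", "))
    stats::setNames(bt, ids)
}

#' Write an expression matrix (and optionally its biotype map)
#'
#' @param x a \linkS4class{StemnessExperiment}.
#' @param path output expression TSV.
#' @param biotypePath optional output path for the biotype map.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(x, path, biotypePath = NULL) {
    m <- exprValues(x)
    df <- data.frame(gene_id = rownames(m),
                     apply(m, 2, .fmtScore),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("gene_id", colnames(m))
    .writeTSV(df, path)
    if (!is.null(biotypePath)) {
        bt <- biotype(x)
        .writeTSV(data.frame(gene_id = names(bt), biotype = unname(bt),
                             stringsAsFactors = FALSE), biotypePath)
    }
    invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each non-empty, non-comment line is: set name, description, then
#' tab-separated member gene ids.
#'
#' @param path GMT file.
#' @return Named list of character vectors (member ids, de-duplicated).
#' @export
readGeneSets <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    sets <- list()
    for (ln in lines) {
        f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
        nm <- f[1]
        members <- unique(f[-(1:2)])
        members <- members[nzchar(members)]
        if (length(f) < 3 || !length(members))
            stop("gene set '", nm, "' has no members in ", path)
        if (nm %in% names(sets))
            stop("duplicate gene set name: ", nm)
        sets[[nm]] <- members
    }
    sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output GMT file.
#' @param descriptions optional named character vector of set
#'   descriptions; defaults to the set name.
#' @return \code{path}, invisibly.
#' @export
writeGeneSets <- function(sets, path, descriptions = NULL) {
    lines <- vapply(names(sets), function(nm) {
        desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
            descriptions[[nm]] else nm
        paste(c(nm, desc, sets[[nm]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}

#' Read a curated regulatory interaction list
#'
#' TSV with columns source, target, category; category must be one of
#' the eight regulatory interaction types (TF-miRNA, TF-lncRNA, TF-PCG,
#' miRNA-lncRNA, miRNA-TF, miRNA-PCG, lncRNA-TF, lncRNA-PCG).
#' Self-interactions are rejected. When a biotype map is supplied, the
#' category of each record must agree with the biotypes of its source
#' and target.
#'
#' @param path interaction TSV.
#' @param biotype optional named character vector gene_id -> biotype for
#'   consistency checking.
#' @return data.frame with columns \code{source}, \code{target},
#'   \code{category}.
#' @export
readInteractions <- function(path, biotype = NULL) {
    df <- .readTSV(path)
    need <- c("source", "target", "category")
    if (!all(need %in% colnames(df)))
        stop("interaction file must have columns source, target, category: ", path)
    df <- df[, need]
    df[] <- lapply(df, as.character)
    validateInteractions(df, biotype = biotype)
    df
}

#' Validate an interaction table
#'
#' @param df data.frame with columns source, target, category.
#' @param biotype optional named biotype vector for category checks.
#' @return \code{df}, invisibly; errors on violations.
#' @export
validateInteractions <- function(df, biotype = NULL) {
    bad <- setdiff(unique(df$category), .REG_CATEGORIES)
    if (length(bad))
        stop("unknown interaction category(ies): ",
             paste(bad, collapse = ", "), "; valid categories are ",
             paste(.REG_CATEGORIES, collapse = ", "))
    self <- df$source == df$target
    if (any(self))
        stop("self-interaction(s) not allowed: ",
             paste(unique(df$source[self]), collapse = ", "))
    if (!is.null(biotype)) {
        parts <- strsplit(df$category, "-", fixed = TRUE)
        sb <- vapply(parts, `[`, character(1), 1L)
        tb <- vapply(parts, `[`, character(1), 2L)
        known <- df$source %in% names(biotype) & df$target %in% names(biotype)
        mism <- known & (biotype[df$source] != sb | biotype[df$target] != tb)
        if (any(mism))
            stop("interaction category inconsistent with biotypes for: ",
                 paste(utils::head(paste0(df$source[mism], "-",
                                          df$target[mism]), 5),
                       collapse = ", "))
    }
    invisible(df)
}

#' Write an interaction list
#'
#' @param df data.frame with columns source, target, category.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
writeInteractions <- function(df, path) {
    .writeTSV(df[, c("source", "target", "category")], path)
}

#' Read a per-sample stemness index vector
#'
#' Two-column TSV (sample_id, index) with index values in [0, 1]. The
#' index (e.g. the mRNAsi) is computed externally and supplied as input.
#'
#' @param path index TSV.
#' @return Named numeric vector sample_id -> index.
#' @export
readStemnessIndex <- function(path) {
    df <- .readTSV(path)
    if (ncol(df) < 2)
        stop("stemness index file needs two columns (sample_id, index): ", path)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
        stop("duplicate sample id(s) in ", path)
    v <- as.numeric(df[[2]])
    if (any(!is.finite(v)) || any(v < 0 | v > 1))
        stop("stemness index values must be finite and in [0, 1]: ", path)
    stats::setNames(v, ids)
}

#' Write / read a ranked pair set as an edge-list TSV
#'
#' Columns node_a, node_b, category, pcc, rank; '#'-prefixed header
#' comments record the per-category pre-threshold totals and the
#' provenance (cutoff percent, seed-filter flag), so the round trip is
#' lossless.
#'
#' @param x a \linkS4class{RankedPairSet}.
#' @param path output TSV.
#' @return \code{path} (writer) or a \linkS4class{RankedPairSet} (reader).
#' @export
writeRankedPairs <- function(x, path) {
    pv <- x@provenance
    comments <- c(sprintf("provenance\tcutoff=%s\tseedFiltered=%s",
                          ifelse(is.na(pv$cutoff), "NA", .fmtScore(pv$cutoff)),
                          pv$seedFiltered),
                  sprintf("total\t%s\t%d", names(x@totals), x@totals))
    p <- x@pairs
    out <- data.frame(node_a = p$gene_a, node_b = p$gene_b,
                      category = p$category, pcc = .fmtScore(p$pcc),
                      rank = p$rank, stringsAsFactors = FALSE)
    .writeTSV(out, path, comments = comments)
}

#' @rdname writeRankedPairs
#' @export
readRankedPairs <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    lines <- readLines(path, encoding = "UTF-8")
    cm <- lines[startsWith(lines, "#")]
    totals <- integer()
    provenance <- list(cutoff = NA_real_, seedFiltered = FALSE)
    for (ln in cm) {
        f <- strsplit(sub("^#", "", ln), "\t", fixed = TRUE)[[1]]
        if (f[1] == "total") {
            totals[f[2]] <- as.integer(f[3])
        } else if (f[1] == "provenance") {
            kv <- strsplit(f[-1], "=", fixed = TRUE)
            for (p in kv) {
                if (p[1] == "cutoff")
                    provenance$cutoff <- suppressWarnings(as.numeric(p[2]))
                if (p[1] == "seedFiltered")
                    provenance$seedFiltered <- as.logical(p[2])
            }
        }
    }
    df <- .readTSV(path)
    pairs <- data.frame(gene_a = as.character(df$node_a),
                        gene_b = as.character(df$node_b),
                        category = as.character(df$category),
                        pcc = as.numeric(df$pcc),
                        rank = as.integer(df$rank),
                        stringsAsFactors = FALSE)
    if (!length(totals)) {
        tt <- table(pairs$category)
        totals <- stats::setNames(as.integer(tt), names(tt))
    }
    methods::new("RankedPairSet", pairs = pairs, totals = totals,
                 provenance = provenance)
}

#' Write / read a network as an edge-list TSV
#'
#' Node biotypes (including isolated nodes) are preserved in
#' '#node'-prefixed comment lines, edges as rows node_a, node_b,
#' category, pcc.
#'
#' @param x a \linkS4class{StemNetwork}.
#' @param path output TSV.
#' @return \code{path} (writer) or a \linkS4class{StemNetwork} (reader).
#' @export
writeNetwork <- function(x, path) {
    pv <- x@provenance
    comments <- c(sprintf("provenance\tkind=%s\tcutoff=%s\tseedFiltered=%s",
                          pv$kind,
                          ifelse(is.na(pv$cutoff), "NA", .fmtScore(pv$cutoff)),
                          pv$seedFiltered),
                  sprintf("node\t%s\t%s", x@nodes, x@biotype[x@nodes]))
    e <- x@edges
    out <- data.frame(node_a = e$node_a, node_b = e$node_b,
                      category = e$category, pcc = .fmtScore(e$pcc),
                      stringsAsFactors = FALSE)
    .writeTSV(out, path, comments = comments)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    lines <- readLines(path, encoding = "UTF-8")
    cm <- lines[startsWith(lines, "#")]
    nodes <- character(); bt <- character()
    provenance <- list(kind = "coexpression", cutoff = NA_real_,
                       seedFiltered = FALSE)
    for (ln in cm) {
        f <- strsplit(sub("^#", "", ln), "\t", fixed = TRUE)[[1]]
        if (f[1] == "node") {
            nodes <- c(nodes, f[2]); bt[f[2]] <- f[3]
        } else if (f[1] == "provenance") {
            kv <- strsplit(f[-1], "=", fixed = TRUE)
            for (p in kv) {
                if (p[1] == "kind") provenance$kind <- p[2]
                if (p[1] == "cutoff")
                    provenance$cutoff <- suppressWarnings(as.numeric(p[2]))
                if (p[1] == "seedFiltered")
                    provenance$seedFiltered <- as.logical(p[2])
            }
        }
    }
    df <- .readTSV(path)
    edges <- data.frame(node_a = as.character(df$node_a),
                        node_b = as.character(df$node_b),
                        category = as.character(df$category),
                        pcc = as.numeric(df$pcc),
                        stringsAsFactors = FALSE)
    methods::new("StemNetwork", nodes = nodes, biotype = bt, edges = edges,
                 provenance = provenance)
}

#' Write propagation + significance results
#'
#' TSV with columns gene_id, biotype, score, rank, empirical_p,
#' significant, sorted by rank ascending (ties already resolved by
#' lexicographic gene id at ranking time). The propagation result and
#' the permutation null must cover the same node set.
#'
#' @param result a \linkS4class{PropagationResult}.
#' @param null a \linkS4class{PermutationNull} over the same nodes.
#' @param biotype named biotype vector covering the nodes.
#' @param path output TSV.
#' @return \code{path} (writer) or a data.frame (reader).
#' @export
writeResults <- function(result, null, biotype, path) {
    nodes <- names(result@scores)
    if (!setequal(nodes, null@nodes))
        stop("propagation result and permutation null cover different node sets")
    missing_bt <- setdiff(nodes, names(biotype))
    if (length(missing_bt))
        stop("node(s) missing from biotype map: ",
             paste(utils::head(missing_bt, 5), collapse = ", "))
    ord <- order(result@ranks)
    out <- data.frame(gene_id = nodes[ord],
                      biotype = unname(biotype[nodes[ord]]),
                      score = .fmtScore(result@scores[ord]),
                      rank = result@ranks[ord],
                      empirical_p = .fmtScore(null@empiricalP[nodes[ord]]),
                      significant = null@significant[nodes[ord]],
                      stringsAsFactors = FALSE)
    .writeTSV(out, path)
}

#' @rdname writeResults
#' @export
readResults <- function(path) {
    df <- .readTSV(path)
    df$score <- as.numeric(df$score)
    df$empirical_p <- as.numeric(df$empirical_p)
    df$significant <- as.logical(df$significant)
    df
}
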