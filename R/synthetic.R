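## Single-factor synthetic data generator.
##
## A latent per-sample stemness factor z ~ N(0, 1) drives the planted
## genes: seed PCGs and true lncRNAs load positively (rho * z), true
## miRNAs negatively (-rho * z), each plus sqrt(1 - rho^2) * N(0,
## noiseSd^2) noise, so at noiseSd = 1 two positively planted genes
## correlate at rho^2 in expectation and a planted miRNA correlates
## with a seed at -rho^2. Background genes are independent noise. The
## observable stemness index is logistic(z), landing in [0, 1] like the
## mRNAsi.
##
## Values are placed on a log2-like expression scale as
## baseline + amplitude * (signal + noise): an affine map that leaves
## every correlation (hence the whole network/propagation path)
## untouched while keeping group means well away from the pseudocount
## singularity of the log2 fold-change, so that planted genes swing
## roughly 4-fold across the stemness range and median-split DE can
## recover them.

#' Generate a synthetic stemness dataset
#'
#' Produces an expression matrix with a latent stemness factor, planted
#' stemness-associated genes (seed PCGs, true lncRNAs and miRNAs),
#' independent background genes, a per-sample stemness index, truth
#' labels and the seed set — everything needed to exercise the full
#' prediction pipeline without external data.
#'
#' Background genes are split 50/30/20 between PCG, lncRNA and miRNA
#' biotypes so that every co-expression pair category is populated.
#'
#' @param nSamples number of samples; default 200.
#' @param nSeedPCGs planted seed protein-coding genes; default 30.
#' @param nTrueLnc planted stemness-associated lncRNAs; default 10.
#' @param nTrueMir planted stemness-associated miRNAs; default 10.
#' @param nNoiseGenes independent background genes; default 400.
#' @param rho correlation strength of planted genes with the latent
#'   factor, in (0, 1); default 0.9. \code{rho = 0} is allowed as a
#'   no-signal null configuration.
#' @param noiseSd noise scale; planted genes get i.i.d. noise of this
#'   standard deviation, background genes draw a per-gene scale from
#'   U(0.5, 1.5) x \code{noiseSd} to emulate the heterogeneous
#'   variability of real expression data (so the variance filter
#'   removes low-variability background genes, not planted signal).
#'   Default 1.
#' @param baseline additive constant of the expression scale; default 2.
#' @param amplitude multiplicative constant of the expression scale;
#'   default 2 (planted genes swing about 4-fold across the stemness
#'   range on the log2-like scale).
#' @param rngSeed integer seed; the dataset is deterministic given it.
#' @return list with \code{expr} (a \linkS4class{StemnessExperiment}
#'   carrying the stemness index in \code{colData}), \code{index}
#'   (named numeric), \code{truth} (named logical: planted
#'   stemness-associated genes), and \code{seeds} (the planted seed PCG
#'   ids).
#' @export
generateSynthetic <- function(nSamples = 200, nSeedPCGs = 30,
                              nTrueLnc = 10, nTrueMir = 10,
                              nNoiseGenes = 400, rho = 0.9, noiseSd = 1,
                              baseline = 2, amplitude = 2, rngSeed = 1) {
    if (any(c(nSamples, nSeedPCGs, nTrueLnc, nTrueMir, nNoiseGenes) < 1))
        stop("all counts must be positive")
    if (rho < 0 || rho >= 1)
        stop("'rho' must lie in [0, 1)")
    set.seed(as.integer(rngSeed))
    samples <- sprintf("sample%03d", seq_len(nSamples))
    z <- stats::rnorm(nSamples)
    planted <- function(n, prefix, sign) {
        ids <- sprintf("%s%03d", prefix, seq_len(n))
        raw <- matrix(sign * rho * z, n, nSamples, byrow = TRUE) +
            sqrt(1 - rho^2) * matrix(stats::rnorm(n * nSamples, sd = noiseSd),
                                     n, nSamples)
        m <- baseline + amplitude * raw
        rownames(m) <- ids
        m
    }
    seedM <- planted(nSeedPCGs, "seedPCG", +1)
    lncM <- planted(nTrueLnc, "stemLnc", +1)
    mirM <- planted(nTrueMir, "stemMir", -1)
    nL <- round(0.3 * nNoiseGenes)
    nM <- round(0.2 * nNoiseGenes)
    nP <- nNoiseGenes - nL - nM
    noiseIds <- c(if (nP) sprintf("bgPCG%03d", seq_len(nP)),
                  if (nL) sprintf("bgLnc%03d", seq_len(nL)),
                  if (nM) sprintf("bgMir%03d", seq_len(nM)))
    ## heterogeneous per-gene variability for the background, as in real
    ## expression data; the low-variability stratum is what the bottom-25%
    ## variance filter removes, while planted genes (unit variance on the
    ## raw scale) sit above the cutoff
    sdg <- noiseSd * stats::runif(nNoiseGenes, 0.5, 1.5)
    noiseM <- baseline + amplitude *
        matrix(stats::rnorm(nNoiseGenes * nSamples, sd = rep(sdg, nSamples)),
               nNoiseGenes, nSamples, dimnames = list(noiseIds, NULL))
    m <- rbind(seedM, lncM, mirM, noiseM)
    colnames(m) <- samples
    bt <- c(stats::setNames(rep("PCG", nSeedPCGs), rownames(seedM)),
            stats::setNames(rep("lncRNA", nTrueLnc), rownames(lncM)),
            stats::setNames(rep("miRNA", nTrueMir), rownames(mirM)),
            stats::setNames(rep(c("PCG", "lncRNA", "miRNA"),
                                c(nP, nL, nM)), noiseIds))
    index <- stats::setNames(stats::plogis(z), samples)
    truth <- stats::setNames(rownames(m) %in% c(rownames(seedM),
                                                rownames(lncM),
                                                rownames(mirM)),
                             rownames(m))
    list(expr = StemnessExperiment(m, bt, stemnessIndex = index),
         index = index, truth = truth, seeds = rownames(seedM))
}

#' Generate a synthetic regulatory interaction list
#'
#' Connects a fraction of the planted ncRNAs to randomly chosen seed
#' PCGs (categories miRNA-PCG / lncRNA-PCG) and adds decoy records
#' among background genes. Record counts follow the floor convention:
#' \code{floor(fracTrue * #planted ncRNAs)} true records and
#' \code{floor(fracDecoy * #background genes)} decoys.
#'
#' @param dataset output of \code{\link{generateSynthetic}}.
#' @param fracTrue fraction of planted ncRNAs wired to a seed; default 1.
#' @param fracDecoy decoy records as a fraction of the background gene
#'   count; default 0.1.
#' @param rngSeed integer seed.
#' @return data.frame with columns source, target, category (the
#'   interaction-list schema of \code{\link{readInteractions}}).
#' @export
generateInteractions <- function(dataset, fracTrue = 1, fracDecoy = 0.1,
                                 rngSeed = 1) {
    if (fracTrue < 0 || fracTrue > 1 || fracDecoy < 0 || fracDecoy > 1)
        stop("fractions must lie in [0, 1]")
    set.seed(as.integer(rngSeed))
    bt <- biotype(dataset$expr)
    truth <- dataset$truth
    seeds <- dataset$seeds
    trueNc <- names(truth)[truth & bt[names(truth)] %in% c("lncRNA", "miRNA")]
    recs <- list()
    nTrue <- floor(fracTrue * length(trueNc))
    if (nTrue > 0) {
        chosen <- if (nTrue == length(trueNc)) trueNc else
            sample(trueNc, nTrue)
        recs$true <- data.frame(
            source = chosen,
            target = sample(seeds, nTrue, replace = TRUE),
            category = ifelse(bt[chosen] == "miRNA", "miRNA-PCG",
                              "lncRNA-PCG"),
            stringsAsFactors = FALSE)
    }
    bg <- names(bt)[!truth[names(bt)]]
    bgNc <- bg[bt[bg] %in% c("lncRNA", "miRNA")]
    bgPcg <- bg[bt[bg] == "PCG"]
    nDecoy <- floor(fracDecoy * length(bg))
    if (nDecoy > 0) {
        if (!length(bgNc) || !length(bgPcg))
            stop("decoys need background ncRNAs and background PCGs")
        src <- sample(bgNc, nDecoy, replace = TRUE)
        recs$decoy <- data.frame(
            source = src,
            target = sample(bgPcg, nDecoy, replace = TRUE),
            category = ifelse(bt[src] == "miRNA", "miRNA-PCG",
                              "lncRNA-PCG"),
            stringsAsFactors = FALSE)
    }
    out <- if (length(recs)) do.call(rbind, recs) else
        data.frame(source = character(), target = character(),
                   category = character(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    validateInteractions(out)
    out
}
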