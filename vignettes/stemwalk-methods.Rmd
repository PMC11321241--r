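---
title: "stemwalk: network propagation for cancer stemness-associated ncRNAs"
author: "stemwalk authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stemwalk: network propagation for cancer stemness-associated ncRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemwalk)
```

## The problem

Cancer stem cells drive tumour initiation, metastasis, recurrence and
therapy resistance, and non-coding RNAs — lncRNAs and miRNAs — are
increasingly recognised as regulators of the stemness programme. Direct
experimental evidence exists for only a small number of ncRNAs, so a
practical route to candidate discovery is guilt by association on
molecular networks: start from protein-coding genes (PCGs) with known
stemness roles, build a cancer-specific network that captures
co-expression and regulatory structure, and let a random walk with
restart (RWR) rank every other node by its proximity to those seeds.

`stemwalk` implements that pipeline end to end: co-expression and
regulatory network construction from an expression matrix and curated
interaction lists, RWR prioritisation from stemness seed genes, a
pseudo-seed permutation null for significance, and validation by
median-split differential expression (DE) against a per-sample stemness
index plus hypergeometric enrichment.

## Co-expression network construction

Starting from a genes x samples matrix with per-gene biotypes
(`StemnessExperiment`), the stages are:

1. **Variance filter** (`filterLowVariance`). Genes in the bottom
   quarter of expression variances are removed (default
   `dropFraction = 0.25`). The cutoff is the empirical
   linear-interpolation quantile of the gene variances, and a gene
   survives only when its variance *strictly* exceeds it; with all
   variances distinct this retains exactly 75% of genes.
   `dropFraction = 0` is the identity.
2. **Pair computation and ranking** (`computePairs`). All PCG-PCG,
   PCG-lncRNA, miRNA-PCG and miRNA-lncRNA pairs are scored by the
   Pearson correlation across all samples. Transcription factors are a
   separate biotype for regulatory bookkeeping but count as PCGs here.
   Ranking is per category: PCG-PCG and PCG-lncRNA descend by |PCC|
   (strong co-expression of either sign is informative), while
   miRNA-PCG and miRNA-lncRNA ascend by signed PCC — miRNAs repress
   their targets, so the most negative correlations are the most
   credible regulatory signals and rank first. lncRNA-lncRNA and
   miRNA-miRNA pairs are never generated. Ties break lexicographically
   so output is platform-independent.
3. **Thresholding** (`thresholdPairs`). Per category, the top
   `ceiling(cutoff/100 * n)` pairs are kept. The supported working
   points are 0.1, 1, 5, 10 and 20 percent; the ceiling convention
   guarantees a non-empty selection at 0.1% even for small categories.
   Because selection is by rank prefix, edge sets are nested across
   increasing cutoffs and network size grows monotonically — a useful
   sanity check that the tests enforce exactly.
4. **Seed-edge retention** (`retainSeedEdges`) keeps the pairs touching
   at least one seed gene, and `buildNetwork` assembles the undirected
   network, merging an unordered pair that appears in several
   categories into one edge with all labels.

Expression values are used exactly as supplied. Whether to
log-transform first is deliberately left to the caller: the PCC is not
invariant to that choice and conventions differ between data sources.

## Regulatory network

Curated interactions come in eight categories (TF-miRNA, TF-lncRNA,
TF-PCG, miRNA-lncRNA, miRNA-TF, miRNA-PCG, lncRNA-TF, lncRNA-PCG).
`intersectRegulatory` keeps the records whose unordered endpoint pair
is also a co-expression pair at the chosen cutoff, ignoring the
co-expression category of the match. Direction is discarded —
propagation runs on an undirected graph, matching the transition-matrix
formula below, which is written on a plain adjacency matrix — but the
regulatory category is kept as edge annotation. By default the
intersection uses unfiltered (not seed-filtered) co-expression pairs;
both choices are available because either is defensible and the
difference is a strict subset relation.

## Random walk with restart

`buildTransition` row-normalizes the binary adjacency matrix:
$w(i,j) = A(i,j) / \sum_j A(i,j)$ when the row sum is nonzero and 0
otherwise (isolated nodes keep an all-zero row). The walk iterates

$$p_{t+1} = (1-\alpha)\,M\,p_t + \alpha\,p_0$$

with restart probability $\alpha = 0.5$ and $p_0$ placing $1/n$ on each
of the $n$ seed nodes present in the network. Seeds absent from the
network are dropped with a warning and $n$ recomputed, keeping $p_0$
normalized.

**Operator orientation.** Applied literally with $M = W$ (the
row-normalized matrix), the update does not conserve probability mass
on graphs with unequal degrees, because row-normalization makes
*incoming* weights sum to one at the receiving node. `stemwalk`
therefore applies $M = W^\top$, the standard RWR convention under which
mass flows *out* of each node in proportion to its normalized weights
and $\sum_t p_t = 1$ holds at every iterate on graphs without isolated
nodes. On symmetric-degree (regular) graphs the two coincide; the
literal form stays available via `literal = TRUE` and its mass drift is
measurable (the tests do).

**Numerics.** Convergence is declared when the L1 change between
iterates drops below `tol = 1e-10` (cap `maxIter = 1000`); the
iteration contracts geometrically with ratio at most $1-\alpha$, so at
$\alpha = 0.5$ about 35 iterations suffice. Non-convergence returns a
flagged result with a warning rather than an error. `rwrSolve` computes
the exact fixed point $(I-(1-\alpha)M)\,p = \alpha\,p_0$ by dense
linear solve and serves both as the production path on small networks
(`rwrScore` uses it up to 2000 nodes) and as the independent oracle the
iterative path is tested against. Edges are unweighted by default; a
|PCC|-weighted mode exists but is off, since the ranking evidence feeds
the network through thresholding, not through edge weights.

## Pseudo-seed permutation significance

To separate genuine proximity from degree effects, `permutationNull`
redraws pseudo-seed sets of the same size as the real seed set
(uniformly without replacement from the network's nodes, 1000 draws by
default) and re-runs the walk for each. The scores recorded under a
draw are those of the nodes *outside* that draw's pseudo-seed set: a
pseudo-seed holds restart mass by construction, so its own score in
that draw says nothing about how the network treats it as a
non-seed. Masking those entries matters — without it, a node's null
distribution is contaminated by the $\alpha/n$ restart spikes from the
draws containing it, and in dense networks no node can ever reach the
top 5% of its own null.

Each node's empirical p-value uses the add-one estimator
$(1 + \#\{\text{null} \ge \text{true}\}) / (\#\text{null} + 1)$, which
can never be zero from finite permutations, and a node is significant
when $p \le 0.05$: its true score lies in the top 5% of its null score
distribution. Two alternative readings are implemented behind flags:
pooling all nodes' null scores (`pooled = TRUE`), and biotype-stratified
pseudo-seed draws (`stratifyByBiotype = TRUE`) for when the real seed
set mixes PCGs and ncRNAs. Per-node nulls are the default because
propagation scores are strongly degree-dependent, and a single integer
`rngSeed` governs all draws, so runs are exactly reproducible.

Internally the fixed point is computed through a single factorization
of the resolvent $\alpha (I-(1-\alpha)M)^{-1}$, after which every
pseudo-seed draw is a column average — algebraically identical to
iterating each draw to convergence, and orders of magnitude faster.

`callPredictions` reports significant non-seed nodes, restricted by
default to the ncRNA biotypes.

## Validation: median-split DE and enrichment

Given a per-sample stemness index in [0, 1] (for example the mRNAsi,
computed externally), `medianSplit` forms low- and high-stemness groups
at the median; samples equal to the median go high, a deterministic and
documented tie rule, and both sides must keep at least two samples.
`differentialExpression` scores each gene with
$\log_2\!\big((\bar{x}_{high}+c)/(\bar{x}_{low}+c)\big)$ (pseudocount
$c = 1$ expression unit) and a two-sided Wilcoxon rank-sum p-value —
chosen over the t-test as the default because expression within groups
need not be normal; the t-test is available by flag. FDR is
Benjamini-Hochberg over all tested genes, and a gene is DE when
$|\log_2 FC| > 1$ (strict) and FDR $< 0.05$ (strict). Genes constant
across all samples get p = 1 and a flag.

`enrichmentTest` asks whether the predicted ncRNAs overlap the DE
ncRNAs more than chance: a one-sided hypergeometric upper tail
$P(X \ge k)$ on the 2x2 table over the ncRNA universe, with a Haldane
0.5 correction on the odds ratio when a cell is zero. The tests verify
it against exhaustive enumeration of all draws on small universes.

## The synthetic data generator

`generateSynthetic` builds the statistical structure the method
assumes, so every stage is testable without any download. A latent
per-sample factor $z \sim N(0,1)$ plays the role of the stemness
programme: planted seed PCGs and true lncRNAs load on it with strength
$\rho$ (default 0.9), true miRNAs with $-\rho$ (the repressor
convention that motivates the signed ranking rule), each plus
$\sqrt{1-\rho^2}$-scaled Gaussian noise, so two positively planted
genes correlate at $\rho^2$ and a planted miRNA at $-\rho^2$ with a
seed. The observable stemness index is $\mathrm{logistic}(z) \in
[0,1]$. Defaults are 200 samples, 30 seed PCGs, 10 + 10 true ncRNAs
and 400 background genes — the operating point used throughout the
package's end-to-end checks, sized so correlations are estimated with
Fisher-z standard errors well below the planted effect.

Two presentation choices make the fixture behave like expression data
rather than raw factor scores. First, values are mapped affinely to
`baseline + amplitude * raw` (defaults 2 and 2) — correlations, and
hence the entire network/propagation path, are unchanged, but group
means stay clear of the pseudocount singularity and planted genes swing
about 4-fold across the stemness range, so the DE rule can see them.
Second, background genes draw a per-gene noise scale from
$U(0.5, 1.5) \times$ `noiseSd`: real transcriptomes have strongly
heterogeneous per-gene variability, and the bottom-25% variance filter
is meant to remove that low-variability stratum. With homogeneous
background variance the filter would delete a uniform random quarter
of all genes — planted signal included — which is both unrealistic and
self-defeating. `rho = 0` gives a calibrated no-signal dataset on which
the significant fraction should match the nominal level.

What the generator does **not** emulate: library-size and compositional
artifacts, counts and mean-variance coupling, heavy-tailed expression,
batch structure, or correlated background modules. Passing the
end-to-end checks therefore demonstrates correctness of the machinery
under the single-factor model, not performance on real tumour data.

`generateInteractions` wires a chosen fraction of planted ncRNAs to
random seed PCGs and adds decoy records among background genes (floor
convention on both counts), providing a matched fixture for the
regulatory intersection.

## Problem sizes and reproducibility

The automated checks run at deliberately desk-sized operating points:
50 random graphs up to 200 nodes for the iterate-vs-solve oracle;
connected graphs up to ~100 nodes for conservation and contraction; a
100-gene matrix for exact threshold counts and cutoff nesting; 20
replicates of a 50-node Erdős–Rényi graph with 200 permutations for
null calibration; 5 replicates of the full 460-gene synthetic dataset
(100–200 permutations) for planted-signal recovery; and 10 replicates
of a 210-gene two-group simulation for DE operating characteristics.
`scripts/acceptance.R` recomputes all of these from scratch from a
single `--seed`. Every stochastic step in the package funnels through
an explicit integer seed, so identical inputs give byte-identical
outputs.

## Known limitations

* Pair enumeration is dense (all category pairs are materialised);
  fine into the low thousands of genes, not engineered for whole
  transcriptomes on small machines.
* The transition matrix and resolvent are dense; `rwrScore` switches to
  power iteration beyond 2000 nodes, but `permutationNull` factorizes
  the resolvent and is intended for networks in the
  hundreds-to-few-thousands of nodes.
* The stemness index is an input, never computed; expression
  transformation (log or otherwise) is the caller's responsibility.
* The permutation null permutes seeds, not edges: degree structure is
  held fixed, which is the intended comparison, but it cannot detect
  miscalibration caused by network construction itself.
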