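---
title: "Methods: multi-tissue differential expression, signature correlation and network drug-target proximity"
author: "proxscreen developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-tissue differential expression, signature correlation and network drug-target proximity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope and model

`proxscreen` implements a hypothesis-generating pipeline for multi-tissue
treated-vs-control transcriptome experiments of the kind used to screen a
systemically distributed drug (e.g., metformin given to healthy animals)
for unexpected beneficial or deleterious effects. Three statistical ideas
carry the analysis:

1. **Per-tissue differential expression** on gene-level counts with very
   few replicates (the design the package targets is 10 tissues x 2 groups
   x 3 biological replicates), using a relaxed raw-p threshold because the
   output feeds downstream screens rather than a confirmatory claim.
2. **Signature correlation**: the treatment's per-gene log2 fold-change
   array is compared by Spearman correlation (SCC), on shared genes only,
   against a curated compendium of reference signatures (disease models,
   drug treatments, lifestyle interventions). Positive SCC with a disease
   signature suggests the treatment mimics the disease; negative SCC
   suggests reversal.
3. **Network drug-target proximity**: for a directed human signalling
   network, `dist(D,T) = mean_i min_j sp(D_i, T_j)` — the mean hop
   distance from each differentially expressed gene to its nearest target
   of a drug. Significance comes from redrawing equally sized false target
   sets from the network (permutation null, empirical FDR), and a
   drug-tissue link is retained only when supported by at least one DEG
   set (up, down, both) in *each* of two independent target-annotation
   sources.

# Differential expression test

The paper-scale analysis this package generalizes used edgeR with default
settings. `proxscreen` deliberately implements an equivalent, fully
self-contained negative-binomial exact test rather than wrapping edgeR;
numerical identity with edgeR is *not* a contract, same-model-family
behaviour is.

* **Model**: counts `y ~ NB(mu, phi)` with `Var = mu + phi mu^2`
  (mean-dispersion parameterization, the RNA-seq convention).
* **Normalization**: median-of-ratios size factors (computed over genes
  expressed in all samples, library-size fallback), rescaled to geometric
  mean 1 so normalized counts stay on the count scale.
* **Dispersion**: the common dispersion is estimated by Cox-Reid adjusted
  profile likelihood; plain profile likelihood and plain method-of-moments
  both underestimate `phi` noticeably at 3 replicates per group (we
  measured ~8% downward bias for MOM at `phi = 0.1`), which makes the
  test anti-conservative. Per-gene method-of-moments estimates (left
  unclamped, so their noise is symmetric) are shrunk toward the common
  value with 20 prior degrees of freedom against 4 residual df — strong
  shrinkage is appropriate at n = 3 + 3.
* **Test**: conditioning on the per-gene total, the treated-group sum is
  compared to its conditional NB distribution; group sums over unequal
  library sizes are moment-matched to NB (`mean q S_g`, dispersion
  `phi * sum(s_i^2)/S_g^2`). The two-sided p aggregates all outcomes at
  most as probable as the observed one ("double tail"). By default the
  **mid-p** variant is used (half of the observed outcome's own point mass
  is excluded): without it the discreteness of low-count genes makes the
  null rejection fraction at `alpha = 0.05` fall below its binomial 99%
  band. `midp = FALSE` restores the classical tail.
* **Fold changes**: `log2((qA + 0.5)/(qB + 0.5))` on normalized group
  means; the 0.5 pseudocount keeps all-zero groups finite. All-zero genes
  are reported with `p = 1`, `log2fc = 0`.
* **Multiplicity**: the default direction call uses raw `p < 0.05`
  exactly as in the relaxed hypothesis-generation design; `fdr = TRUE`
  switches the call to BH-adjusted p.

Enumeration of the conditional distribution is windowed at +/-16
conditional SDs around the mode (always containing the observed value), so
the test stays exact to machine precision while remaining O(window) per
gene.

# Signature machinery

Fold-change deduction is platform-aware: paired two-colour arrays average
per-pair log2 signal ratios; universal-reference two-colour arrays are
treated exactly as one-colour arrays; one-colour and RNA-seq designs use
`mean(log2 case) - mean(log2 control)`, log2-transforming on the way in if
needed (RNA-seq with a +1 pseudocount).

Correlations use average ranks for ties. The p-value policy is
deterministic: full permutation enumeration below 10 shared genes, the
large-sample t approximation otherwise. References sharing fewer than 3
genes are reported untestable and excluded from the Bonferroni count.
Because empirical compendia report both family-wise and FDR-adjusted
values for the same analyses, both `p_bonferroni` and `p_bh` columns are
always emitted; the `significant` flag follows the chosen `correction`.

Redundancy pruning links same-topic pairs with SCC > 0.5 and keeps one
representative per connected component — the signature with the most
genes, ties broken by lexicographic id. Cross-topic pairs are never
pruned, and topics match by exact string equality (no published topic
taxonomy exists to do better). Pruning is idempotent by construction.

# Proximity statistic and its null

Distances default to **undirected** traversal (the formula is silent
about direction and undirected proximity is robust to annotation
directionality); `mode = "directed"` follows edges. Genes absent from the
network are dropped and counted. A DEG unreachable from every target
contributes a penalty of diameter + 1 — identically in observed and null
computations, so comparisons stay fair; `unreachable = "drop"` excludes
such genes instead.

The null redraws `|T|` nodes uniformly from the whole network (the
source description says only "randomly selected from the network"); a
degree-matched null (out-degree decile bins) is available for sensitivity
analysis. The empirical p uses the add-one estimator
`(1 + #[null <= observed])/(n_perm + 1)`, which is never zero. "FDR
assessed accordingly" is implemented as BH across drugs within each
(tissue, DEG-kind, source) stratum — the stratification is stated here
explicitly so counts are reproducible.

A note on calibration: the empirical p lives on the grid
`{1, ..., n_perm+1}/(n_perm+1)`. Uniformity on that support is verified in
the acceptance tests via the randomized probability integral transform
(`p - U/(n_perm+1)`), which is exactly U(0,1) iff p is uniform on the
grid. On very small or hub-dominated networks the hop-distance statistic
has point masses, ties between observed and null values accumulate, and
the estimator becomes (validly) conservative rather than uniform — a
property of discrete distances, not an implementation artifact.

# Synthetic world

The generator's defaults state the experimental design the pipeline
targets: 10 tissues (aorta, brown adipose, brain, eye, heart, liver,
kidney, skeletal muscle, stomach, testis), treated vs control, 3
biological replicates, 5000 genes.

* Counts are NB with log-normal gene baselines (log-mean `log 60`, log-sd
  1.2), per-tissue gene effects (`tissue_effect_sd = 1` on log2; this is
  what makes samples cluster by tissue, as real multi-tissue data do),
  dispersion 0.1, and totals drawn log-uniform in `2e5..5e5` and applied
  multiplicatively so normalization is actually exercised. No published
  distributional form exists for the motivating data; NB is this module's
  assumption.
* Planted DEGs (fraction `deg_fraction` per tissue, half up half down)
  shift the treated-group mean by `2^(+/-lfc_magnitude)` in their tissue
  only.
* The network is preferential attachment; edges are directed
  low-to-high node index with 10% reciprocated. Planted-proximal drugs
  draw targets from nodes within the configured hop distance of that
  tissue's planted DEGs, chosen coverage-greedily (each pick minimizes
  the resulting mean min-distance, ties broken at random): planting is
  about *controlled distance*, and arbitrary draws inside the hop ball
  dissolve the signal into the mean. Other drugs draw targets uniformly.
  Both annotation sources are drawn independently per drug.
* Planted reference signatures rank-blend the treatment signature's
  normal scores with Gaussian noise at the Pearson level `2 sin(pi s/6)`
  that induces Spearman `s`; the achieved SCC is verified before emission
  and redrawn (deterministically under the seed) if off by more than
  0.04. Targets of exactly +/-1 are emitted as exact monotone transforms.
  Unplanted references are independent permutations of the treatment
  values.
* One global seed drives independent per-component streams via a string
  hash (`sub_seed`), so adding reference signatures never changes the
  count matrix. All outputs are bit-identical under a fixed
  (config, seed).

What a green synthetic test does *not* establish: agreement with edgeR on
real data, robustness to batch effects, outlier samples, isoform-level
effects, or annotation errors in real networks and target databases —
none of which the generator emulates.

# Degenerate inputs and numerical choices

* `alpha = 0` produces zero DEGs and empty-but-valid downstream outputs.
* Constant expression matrices are a flagged PCA/clustering error.
* Zero-depth samples and missing gene lengths are FPKM errors (listing
  offenders), not warnings.
* A read failing both QC rules is tallied once, under the N-fraction rule,
  so report arithmetic is deterministic. The low-quality rule reads
  "quality no larger than 20" as Phred <= 20.
* Hypergeometric/Fisher machinery is one routine (`phyper` upper tail)
  shared by gene-set and drug-feature tests; tests verify it against
  literal subset enumeration and an independent implementation.
* Tissue modules cut the average-linkage dendrogram of `1 - cosine` at 3
  clusters and label them by mean signed DEG balance (most-up cluster
  `Mod_up`, most-down `Mod_down`, rest `Mod_inbetween`); the 3-module
  structure is descriptive in the motivating analysis, so the cut rule is
  this package's own deterministic choice.
* Pipeline configuration files are JSON (argument names mirror
  `pipeline_config()`); YAML is not supported because no YAML parser is
  part of the supported dependency set.

# Known limitations

* The exact test moment-matches group sums under unequal size factors;
  with extreme library-size ratios (>5x within a group) the approximation
  degrades. The motivating designs are within 2.5x.
* The proximity screen's permutation loop is O(drugs x kinds x sources x
  n_perm); at 1000 permutations and dozens of drugs it is minutes, not
  seconds, on one CPU.
* `prune_redundant` computes all within-topic pairwise SCCs; compendia
  beyond ~2000 signatures per topic would need blocking.
* No batch correction, no isoform quantification, no live access to any
  annotation service: gene sets, drug targets, orthologs and networks all
  arrive as files.
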