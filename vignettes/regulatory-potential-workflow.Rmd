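---
title: "Gene activity modeling and multi-omic integration with scregpot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene activity modeling and multi-omic integration with scregpot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scregpot)
library(Matrix)
```

## The problem

Single-cell ATAC-seq measures chromatin accessibility at peaks, not gene
expression. To cluster ATAC cells by cell type, annotate them with marker
genes, or integrate them with scRNA-seq, accessibility must first be turned
into a per-gene, per-cell quantity — a *gene activity* score. scregpot
implements an exponential-decay regulatory-potential (RP) model of gene
activity and the workflow around it: barcode QC, LSI/PCA embeddings, graph
clustering, Wilcoxon marker detection, signature-based annotation,
transcriptional-regulator inference, and anchor-based label transfer between
modalities, together with the evaluation statistics commonly used to
benchmark these steps (NMI, RAGI, median F1, prediction scores).

## The regulatory-potential model

The model assumes each accessible peak contributes to a gene's activity
independently and additively, with influence decaying exponentially in the
distance between the peak center and the gene's transcription start site
(TSS). For peak $i$ and gene $j$ at distance $d_{ij}$:

$$W_{ij} = 2^{-d_{ij}/d_0},$$

where $d_0$ is the **half-decay distance**: a peak one $d_0$ from the TSS
counts half as much as a peak on the TSS. Given the binary peak-by-cell
matrix $B$ (any positive count means "open" — accessibility in a diploid
cell is on/off), the gene-by-cell activity matrix is a single sparse
product:

$$R = W^{\top} B.$$

Defaults: $d_0 = 10$ kb, appropriate for enhancer-driven regulation (a
promoter-oriented preset of 1 kb is available via `rp_config(d0 = 1000)`),
and a hard distance cutoff of 150 kb beyond which $W_{ij}$ is set to
exactly 0. At the default $d_0$ every discarded weight is below
$2^{-15} \approx 3.05\times 10^{-5} < 5\times10^{-4}$, so truncation
changes nothing of practical consequence while keeping $W$ sparse.

### The enhanced model

Two refinements, on by default (`rp_config(model = "enhanced")`), improve
the correspondence between activity and expression:

1. **Exonic peaks score as if on the TSS.** Active transcription leaves
   accessible chromatin on exons (RNA Pol II passage), so a peak
   overlapping one of gene $j$'s exons is first given weight 1 and then
   normalized by the gene's total merged exon length:
   $W_{ij} = s/L_j$, with $L_j$ in bp. The unit of the normalization is
   not fixed by the formula itself, so the scale $s$ is exposed as
   `exon_length_scale` (default 1000, i.e. per-kilobase, which keeps
   exon contributions on the same order as proximal decay weights; set
   `exon_length_scale = 1` for the raw reciprocal in bp).
2. **Neighbouring genes' promoters and exons are masked.** A peak lying in
   the promoter window (TSS $\pm$ 2 kb by default) or exons of *another*
   gene mostly reflects that other gene's activity, so its weight for
   gene $j$ is set to 0. A gene's own promoter is never masked, and the
   own-exon rule takes precedence: a peak in an exon shared by two
   overlapping genes scores for each gene whose exon it overlaps.
   "Another gene" means any other gene whose promoter window or exon
   overlaps the peak, with no extra distance condition — the simplest
   reading of the rule.

Peak-to-gene distance is measured from the **peak center** to the single
annotated TSS (gene start, strand-aware). Alternative isoform TSSs are out
of scope; whether a peak "overlaps an exon" is decided by any-base overlap
of the full peak interval, not its center.

## Quality control

Per-barcode filters follow the usual single-cell conventions, with the
comparison directions chosen deliberately:

| check | RNA default | ATAC default | direction |
|---|---|---|---|
| reads / UMIs | 1000 | 1000 | strict `>` |
| detected genes | 500 | — | `>=` |
| promoter-read fraction | — | 0.10 | `>=` |
| mitochondrial fraction | 0.05 | 0.10 | `<=` |
| spike-in fraction | 0.05 | — | `<=` |

The ATAC filter uses the fraction of reads in **promoter windows** rather
than the fraction of reads in peaks (FRiP): peak calls on aggregated data
are dominated by the major populations, so a FRiP filter can silently
remove rare cell types. No FRiP filter is implemented. Fragment overlap
with a promoter window is any-base overlap, weighted by the fragment's
duplicate count.

## Embedding, clustering, differential analysis

*Normalization.* Expression counts are scaled per cell to a library size of
10,000 and log-transformed (`normalize_log`). Binary peak matrices are
divided by the number of peaks per cell (`normalize_peak_depth`), so each
cell's column sums to 1.

*Feature selection.* `select_variable_genes` ranks genes by
variance-stabilized standardized variance: a loess trend of log10 variance
on log10 mean predicts each gene's expected spread, values are z-scored
against it, clipped at $\sqrt{n_\mathrm{cells}}$, and the variance of the
clipped z-scores is the ranking statistic. The default returns the top
2000 genes.

*LSI.* The ATAC embedding is TF-IDF (term frequency = entry / cell total;
IDF = $\ln(1 + n_\mathrm{cells}/\mathrm{occurrence})$) followed by
truncated SVD to 50 dimensions, cells placed at right singular vectors
scaled by singular values. The first LSI component of binary ATAC data
tracks per-cell sequencing depth rather than identity — on our fixtures it
correlates with depth at $r \approx 0.5$ and carries no cell-type signal —
so it is dropped from the returned coordinates by default
(`lsi_embed(..., drop_first = TRUE)`), as is standard practice for LSI
embeddings of scATAC data. For RNA, `pca_embed` standardizes genes and
keeps the top 15 components.

*Clustering.* `cluster_cells` builds a k-nearest-neighbor graph
(default 20 neighbors; the neighbor count is not dictated by the method
and is configurable), refines edge weights by the Jaccard similarity of
neighborhoods, prunes edges below 1/15, and runs Louvain modularity
optimization at resolution 0.6. Community detection is randomized, so the
seed is a required configuration value (default 2020).

*Markers.* One-vs-rest two-sided Wilcoxon rank-sum tests. When the number
of distinct group assignments is small enough to enumerate (up to 50,000
combinations), the exact permutation distribution is used — ties and all;
larger problems use the normal approximation with tie correction and no
continuity correction, the convention of the fast rank-sum marker
frameworks. The log fold change is $\ln((m_{in}+1)/(m_{out}+1))$ on
de-logged normalized means. Reported markers must pass logFC $>$ 0.25,
presence fraction $\geq$ 0.25 and $p < 10^{-5}$ for genes
(0.1 / 0.01 / $10^{-5}$ for peaks); the cutoffs act on raw p-values, so no
multiple-testing correction is layered on top. For differential *peaks*
the depth-normalized matrix is first rescaled by the median per-cell peak
count: without that rescaling the entries are of order $1/n_\mathrm{peaks}$
and the logFC threshold could never fire, so the threshold is applied on
the scale of a typical cell.

## Cell-type annotation

For each cluster, `cluster_logfc` computes the unfiltered log fold change
of every gene (both signs kept). A cell-type signature scores

$$\mathrm{score}(t) = \frac{\sum_{g \in \mathrm{markers}(t) \cap
\mathrm{data}} \mathrm{logFC}(g)}{\log_2 \max(2, |\mathrm{markers}(t)
\cap \mathrm{data}|)},$$

and the cluster takes the best-scoring type; if no signature scores
strictly above 0 the cluster is called `"others"` (it may be a population
the signature set does not describe). The $\max(2,\cdot)$ guard exists
because a singleton signature would otherwise divide by $\log_2 1 = 0$;
only markers present in the data are summed. Ties break lexicographically.
For ATAC clusters the same procedure runs on the log-normalized gene
activity matrix — regulatory potential standing in for expression.

## Driver-regulator inference

For each cluster, its differential peaks are tested for overlap enrichment
against reference regulator binding-site sets (e.g. ChIP-seq peak sets)
over the peak universe: a one-sided Fisher exact test (enrichment tail)
on the 2x2 table of universe peaks, an odds ratio with Haldane +0.5
smoothing on every cell (so zero cells cannot blow it up), and the
composite score

$$S = -\log_{10}(p) \times \log_2(\mathrm{OR}),$$

negative under depletion. The exact p-value is computed on the raw
(unsmoothed) table — Fisher's test is undefined on non-integer counts —
while the smoothing applies to the odds ratio. When several reference sets
describe the same regulator, only the best-scoring one is kept.

Regulators with near-identical motifs cannot be distinguished by motif
evidence, so enrichment scores are shared within *motif families*:
`pwm_similarity` scores two position weight matrices by the
information-content-weighted mean Pearson correlation of aligned columns,
maximized over all alignment offsets with at least 5 aligned columns and
over the reverse complement; `cluster_motifs` then applies average-linkage
hierarchical clustering on $1 - \mathrm{similarity}$ cut at similarity
0.7, and `propagate_family_scores` assigns each family's maximum score to
all members. The exact offset/weighting scheme of published motif
clustering tools is not reproduced verbatim; the kernel here is
deterministic, documented, and validated against an exhaustive brute-force
search in the test suite.

Regulators are then filtered on evidence of being expressed — mean
expression equal to 0, or mean regulatory potential below 0.5, drops the
candidate — and re-ranked by mean expression (RNA context) or mean RP
(ATAC context). When both modalities yield a ranking, they combine by the
rank product $\sqrt{r_\mathrm{RNA} \times r_\mathrm{ATAC}}$ (a regulator
missing from one list takes that list's worst rank plus one; ties break by
name), and reports keep the top 100 regulators per cluster.

## Label transfer between modalities

`cca_embed` standardizes the shared gene rows (by default the RNA top-2000
variable genes) of the expression matrix and the log-normalized activity
matrix, decomposes the cells-by-cells cross-product by truncated SVD, and
L2-normalizes each cell's coordinates — a canonical-correlation-style
co-embedding that treats the two modalities as two batches measuring the
same genes. Anchors are mutual nearest neighbors across modalities
(`find_anchors`, 5 neighbors each way), weighted by how early the pair
appears in each other's neighbor lists. `transfer_labels` gives every ATAC
cell a Gaussian-kernel-weighted vote over its 10 nearest anchors
(bandwidth = mean distance to those anchors, votes also weighted by anchor
weight), normalized to a probability vector; the maximum is the
**prediction score**, and scores above 0.5 mark high-quality transfers.
Degenerate rule: if an ATAC cell coincides with an anchor whose two cells
also coincide (identical datasets), only such exact anchors vote, making
self-transfer exact. This deliberately simplifies the full anchor-scoring
machinery of the established integration frameworks (shared-neighbor
filtering, quantile weight trimming): the package's contribution is the RP
input to integration, not the transfer algorithm, and the transfer output
schema accepts externally computed results for comparison.

## Evaluation statistics

- `nmi`: mutual information normalized by the arithmetic mean of the two
  entropies (natural logs); `min`, `max` and `sqrt` normalizations are
  options. Two trivial (single-cluster) partitions are defined as NMI 1.
- `gini_index`: $\sum_{i,j}|x_i - x_j| / (2 n \sum x)$; an all-zero
  vector returns 0.
- `ragi`: mean Gini of per-cluster mean activity over marker genes minus
  the same over housekeeping genes; antisymmetric in its two gene sets.
- `median_f1`: per-true-class F1 ($2PR/(P+R)$, 0 when $P+R=0$), median
  over classes.
- `expression_activity_correlation`: per cell type, Spearman correlation
  between mean expression (RNA cells) and mean activity (ATAC cells).

## The synthetic-data generator

`simulate_genome` / `simulate_cells` / `simulate_fragments` generate
coupled RNA/ATAC toy datasets with full ground truth, so every stage of
the workflow is testable without external data. The design, chosen once
as the package's standard study conditions:

- One synthetic chromosome; 10 kb gene bodies every 400 kb (the first at
  200 kb, so every gene has its full 150 kb upstream space), alternating
  strand, three exons each. Per gene: one promoter peak centered on the
  TSS, one exonic peak, and 1-5 distal peaks 20-140 kb upstream;
  background peaks sit more than 150 kb from every TSS.
- Four cell types, 100 cells per type per modality, 10 marker genes per
  type. Gene-linked peaks open with probability
  $p_\mathrm{base} \times u_g$, where $p_\mathrm{base} = 0.15$ and
  $u_g \sim U(0.3, 1)$ is a per-gene baseline — real genes differ in
  overall activity, and without this spread cross-gene rank statistics
  would be pure noise. Promoter peaks are twice as accessible as distal
  ones (TSS enrichment is the hallmark of ATAC data). In a marker gene's
  own cell type its peaks open with the full
  $\min(0.95, 4 \times p_\mathrm{base})$ (doubled again at promoters):
  an active gene's regulatory elements open strongly regardless of basal
  level. Per-cell depth factors are $U(0.8, 1.2)$.
- RNA means per type are proportional to the regulatory potential of the
  type's expected accessibility profile (simple decay model), drawn as
  negative binomial counts with dispersion 0.2 at ~5000 counts per cell.
- Fragment files emit 1-3 fragments per open peak with duplicate counts
  scaled to roughly 2500 reads per good barcode, plus planted bad
  barcodes: low count, low promoter fraction (background-only
  fragments), and high mitochondrial content.

What the generator does **not** emulate: doublets, batch effects,
sequence-level signal, chromatin co-accessibility structure, continuous
differentiation trajectories, and realistic gene/peak counts (hundreds of
genes, not tens of thousands). Passing tests therefore demonstrate the
internal consistency and statistical behavior of the implementation under
its own assumptions — not performance on real tissue atlases.

## Numerical choices and degenerate inputs

- All-zero cells: metrics report zero fractions; normalizations map them
  to zero columns rather than NaN.
- `truncated_svd` uses dense LAPACK SVD for small matrices and an
  implicitly restarted Lanczos solver (irlba) when genuinely truncated.
- Sparse matrices stay sparse through binarization, normalization, TF-IDF
  and the RP product.
- Pattern/symmetric/diagonal sparse classes from MatrixMarket files are
  coerced to general numeric CSC on read, so round trips are faithful.
- Annotation and rank-product ties break lexicographically; Louvain runs
  under an explicit seed.
- Test-suite problem sizes (the package's choices for its own fixtures):
  100 genes / 600 peaks / 400+400 cells for the standard coupled dataset,
  10 seeds for annotation and regulator recovery, 5 seeds for transfer.

## Known limitations

- The RP model ignores co-accessibility and long-range interactions
  beyond the decay kernel; gene-boundary models are deliberately not
  implemented.
- Regulator inference consumes user-supplied reference peak sets; the
  published epigenetic-landscape systems it stands beside are separate
  tools, and their outputs can be slotted in via the enrichment-table
  schema instead.
- The label-transfer algorithm is a documented simplification (MNN
  anchors + Gaussian vote), adequate for comparing gene-activity inputs,
  not a re-implementation of the full anchor framework.
- One TSS per gene; isoform-aware scoring is out of scope.
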