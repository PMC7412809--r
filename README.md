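# scregpot

Regulatory-potential modeling of gene activity from single-cell ATAC-seq,
and the workflow around it: quality control, clustering, cell-type
annotation, driver-regulator inference, and label transfer between
scRNA-seq and scATAC-seq.

## Who this is for

Single-cell ATAC-seq yields a peaks-by-cells accessibility matrix, but
most downstream biology — annotating cell types with marker genes,
comparing against scRNA-seq, nominating driver transcription factors — is
phrased in terms of *genes*. This package is for analysts who need a
principled peak-to-gene summary and a compact, scriptable, fully testable
pipeline around it.

## The model

The regulatory-potential (RP) model assumes each accessible peak acts on a
gene independently and additively, with influence decaying exponentially
in the distance from the peak center to the gene's transcription start
site (TSS):

    W_ij = 2^(−d_ij / d0),      R = Wᵀ B

`B` is the binary peaks-by-cells matrix, `W` the peaks-by-genes weight
matrix, and `R` the resulting genes-by-cells gene-activity matrix. `d0` is
the half-decay distance (default 10 kb, suited to enhancer-driven
regulation; use 1 kb for promoter-driven analyses). Weights for peaks more
than 150 kb from the TSS are set to exactly 0 — the largest discarded
weight at the default `d0` is `2^-15 ≈ 3.05e-5`.

The default **enhanced** model adds two rules: a peak overlapping one of
the gene's own exons is scored as if it sat on the TSS and normalized by
the gene's merged exon length (accessibility on exons accompanies active
transcription), and a peak inside another gene's promoter or exons is
masked (it mostly reflects that other gene). See the methods vignette
(`vignettes/regulatory-potential-workflow.Rmd`) for the full specification
of every stage.

## Worked example

Everything below runs on synthetic data generated by the package itself —
no downloads. The generator plants four cell types whose marker-gene peaks
are preferentially accessible, with RNA counts coupled to the accessibility
profile through the RP model.

```r
library(scregpot)

cfg     <- sim_config(seed = 1)
genome  <- simulate_genome(cfg)            # genes, peaks, ground truth
cells   <- simulate_cells(cfg, genome)     # coupled RNA counts + binary ATAC

W        <- build_weight_matrix(genome$peaks, genome$genes, rp_config())
activity <- regulatory_potential(W, cells$atac_binary)
dim(activity)
#> [1] 100 400          # genes x ATAC cells

emb      <- lsi_embed(cells$atac_binary, k = 15)
clusters <- cluster_cells(emb)             # kNN graph + Louvain, res 0.6
table(clusters)
#>   1   2   3   4
#> 100 100 100 100
nmi(clusters, cells$atac_labels)
#> [1] 1
```

The four Louvain clusters reproduce the planted cell types exactly
(normalized mutual information 1). Annotation on the gene-activity matrix
assigns each cluster its planted identity with a clearly positive
signature score:

```r
annotate_clusters(normalize_log(activity), clusters, cells$signatures)
#>   cluster cell_type    score
#> 1       1     type1 4.871224
#> 2       2     type2 5.178017
#> 3       3     type3 5.260754
#> 4       4     type4 5.416337
```

The score is the summed marker-gene log fold change divided by log2 of the
marker count; anything below 0 would be labeled `"others"`. Finally,
computed gene activity tracks measured expression within each cell type:

```r
expression_activity_correlation(normalize_log(cells$rna_counts),
                                normalize_log(activity),
                                cells$rna_labels, cells$atac_labels)
#> type1 type2 type3 type4
#> 0.856 0.872 0.882 0.889
```

Spearman correlations of 0.85-0.89 per type mean the RP scores are a
usable stand-in for expression — which is what makes cross-modality label
transfer (`cca_embed`, `find_anchors`, `transfer_labels`) work.

A thin command-line front end over the same functions lives at
`inst/cli/scregpot.R`:

```sh
Rscript inst/cli/scregpot.R simulate --seed 1 --out fixture/
Rscript inst/cli/scregpot.R run --config config.yaml --out results/
```

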