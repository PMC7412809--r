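#' Normalized mutual information between two partitions
#'
#' Mutual information (natural logs) normalized, by default, by the
#' arithmetic mean of the two entropies: 1 for identical partitions (up to
#' label permutation), near 0 for independent ones.
#'
#' @param a,b Label vectors of equal length.
#' @param normalization One of `"mean"`, `"min"`, `"max"`, `"sqrt"`.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(a, b, normalization = c("mean", "min", "max", "sqrt")) {
  normalization <- match.arg(normalization)
  if (length(a) != length(b)) stop("label vectors differ in length")
  joint <- table(a, b) / length(a)
  pa <- rowSums(joint)
  pb <- colSums(joint)
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  ha <- ent(pa)
  hb <- ent(pb)
  outer_p <- outer(pa, pb)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer_p[nz]))
  denom <- switch(normalization,
                  mean = (ha + hb) / 2,
                  min = min(ha, hb),
                  max = max(ha, hb),
                  sqrt = sqrt(ha * hb))
  if (denom == 0) return(1)  # both partitions trivial, hence identical
  max(0, min(1, mi / denom))
}

#' Gini index of a nonnegative vector
#'
#' Standard discrete Gini coefficient
#' `sum_i sum_j |x_i - x_j| / (2 n sum(x))`; 0 for a constant vector,
#' `1 - 1/n` for a one-hot vector of length `n`, 0 for an all-zero vector.
#'
#' @param values Nonnegative numeric vector.
#' @return Gini index in `[0, 1)`.
#' @export
gini_index <- function(values) {
  if (any(values < 0)) stop("values must be nonnegative")
  n <- length(values)
  s <- sum(values)
  if (s == 0 || n < 2) return(0)
  x <- sort(values)
  (2 * sum(seq_len(n) * x)) / (n * s) - (n + 1) / n
}

#' Residual average Gini index (RAGI)
#'
#' Cluster-specificity of marker genes relative to housekeeping genes:
#' the mean Gini index of per-cluster mean activity over marker genes
#' minus the same quantity over housekeeping genes. Higher values mean the
#' clustering separates marker activity while housekeeping activity stays
#' flat; the statistic is antisymmetric in its two gene sets.
#'
#' @param activity Genes x cells matrix (expression or gene activity).
#' @param labels Named cluster vector over the columns.
#' @param markers Character vector of marker genes.
#' @param housekeeping Character vector of housekeeping genes.
#' @return RAGI score (difference of mean Gini indices).
#' @export
ragi <- function(activity, labels, markers, housekeeping) {
  x <- as.matrix(activity)
  labels <- labels[colnames(x)]
  cls <- sort(unique(labels))
  cluster_means <- vapply(cls, function(cl) {
    rowMeans(x[, labels == cl, drop = FALSE])
  }, numeric(nrow(x)))
  mean_gini <- function(genes) {
    genes <- intersect(genes, rownames(x))
    if (length(genes) == 0) return(NA_real_)
    mean(apply(cluster_means[genes, , drop = FALSE], 1, gini_index))
  }
  mean_gini(markers) - mean_gini(housekeeping)
}

#' Median F1 score of a label prediction
#'
#' Per true class: precision and recall of the predicted assignment,
#' `F1 = 2PR / (P + R)` (0 when `P + R = 0`, e.g. a class never
#' predicted); the median over true classes is returned.
#'
#' @param true_labels,predicted_labels Label vectors of equal length.
#' @return Median per-class F1 in `[0, 1]`.
#' @export
median_f1 <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors differ in length")
  }
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  f1 <- vapply(sort(unique(true_labels)), function(cl) {
    tp <- sum(true_labels == cl & predicted_labels == cl)
    fp <- sum(true_labels != cl & predicted_labels == cl)
    fn <- sum(true_labels == cl & predicted_labels != cl)
    if (tp == 0) return(0)
    p <- tp / (tp + fp)
    r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1))
  stats::median(f1)
}

#' Spearman correlation between expression and gene activity per cell type
#'
#' For each cell type, correlates the mean expression over that type's RNA
#' cells with the mean gene activity over that type's ATAC cells, across a
#' gene subset (all shared genes by default).
#'
#' @param expr Genes x cells expression matrix.
#' @param activity Genes x cells gene-activity matrix.
#' @param rna_labels,atac_labels Named cell-type vectors over the columns
#'   of `expr` / `activity`.
#' @param genes Optional gene subset (e.g. the top variable genes).
#' @return Named numeric vector of Spearman rho per shared cell type.
#' @export
expression_activity_correlation <- function(expr, activity, rna_labels,
                                            atac_labels, genes = NULL) {
  shared_genes <- intersect(rownames(expr), rownames(activity))
  if (!is.null(genes)) shared_genes <- intersect(shared_genes, genes)
  if (length(shared_genes) < 3) stop("too few shared genes")
  types <- intersect(unique(rna_labels), unique(atac_labels))
  vapply(stats::setNames(types, types), function(tp) {
    e <- Matrix::rowMeans(expr[shared_genes,
                               names(rna_labels)[rna_labels == tp],
                               drop = FALSE])
    a <- Matrix::rowMeans(activity[shared_genes,
                                   names(atac_labels)[atac_labels == tp],
                                   drop = FALSE])
    stats::cor(e, a, method = "spearman")
  }, numeric(1))
}
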