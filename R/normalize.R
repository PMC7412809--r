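#' Global-scaling log normalization
#'
#' Scales each cell's counts to a common library size, then log-transforms:
#' `x -> ln(1 + scale * x / colsum)`. All-zero cells stay zero.
#'
#' @param counts Genes x cells nonnegative matrix.
#' @param scale Target library size (default 10000).
#' @return Sparse matrix of log-normalized values.
#' @export
normalize_log <- function(counts, scale = 10000) {
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  cs <- Matrix::colSums(m)
  fac <- ifelse(cs > 0, scale / cs, 0)
  m <- m %*% Matrix::Diagonal(x = fac)
  m@x <- log1p(m@x)
  dimnames(m) <- dimnames(counts)
  m
}

#' Per-cell peak-count normalization of a binary peak matrix
#'
#' Divides every cell's column by the number of peaks present in that
#' cell, so differential peak tests are not driven by per-cell peak depth.
#'
#' @param B Binary peaks x cells matrix.
#' @return Sparse matrix whose nonzero columns sum to 1.
#' @export
normalize_peak_depth <- function(B) {
  m <- methods::as(Matrix::Matrix(B, sparse = TRUE), "CsparseMatrix")
  cs <- Matrix::colSums(m)
  fac <- ifelse(cs > 0, 1 / cs, 0)
  m <- m %*% Matrix::Diagonal(x = fac)
  dimnames(m) <- dimnames(B)
  m
}

#' Select highly variable genes by standardized variance
#'
#' Variance-stabilizing selection: a loess trend of log10 variance on
#' log10 mean predicts each gene's expected standard deviation; values are
#' z-scored against that prediction, clipped at `sqrt(n_cells)`, and genes
#' are ranked by the variance of the clipped z-scores.
#'
#' @param m Genes x cells matrix (typically log-normalized values).
#' @param n Number of genes to return (default 2000).
#' @param loess_span Span of the mean-variance trend fit (default 0.3).
#' @return Character vector of the top `n` gene names, most variable first.
#'   If fewer informative genes exist, all are returned with a warning.
#' @export
select_variable_genes <- function(m, n = 2000, loess_span = 0.3) {
  x <- as.matrix(m)
  nc <- ncol(x)
  mu <- rowMeans(x)
  v <- apply(x, 1, stats::var)
  informative <- v > 0
  if (sum(informative) < n) {
    warning("only ", sum(informative), " genes with nonzero variance; ",
            "returning all of them")
    n <- sum(informative)
  }
  std_var <- rep(0, nrow(x))
  idx <- which(informative)
  fit <- stats::loess(log10(v[idx]) ~ log10(mu[idx]), span = loess_span,
                      degree = 2)
  sd_exp <- sqrt(10^stats::fitted(fit))
  clip <- sqrt(nc)
  for (k in seq_along(idx)) {
    z <- (x[idx[k], ] - mu[idx[k]]) / sd_exp[k]
    z <- pmin(pmax(z, -clip), clip)
    std_var[idx[k]] <- stats::var(z)
  }
  ord <- order(std_var, decreasing = TRUE)
  head(rownames(x)[ord[std_var[ord] > 0]], n)
}
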