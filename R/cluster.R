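new_embedding <- function(coords, method, singular_values = NULL) {
  structure(list(coords = coords, method = method,
                 singular_values = singular_values),
            class = "sc_embedding")
}

# Truncated SVD helper: irlba for genuinely truncated problems, dense svd
# for tiny matrices where irlba's Lanczos iteration is not worthwhile.
truncated_svd <- function(x, k) {
  if (k >= min(dim(x))) stop("k must be smaller than both matrix dimensions")
  if (min(dim(x)) <= 100 || k > min(dim(x)) / 3) {
    s <- svd(as.matrix(x), nu = k, nv = k)
    list(d = s$d[seq_len(k)], u = s$u, v = s$v)
  } else {
    irlba::irlba(x, nv = k)
  }
}

#' TF-IDF + SVD (latent semantic indexing) embedding of a binary peak matrix
#'
#' Term frequency is each entry divided by its cell's total peak count;
#' inverse document frequency is `ln(1 + n_cells / peak_occurrence)`. The
#' TF-IDF matrix is reduced by truncated SVD and cells are placed at
#' right-singular-vector coordinates scaled by the singular values. The
#' first component of an LSI decomposition typically tracks per-cell
#' sequencing depth rather than cell identity, so it is excluded from the
#' returned coordinates by default (`drop_first`); all singular values are
#' still reported.
#'
#' @param B Binary peaks x cells matrix.
#' @param k Number of singular vectors to compute (default 50).
#' @param drop_first Drop the depth-correlated first component from the
#'   coordinates (default `TRUE`).
#' @return An `sc_embedding` with a cells x k (or k - 1) coordinate
#'   matrix.
#' @export
lsi_embed <- function(B, k = 50, drop_first = TRUE) {
  B <- methods::as(Matrix::Matrix(B, sparse = TRUE), "CsparseMatrix")
  if (k >= min(dim(B))) stop("k must be smaller than both matrix dimensions")
  cs <- Matrix::colSums(B)
  occ <- Matrix::rowSums(B > 0)
  tf <- B %*% Matrix::Diagonal(x = ifelse(cs > 0, 1 / cs, 0))
  idf <- ifelse(occ > 0, log(1 + ncol(B) / occ), 0)
  x <- Matrix::Diagonal(x = idf) %*% tf
  s <- truncated_svd(x, k)
  coords <- s$v %*% diag(s$d, nrow = k)
  rownames(coords) <- colnames(B)
  colnames(coords) <- paste0("LSI_", seq_len(k))
  if (drop_first && k > 1) coords <- coords[, -1, drop = FALSE]
  new_embedding(coords, "lsi", s$d)
}

#' PCA embedding of a (log-normalized) expression matrix
#'
#' Rows (genes) are centered and scaled to unit variance before the
#' truncated SVD; constant genes are dropped.
#'
#' @param m Genes x cells matrix.
#' @param features Optional character vector restricting to a gene subset
#'   (e.g. from [select_variable_genes()]).
#' @param k Number of principal components (default 15).
#' @return An `sc_embedding` with a cells x k coordinate matrix.
#' @export
pca_embed <- function(m, features = NULL, k = 15) {
  x <- as.matrix(m)
  if (!is.null(features)) x <- x[intersect(features, rownames(x)), , drop = FALSE]
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  keep <- sdv > 0
  x <- (x[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  if (k >= min(dim(x))) stop("k must be smaller than both matrix dimensions")
  s <- truncated_svd(x, k)
  coords <- s$v %*% diag(s$d, nrow = k)
  rownames(coords) <- colnames(m)
  colnames(coords) <- paste0("PC_", seq_len(k))
  new_embedding(coords, "pca", s$d)
}

#' Graph-based clustering of an embedding
#'
#' Builds a k-nearest-neighbor graph on the embedding, refines edge weights
#' by the Jaccard similarity of the two cells' neighborhoods (shared
#' nearest neighbors), prunes weak edges, and finds modularity-optimizing
#' communities with the Louvain algorithm.
#'
#' @param emb An `sc_embedding`.
#' @param n_neighbors Neighbors per cell (default 20).
#' @param resolution Modularity resolution (default 0.6).
#' @param prune Minimum Jaccard similarity to keep an edge (default 1/15).
#' @param seed Random seed for community detection (default 2020).
#' @return Named integer vector: cluster id per barcode.
#' @export
cluster_cells <- function(emb, n_neighbors = 20, resolution = 0.6,
                          prune = 1 / 15, seed = 2020) {
  coords <- emb$coords
  n <- nrow(coords)
  if (n < n_neighbors + 1) stop("fewer cells than n_neighbors + 1")
  nn <- RANN::nn2(coords, k = n_neighbors)$nn.idx
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), n_neighbors),
                              j = as.vector(nn), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  jac <- methods::as(shared, "TsparseMatrix")
  keep <- jac@i < jac@j
  i <- jac@i[keep] + 1L
  j <- jac@j[keep] + 1L
  s <- jac@x[keep]
  w <- s / (2 * n_neighbors - s)
  edge <- w >= prune
  g <- igraph::graph_from_data_frame(
    data.frame(from = i[edge], to = j[edge], weight = w[edge]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- igraph::membership(comm)[as.character(seq_len(n))]
  stats::setNames(as.integer(labels), rownames(coords))
}
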