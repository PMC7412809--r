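#' Signature scores for one cluster
#'
#' The score of a cell-type signature is the summed log fold change of its
#' marker genes (restricted to genes present in the data) divided by
#' `log2` of the marker count. The denominator is guarded as
#' `log2(max(2, n))` so singleton signatures do not divide by `log2(1) = 0`.
#' Signatures with no marker present score `-Inf` and are never selected.
#'
#' @param logfc_col Named numeric vector of per-gene log fold changes for
#'   one cluster (a column of [cluster_logfc()]).
#' @param signatures Named list of marker gene vectors
#'   (see [read_signatures()]).
#' @return Named numeric vector of per-cell-type scores.
#' @export
signature_score <- function(logfc_col, signatures) {
  if (length(signatures) == 0) stop("at least one signature required")
  vapply(signatures, function(markers) {
    present <- intersect(markers, names(logfc_col))
    if (length(present) == 0) {
      warning("signature with no marker present in the data")
      return(-Inf)
    }
    sum(logfc_col[present]) / log2(max(2, length(present)))
  }, numeric(1))
}

#' Assign cell types to clusters from signature scores
#'
#' Each cluster takes the cell type with the highest signature score; ties
#' break lexicographically by cell-type name. If no signature scores above
#' 0, the cluster is labeled `"others"` (it may be a population absent
#' from the signature set).
#'
#' @param scores Cell types x clusters numeric matrix, or a list of
#'   per-cluster named score vectors.
#' @return Data frame with `cluster`, `cell_type`, `score`, plus the full
#'   score matrix as attribute `per_type_scores`.
#' @export
assign_cell_types <- function(scores) {
  if (is.list(scores) && !is.data.frame(scores)) {
    scores <- do.call(cbind, scores)
  }
  types <- rownames(scores)
  ord <- order(types)
  res <- lapply(seq_len(ncol(scores)), function(j) {
    s <- scores[ord, j]
    best <- which.max(s)  # first index on ties; rows are sorted by name
    if (!is.finite(s[best]) || s[best] <= 0) {
      list(cell_type = "others", score = max(s[is.finite(s)], -Inf))
    } else {
      list(cell_type = types[ord][best], score = s[best])
    }
  })
  out <- data.frame(
    cluster = colnames(scores),
    cell_type = vapply(res, `[[`, "", "cell_type"),
    score = vapply(res, `[[`, 0, "score"),
    stringsAsFactors = FALSE
  )
  attr(out, "per_type_scores") <- scores
  out
}

#' Annotate clusters by marker-gene signatures
#'
#' Convenience wrapper: per-cluster log fold changes, signature scores and
#' cell-type assignment in one call. For scATAC-seq input, pass the
#' log-normalized gene activity matrix so regulatory potential stands in
#' for expression.
#'
#' @param normed Genes x cells log-normalized matrix (expression or gene
#'   activity).
#' @param labels Named cluster vector over the columns.
#' @param signatures Named list of marker gene vectors.
#' @return See [assign_cell_types()].
#' @export
annotate_clusters <- function(normed, labels, signatures) {
  lfc <- cluster_logfc(normed, labels)
  score_mat <- vapply(seq_len(ncol(lfc)),
                      function(j) signature_score(lfc[, j], signatures),
                      numeric(length(signatures)))
  score_mat <- matrix(score_mat, nrow = length(signatures),
                      dimnames = list(names(signatures), colnames(lfc)))
  assign_cell_types(score_mat)
}
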