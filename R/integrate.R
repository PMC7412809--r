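#' Joint CCA embedding of expression and gene activity
#'
#' Canonical-correlation-style co-embedding: gene rows of both matrices are
#' standardized, the cross-product `t(X) %*% Y` is decomposed by truncated
#' SVD, RNA cells take the left singular vectors and ATAC cells the right
#' ones, and every cell's coordinate row is L2-normalized. This treats the
#' two modalities as two batches measuring the same genes, with regulatory
#' potential standing in for expression on the ATAC side.
#'
#' @param X Genes x cells expression matrix (log-normalized).
#' @param Y Genes x cells gene-activity matrix (log-normalized), same gene
#'   rows as `X` (typically the top 2000 variable genes of the RNA data).
#' @param k Embedding dimension (default 20).
#' @return A `joint_embedding`: list with `rna` and `atac` coordinate
#'   matrices (cells x k) and `method = "cca"`.
#' @export
cca_embed <- function(X, Y, k = 20) {
  shared <- intersect(rownames(X), rownames(Y))
  if (length(shared) < k) stop("fewer shared genes than embedding dimensions")
  x <- as.matrix(X[shared, , drop = FALSE])
  y <- as.matrix(Y[shared, , drop = FALSE])
  std <- function(m) {
    mu <- rowMeans(m)
    sdv <- apply(m, 1, stats::sd)
    sdv[sdv == 0] <- 1
    (m - mu) / sdv
  }
  cross <- crossprod(std(x), std(y))
  s <- truncated_svd(cross, k)
  l2 <- function(m) m / pmax(sqrt(rowSums(m^2)), 1e-12)
  rna <- l2(s$u)
  atac <- l2(s$v)
  rownames(rna) <- colnames(X)
  rownames(atac) <- colnames(Y)
  colnames(rna) <- colnames(atac) <- paste0("CC_", seq_len(k))
  structure(list(rna = rna, atac = atac, method = "cca"),
            class = "joint_embedding")
}

#' Mutual-nearest-neighbor anchors between modalities
#'
#' A pair (RNA cell, ATAC cell) is an anchor when each is among the other's
#' `k_anchor` nearest cross-modality neighbors in the joint embedding. The
#' anchor weight is `1 - mean(rank - 1) / k_anchor` over the pair's ranks
#' in the two neighbor lists, so mutually-first neighbors get weight 1.
#'
#' @param emb A `joint_embedding` from [cca_embed()].
#' @param k_anchor Neighbors searched per cell (default 5).
#' @return Data frame with `rna_cell`, `atac_cell`, `weight`, `distance`.
#' @export
find_anchors <- function(emb, k_anchor = 5) {
  kr <- min(k_anchor, nrow(emb$atac))
  ka <- min(k_anchor, nrow(emb$rna))
  nn_ra <- RANN::nn2(emb$atac, emb$rna, k = kr)   # atac neighbors of rna cells
  nn_ar <- RANN::nn2(emb$rna, emb$atac, k = ka)   # rna neighbors of atac cells
  pairs <- data.frame(r = rep(seq_len(nrow(emb$rna)), kr),
                      a = as.vector(nn_ra$nn.idx),
                      rank_r = rep(seq_len(kr), each = nrow(emb$rna)),
                      dist = as.vector(nn_ra$nn.dists))
  rank_a <- matrix(NA_integer_, nrow(emb$atac), nrow(emb$rna))
  for (j in seq_len(ka)) {
    rank_a[cbind(seq_len(nrow(emb$atac)), nn_ar$nn.idx[, j])] <- j
  }
  pr <- rank_a[cbind(pairs$a, pairs$r)]
  mutual <- !is.na(pr)
  pairs <- pairs[mutual, , drop = FALSE]
  pairs$rank_a <- pr[mutual]
  w <- 1 - ((pairs$rank_r - 1) + (pairs$rank_a - 1)) / (2 * k_anchor)
  out <- data.frame(rna_cell = rownames(emb$rna)[pairs$r],
                    atac_cell = rownames(emb$atac)[pairs$a],
                    weight = w, distance = pairs$dist,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Transfer labels from RNA cells to ATAC cells through anchors
#'
#' Each ATAC cell collects its `k_weight` nearest anchors in the joint
#' embedding (measured to the anchors' ATAC-side coordinates) and takes a
#' Gaussian-kernel-weighted vote of the anchors' RNA labels, further
#' weighted by the anchor weights; scores are normalized to sum to 1. When
#' an ATAC cell coincides with an anchor whose two cells also coincide
#' (an exact cross-modality match, as with identical datasets), only such
#' exact anchors vote. Cells with no anchors in reach get label
#' `"unassigned"` with score 0.
#'
#' @param anchors Anchor data frame from [find_anchors()].
#' @param rna_labels Named vector of labels for the RNA cells.
#' @param emb The `joint_embedding` the anchors were found in.
#' @param k_weight Anchors voting per cell (default 10).
#' @return Data frame (`barcode`, `predicted_label`, `max_score`), with
#'   the full cells x labels score matrix as attribute `prediction_scores`.
#' @export
transfer_labels <- function(anchors, rna_labels, emb, k_weight = 10) {
  atac_cells <- rownames(emb$atac)
  labels <- sort(unique(as.character(rna_labels)))
  scores <- matrix(0, length(atac_cells), length(labels),
                   dimnames = list(atac_cells, labels))
  if (nrow(anchors) > 0) {
    anchor_lab <- as.character(rna_labels[anchors$rna_cell])
    anchor_pos <- emb$atac[anchors$atac_cell, , drop = FALSE]
    nn <- RANN::nn2(anchor_pos, emb$atac, k = min(k_weight, nrow(anchors)))
    eps <- 1e-8
    for (i in seq_along(atac_cells)) {
      d <- nn$nn.dists[i, ]
      idx <- nn$nn.idx[i, ]
      exact <- d < eps & anchors$distance[idx] < eps
      if (any(exact)) {
        sel <- idx[exact]
        w <- anchors$weight[sel]
      } else {
        sel <- idx
        sigma <- mean(d)
        w <- exp(-d^2 / (2 * sigma^2)) * anchors$weight[sel]
      }
      v <- tapply(w, anchor_lab[sel], sum)
      scores[i, names(v)] <- v
    }
  }
  tot <- rowSums(scores)
  norm <- scores / ifelse(tot > 0, tot, 1)
  pred <- ifelse(tot > 0, labels[max.col(norm, ties.method = "first")],
                 "unassigned")
  out <- data.frame(barcode = atac_cells, predicted_label = pred,
                    max_score = apply(norm, 1, max) * (tot > 0),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "prediction_scores") <- norm
  out
}
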