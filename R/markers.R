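# Rank matrix (cells ranked within each feature row), plus the per-row tie
# correction term sum(t^3 - t) needed by the normal approximation.
row_ranks_and_ties <- function(x) {
  ranks <- t(apply(x, 1, rank))
  ties <- apply(x, 1, function(r) {
    t <- table(r)
    sum(t^3 - t)
  })
  list(ranks = ranks, ties = ties)
}

# One-vs-rest two-sided Wilcoxon rank-sum p-values for every feature.
# Small problems (few enough group assignments to enumerate) get the exact
# permutation distribution, ties and all; larger ones the normal
# approximation with tie correction, the convention of the fast rank-sum
# marker frameworks.
wilcoxon_p <- function(ranks, ties, in_group, max_exact = 50000) {
  n <- ncol(ranks)
  n1 <- sum(in_group)
  n2 <- n - n1
  mu <- n1 * n2 / 2
  r1 <- rowSums(ranks[, in_group, drop = FALSE])
  u <- r1 - n1 * (n1 + 1) / 2
  if (choose(n, n1) <= max_exact) {
    combos <- utils::combn(n, n1)
    apply(ranks, 1, function(r) {
      u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
      u_obs <- sum(r[in_group]) - n1 * (n1 + 1) / 2
      mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    })
  } else {
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - ties / (n * (n - 1)))
    z <- ifelse(sigma2 > 0, (u - mu) / sqrt(sigma2), 0)
    pmin(1, 2 * stats::pnorm(-abs(z)))
  }
}

#' Default differential-analysis thresholds
#'
#' @param type `"genes"` (logFC > 0.25, presence fraction >= 0.25,
#'   p < 1e-5) or `"peaks"` (logFC > 0.1, presence >= 0.01, p < 1e-5).
#' @return List with `min_logfc`, `min_pct`, `max_p`.
#' @export
marker_thresholds <- function(type = c("genes", "peaks")) {
  type <- match.arg(type)
  if (type == "genes") list(min_logfc = 0.25, min_pct = 0.25, max_p = 1e-5)
  else list(min_logfc = 0.1, min_pct = 0.01, max_p = 1e-5)
}

#' One-vs-rest Wilcoxon marker detection
#'
#' For every cluster, tests each feature with a two-sided Wilcoxon
#' rank-sum test (cells in the cluster versus all other cells; normal
#' approximation with tie correction) and reports features passing the
#' effect-size, presence and significance thresholds. The log fold change
#' is `ln((mean_in + 1) / (mean_out + 1))` on de-logged normalized values.
#'
#' @param normed Features x cells matrix of log-normalized values (for
#'   peaks, use [normalize_peak_depth()] output, which is not logged; the
#'   logFC formula is applied to the values as given).
#' @param labels Named cluster vector over the columns of `normed`.
#' @param thresholds See [marker_thresholds()].
#' @param delogged Set `TRUE` when `normed` holds values on the natural
#'   scale already (e.g. depth-normalized peak matrices), so means are not
#'   exponentiated first.
#' @return Data frame of marker records: `feature`, `cluster`, `logFC`,
#'   `pct_in`, `pct_out`, `p_value`, sorted by cluster then p-value.
#'   Clusters with fewer than 3 cells are skipped with a warning.
#' @export
wilcoxon_markers <- function(normed, labels,
                             thresholds = marker_thresholds("genes"),
                             delogged = FALSE) {
  x <- as.matrix(normed)
  labels <- labels[colnames(x)]
  if (anyNA(labels)) stop("labels must cover every column of the matrix")
  rt <- row_ranks_and_ties(x)
  vals <- if (delogged) x else expm1(x)
  out <- list()
  for (cl in sort(unique(labels))) {
    in_group <- labels == cl
    if (sum(in_group) < 3) {
      warning("cluster ", cl, " has fewer than 3 cells; skipped")
      next
    }
    p <- wilcoxon_p(rt$ranks, rt$ties, in_group)
    mean_in <- rowMeans(vals[, in_group, drop = FALSE])
    mean_out <- rowMeans(vals[, !in_group, drop = FALSE])
    lfc <- log((mean_in + 1) / (mean_out + 1))
    pct_in <- rowMeans(x[, in_group, drop = FALSE] > 0)
    pct_out <- rowMeans(x[, !in_group, drop = FALSE] > 0)
    keep <- lfc > thresholds$min_logfc & pct_in >= thresholds$min_pct &
      p < thresholds$max_p
    if (any(keep)) {
      rec <- data.frame(feature = rownames(x)[keep], cluster = cl,
                        logFC = lfc[keep], pct_in = pct_in[keep],
                        pct_out = pct_out[keep], p_value = p[keep],
                        stringsAsFactors = FALSE)
      out[[as.character(cl)]] <- rec[order(rec$p_value, -rec$logFC), ]
    }
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(feature = character(0), cluster = integer(0),
               logFC = numeric(0), pct_in = numeric(0), pct_out = numeric(0),
               p_value = numeric(0))
  }
  rownames(res) <- NULL
  res
}

#' Per-cluster log fold changes for every gene
#'
#' Unfiltered one-vs-rest log fold changes (same formula as
#' [wilcoxon_markers()], both signs kept), the input to signature scoring.
#'
#' @inheritParams wilcoxon_markers
#' @return Genes x clusters numeric matrix.
#' @export
cluster_logfc <- function(normed, labels, delogged = FALSE) {
  x <- as.matrix(normed)
  labels <- labels[colnames(x)]
  if (anyNA(labels)) stop("labels must cover every column of the matrix")
  vals <- if (delogged) x else expm1(x)
  cls <- sort(unique(labels))
  out <- vapply(cls, function(cl) {
    in_group <- labels == cl
    mean_in <- rowMeans(vals[, in_group, drop = FALSE])
    mean_out <- rowMeans(vals[, !in_group, drop = FALSE])
    log((mean_in + 1) / (mean_out + 1))
  }, numeric(nrow(x)))
  dimnames(out) <- list(rownames(x), cls)
  out
}
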