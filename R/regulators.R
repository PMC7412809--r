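# Information content of PWM columns: 2 + sum(p * log2 p), in bits.
pwm_ic <- function(probs) {
  apply(probs, 2, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

pwm_revcomp <- function(probs) {
  probs[c("T", "G", "C", "A"), rev(seq_len(ncol(probs))), drop = FALSE]
}

# IC-weighted mean column-wise Pearson correlation at one alignment.
aligned_similarity <- function(pa, pb, ica, icb) {
  w <- (ica + icb) / 2
  pcc <- vapply(seq_len(ncol(pa)), function(k) {
    r <- suppressWarnings(stats::cor(pa[, k], pb[, k]))
    if (is.na(r)) 0 else r
  }, numeric(1))
  if (sum(w) <= 0) return(NA_real_)
  sum(w * pcc) / sum(w)
}

#' Similarity between two position weight matrices
#'
#' Slides one motif across the other (both orientations), computes at each
#' alignment the mean Pearson correlation of aligned probability columns
#' weighted by their average information content, and returns the maximum
#' over all alignments with at least `min_overlap` aligned columns.
#'
#' @param a,b `pwm` objects.
#' @param min_overlap Minimum aligned columns per alignment (default 5).
#' @return Similarity in `[-1, 1]`; identical motifs (or a motif and its
#'   reverse complement) score 1.
#' @export
pwm_similarity <- function(a, b, min_overlap = 5) {
  pa <- a$probs
  la <- ncol(pa)
  lb <- ncol(b$probs)
  if (min(la, lb) < min_overlap) {
    stop("motifs too short for the required overlap")
  }
  ica <- pwm_ic(pa)
  best <- -Inf
  for (pb_full in list(b$probs, pwm_revcomp(b$probs))) {
    icb <- pwm_ic(pb_full)
    for (off in seq(-(lb - min_overlap), la - min_overlap)) {
      ia <- seq(max(1, 1 + off), min(la, lb + off))
      ib <- ia - off
      s <- aligned_similarity(pa[, ia, drop = FALSE],
                              pb_full[, ib, drop = FALSE],
                              ica[ia], icb[ib])
      if (!is.na(s) && s > best) best <- s
    }
  }
  if (!is.finite(best)) stop("no alignment with positive information content")
  best
}

#' Group motifs into families by similarity
#'
#' Average-linkage hierarchical clustering on distance `1 - similarity`,
#' cut so that motifs with similarity above the threshold share a family.
#' Enrichment scores are later shared within each family, since factors
#' with near-identical motifs cannot be distinguished by motif evidence.
#'
#' @param pwms List of `pwm` objects.
#' @param threshold Similarity threshold (default 0.7).
#' @param min_overlap Passed to [pwm_similarity()].
#' @return Named list mapping family id (`"family1"`, ...) to member motif
#'   names; families partition the input, singletons allowed.
#' @export
cluster_motifs <- function(pwms, threshold = 0.7, min_overlap = 5) {
  nms <- vapply(pwms, `[[`, "", "name")
  n <- length(pwms)
  if (n == 0) return(list())
  if (n == 1) return(list(family1 = nms))
  d <- matrix(0, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      s <- pwm_similarity(pwms[[i]], pwms[[j]], min_overlap)
      d[i, j] <- d[j, i] <- 1 - s
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  memb <- stats::cutree(hc, h = 1 - threshold)
  fam <- split(nms, memb)
  names(fam) <- paste0("family", seq_along(fam))
  fam
}

#' Peak-set enrichment of reference regulator binding sites
#'
#' For each regulator's reference peak set, builds the 2x2 table of
#' universe peaks (in the cluster-specific set or not, overlapping the
#' reference set or not), computes a one-sided Fisher exact p-value for
#' enrichment, a Haldane-smoothed odds ratio (+0.5 on every cell), and the
#' composite score `-log10(p) * log2(odds_ratio)` (negative under
#' depletion). When several reference sets share a regulator name, only
#' the highest-scoring one is kept.
#'
#' @param cluster_peaks Interval data frame of cluster-specific peaks
#'   (a subset of `universe`).
#' @param universe Interval data frame of all peaks considered.
#' @param reference_sets Named list: regulator -> interval data frame of
#'   reference (e.g. ChIP-seq) peaks.
#' @param cluster Optional cluster id recorded in the output.
#' @return Data frame of enrichment records (`regulator`, `cluster`,
#'   `p_value`, `odds_ratio`, `score`, `rank`), rank 1 = highest score.
#' @export
peakset_enrichment <- function(cluster_peaks, universe, reference_sets,
                               cluster = NA) {
  if (nrow(universe) == 0) stop("empty peak universe")
  uid <- interval_ids(universe)
  in_cluster <- uid %in% interval_ids(cluster_peaks)
  recs <- lapply(names(reference_sets), function(reg) {
    hits <- interval_overlaps(universe, reference_sets[[reg]])
    in_ref <- logical(nrow(universe))
    in_ref[unique(hits$query)] <- TRUE
    a <- sum(in_cluster & in_ref)
    b <- sum(in_cluster & !in_ref)
    c_ <- sum(!in_cluster & in_ref)
    d <- sum(!in_cluster & !in_ref)
    p <- stats::fisher.test(matrix(c(a, c_, b, d), 2),
                            alternative = "greater")$p.value
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    data.frame(regulator = reg, cluster = cluster, p_value = p,
               odds_ratio = or, score = -log10(p) * log2(or),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  # best dataset per regulator
  out <- out[order(out$regulator, -out$score), ]
  out <- out[!duplicated(out$regulator), ]
  rank_by_score(out)
}

rank_by_score <- function(records) {
  ord <- order(-records$score, records$regulator)
  records <- records[ord, ]
  records$rank <- seq_len(nrow(records))
  rownames(records) <- NULL
  records
}

#' Propagate enrichment scores within motif families
#'
#' Every regulator takes the maximum enrichment score found in its motif
#' family (regulators absent from any family keep their own score); ranks
#' are recomputed. Idempotent, and never decreases a score.
#'
#' @param records Enrichment data frame from [peakset_enrichment()].
#' @param families Named list of family member vectors from
#'   [cluster_motifs()].
#' @return Records with propagated `score` and fresh `rank`.
#' @export
propagate_family_scores <- function(records, families) {
  fam_of <- stats::setNames(rep(names(families), lengths(families)),
                            unlist(families, use.names = FALSE))
  fam <- fam_of[records$regulator]
  known <- !is.na(fam)
  if (any(known)) {
    fam_max <- tapply(records$score[known], fam[known], max)
    records$score[known] <- pmax(records$score[known],
                                 as.numeric(fam_max[fam[known]]))
  }
  rank_by_score(records)
}

#' Combine regulator rankings from two modalities by rank product
#'
#' @param rna_records,atac_records Enrichment data frames with `regulator`
#'   and `rank` columns. A regulator missing from one modality receives
#'   that modality's worst rank plus one.
#' @return Data frame (`regulator`, `rank_rna`, `rank_atac`,
#'   `rank_product`, `rank`) sorted by the rank product
#'   `sqrt(rank_rna * rank_atac)`, ties broken by regulator name.
#' @export
rank_product_combine <- function(rna_records, atac_records) {
  regs <- sort(union(rna_records$regulator, atac_records$regulator))
  r1 <- rna_records$rank[match(regs, rna_records$regulator)]
  r2 <- atac_records$rank[match(regs, atac_records$regulator)]
  worst1 <- if (nrow(rna_records)) max(rna_records$rank) + 1 else 1
  worst2 <- if (nrow(atac_records)) max(atac_records$rank) + 1 else 1
  r1[is.na(r1)] <- worst1
  r2[is.na(r2)] <- worst2
  rp <- sqrt(r1 * r2)
  ord <- order(rp, regs)
  out <- data.frame(regulator = regs[ord], rank_rna = r1[ord],
                    rank_atac = r2[ord], rank_product = rp[ord],
                    stringsAsFactors = FALSE)
  out$rank <- seq_len(nrow(out))
  out
}

#' Filter regulators on expression / regulatory-potential support
#'
#' Drops regulators with mean expression equal to 0 or mean regulatory
#' potential below 0.5, then re-ranks the survivors by mean expression
#' (RNA context) or mean RP (ATAC context), highest first.
#'
#' @param records Enrichment data frame.
#' @param mean_expression,mean_rp Named numeric vectors (regulator ->
#'   level). Regulators missing from either vector are dropped.
#' @param context `"rna"` or `"atac"`: which level drives the re-ranking.
#' @param min_rp RP threshold (default 0.5).
#' @return Filtered, re-ranked records with `mean_expression` and
#'   `mean_rp` columns appended.
#' @export
filter_regulators <- function(records, mean_expression, mean_rp,
                              context = c("rna", "atac"), min_rp = 0.5) {
  context <- match.arg(context)
  expr <- mean_expression[records$regulator]
  rp <- mean_rp[records$regulator]
  keep <- !is.na(expr) & !is.na(rp) & expr > 0 & rp >= min_rp
  out <- records[keep, , drop = FALSE]
  out$mean_expression <- as.numeric(expr[keep])
  out$mean_rp <- as.numeric(rp[keep])
  key <- if (context == "rna") out$mean_expression else out$mean_rp
  out <- out[order(-key, out$regulator), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
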