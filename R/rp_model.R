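#' Regulatory-potential model configuration
#'
#' The regulatory-potential (RP) model scores a gene in a cell by summing,
#' over the cell's accessible peaks, weights that decay exponentially with
#' the peak-center-to-TSS distance: `w = 2^(-d / d0)`. `d0` is the
#' half-decay distance; 10 kb (the default) suits enhancer-driven
#' regulation and 1 kb promoter-driven regulation. Weights for peaks beyond
#' `distance_cutoff` are set to exactly 0 (with the defaults the largest
#' discarded weight is below 5e-4).
#'
#' The enhanced model additionally (a) scores a peak overlapping one of the
#' gene's own exons as `exon_length_scale / total_exon_length` — as if it
#' sat on the TSS, normalized by the gene's merged exon length — and (b)
#' zeroes any peak lying in the promoter window or exons of a different
#' gene, removing interference from neighbouring highly expressed genes.
#'
#' @param d0 Half-decay distance in bp (default 10000).
#' @param distance_cutoff Peak-to-TSS distance beyond which weights are 0
#'   (default 150000 bp).
#' @param model `"simple"` or `"enhanced"`.
#' @param exon_length_scale Numerator of the exon rule in bp (default 1000,
#'   i.e. per-kilobase of exon; 1 gives the raw reciprocal of the exon
#'   length in bp).
#' @param promoter_flank Promoter half-width used by the exclusion rule
#'   (default 2000 bp).
#' @return An `rp_config` list.
#' @export
rp_config <- function(d0 = 10000, distance_cutoff = 150000,
                      model = c("enhanced", "simple"),
                      exon_length_scale = 1000, promoter_flank = 2000) {
  model <- match.arg(model)
  if (d0 <= 0) stop("d0 must be positive")
  if (distance_cutoff <= 0) stop("distance_cutoff must be positive")
  structure(list(d0 = d0, distance_cutoff = distance_cutoff, model = model,
                 exon_length_scale = exon_length_scale,
                 promoter_flank = promoter_flank),
            class = "rp_config")
}

#' Exponential-decay regulatory-potential weight
#'
#' @param distance Peak-center-to-TSS distance in bp (nonnegative;
#'   vectorized).
#' @param d0 Half-decay distance in bp.
#' @param cutoff Distances strictly greater than this give weight 0; use
#'   `Inf` to disable truncation.
#' @return `2^(-distance / d0)`, or 0 beyond the cutoff.
#' @examples
#' decay_weight(0, 10000)       # 1
#' decay_weight(10000, 10000)   # 0.5 (half-decay)
#' decay_weight(150001, 10000)  # 0 (truncated)
#' @export
decay_weight <- function(distance, d0 = 10000, cutoff = 150000) {
  if (any(distance < 0)) stop("distance must be nonnegative")
  ifelse(distance > cutoff, 0, 2^(-distance / d0))
}

#' Build the peak-by-gene regulatory-potential weight matrix
#'
#' @param peaks Interval data frame of peaks.
#' @param genes A `gene_models` object.
#' @param config An [rp_config()].
#' @return Sparse nonnegative peaks x genes matrix; row names are peak ids
#'   (`chrom:start-end`), column names gene ids. Peak-gene pairs with
#'   center-to-TSS distance over the cutoff are exactly 0 unless rescued by
#'   the enhanced exon rule.
#' @export
build_weight_matrix <- function(peaks, genes, config = rp_config()) {
  gene_tab <- genes$genes
  np <- nrow(peaks)
  ng <- nrow(gene_tab)
  peak_ids <- interval_ids(peaks)
  if (np == 0 || ng == 0) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(np, ng),
                                dimnames = list(peak_ids, gene_tab$gene_id)))
  }
  centers <- interval_centers(peaks)

  # candidate decay pairs: peak centers within the cutoff of a TSS
  tss_win <- genomic_intervals(gene_tab$chrom,
                               pmax(0, gene_tab$tss - config$distance_cutoff),
                               gene_tab$tss + config$distance_cutoff + 1)
  center_pts <- genomic_intervals(peaks$chrom, floor(centers),
                                  floor(centers) + 1)
  cand <- interval_overlaps(center_pts, tss_win)
  d <- abs(centers[cand$query] - gene_tab$tss[cand$subject])
  keep <- d <= config$distance_cutoff
  pi <- cand$query[keep]
  gi <- cand$subject[keep]
  w <- decay_weight(d[keep], config$d0, config$distance_cutoff)

  if (config$model == "enhanced") {
    exon_hits <- interval_overlaps(peaks, genes$exons)
    exon_gene <- match(genes$exons$gene_id[exon_hits$subject], gene_tab$gene_id)
    own_exon <- unique(data.frame(p = exon_hits$query, g = exon_gene))

    prom_hits <- interval_overlaps(peaks, promoter_windows(
      genes, config$promoter_flank))
    annot <- unique(rbind(own_exon,
                          data.frame(p = prom_hits$query, g = prom_hits$subject)))

    # (b) zero decay weights of pairs where the peak lies in another gene's
    # promoter or exon
    blocked_peaks <- split(annot$g, annot$p)
    if (length(pi)) {
      blocked <- vapply(seq_along(pi), function(k) {
        hit_genes <- blocked_peaks[[as.character(pi[k])]]
        !is.null(hit_genes) && any(hit_genes != gi[k])
      }, logical(1))
      w[blocked] <- 0
    }

    # (a) own-exon rule takes precedence: replace/insert those pairs
    key <- paste(pi, gi)
    exon_key <- paste(own_exon$p, own_exon$g)
    exon_w <- config$exon_length_scale /
      gene_tab$total_exon_length[own_exon$g]
    hit <- match(exon_key, key)
    w[hit[!is.na(hit)]] <- exon_w[!is.na(hit)]
    new <- is.na(hit)
    pi <- c(pi, own_exon$p[new])
    gi <- c(gi, own_exon$g[new])
    w <- c(w, exon_w[new])
  }

  nz <- w > 0
  Matrix::sparseMatrix(i = pi[nz], j = gi[nz], x = w[nz], dims = c(np, ng),
                       dimnames = list(peak_ids, gene_tab$gene_id))
}

#' Gene activity scores by matrix multiplication
#'
#' Computes `R = t(W) %*% B`: the genes x cells matrix of regulatory
#' potential scores, where `W` holds peak-to-gene weights and `B` is the
#' binary peak-by-cell matrix. No further normalization is applied.
#'
#' @param W Peaks x genes weight matrix from [build_weight_matrix()].
#' @param B Binary peaks x cells matrix; row names must equal `W`'s.
#' @return Sparse genes x cells matrix of nonnegative scores.
#' @export
regulatory_potential <- function(W, B) {
  if (nrow(W) != nrow(B) || !identical(rownames(W), rownames(B))) {
    stop("peak lists of W and B are not aligned")
  }
  methods::as(Matrix::t(W) %*% B, "CsparseMatrix")
}
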