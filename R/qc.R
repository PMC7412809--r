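#' Read a 10x-style fragments table
#'
#' @param path TSV with columns chrom, start, end, barcode, count
#'   (0-based half-open, no header).
#' @return Data frame with those five columns; `count >= 1` enforced.
#' @export
read_fragments <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 5) stop("fragments file needs 5 columns")
  out <- data.frame(chrom = as.character(tab[[1]]),
                    start = as.numeric(tab[[2]]),
                    end = as.numeric(tab[[3]]),
                    barcode = as.character(tab[[4]]),
                    count = as.integer(tab[[5]]),
                    stringsAsFactors = FALSE)
  if (any(out$count < 1)) stop("fragment counts must be >= 1")
  if (any(out$start >= out$end)) stop("fragment start >= end")
  out
}

#' Write a fragments table
#' @param fragments Data frame as returned by [read_fragments()].
#' @param path Output path.
#' @export
write_fragments <- function(fragments, path) {
  utils::write.table(
    fragments[, c("chrom", "start", "end", "barcode", "count")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-barcode QC metrics for scRNA-seq counts
#'
#' @param counts Genes x cells count matrix (nonnegative integers) with
#'   gene row names and barcode column names.
#' @param mito_gene_prefix Prefix identifying mitochondrial genes
#'   (default `"MT-"`).
#' @param spikein_prefix Prefix identifying spike-in features (default
#'   `"ERCC-"`).
#' @return Data frame with `barcode`, `n_reads` (column sum), `n_features`
#'   (genes with nonzero count), `frac_mito`, `frac_spikein`. Fractions of
#'   an all-zero barcode are 0.
#' @export
rna_cell_metrics <- function(counts, mito_gene_prefix = "MT-",
                             spikein_prefix = "ERCC-") {
  if (any(counts < 0)) stop("counts must be nonnegative")
  total <- Matrix::colSums(counts)
  mito <- startsWith(rownames(counts), mito_gene_prefix)
  spike <- startsWith(rownames(counts), spikein_prefix)
  safe_frac <- function(part) ifelse(total > 0, part / total, 0)
  data.frame(
    barcode = colnames(counts),
    n_reads = as.numeric(total),
    n_features = as.numeric(Matrix::colSums(counts > 0)),
    frac_mito = as.numeric(safe_frac(Matrix::colSums(counts[mito, , drop = FALSE]))),
    frac_spikein = as.numeric(safe_frac(Matrix::colSums(counts[spike, , drop = FALSE]))),
    stringsAsFactors = FALSE
  )
}

#' Per-barcode QC metrics for scATAC-seq fragments
#'
#' Reads are counted with the fragment `count` field; a fragment lies in a
#' promoter if it overlaps any gene's promoter window (TSS +/- the flank
#' stored in `genes`) by at least one base.
#'
#' @param fragments Fragment data frame (see [read_fragments()]).
#' @param genes A `gene_models` object supplying promoter windows.
#' @param mito_chroms Chromosome names counted as mitochondrial
#'   (default `"chrM"`).
#' @return Data frame with `barcode`, `n_reads`, `n_features` (number of
#'   distinct fragments), `frac_promoter`, `frac_mito`.
#' @export
atac_cell_metrics <- function(fragments, genes, mito_chroms = "chrM") {
  prom <- promoter_windows(genes)
  frag_iv <- genomic_intervals(fragments$chrom, fragments$start, fragments$end)
  hits <- interval_overlaps(frag_iv, prom)
  in_prom <- logical(nrow(fragments))
  in_prom[unique(hits$query)] <- TRUE
  is_mito <- fragments$chrom %in% mito_chroms

  total <- rowsum(fragments$count, fragments$barcode)
  prom_reads <- rowsum(fragments$count * in_prom, fragments$barcode)
  mito_reads <- rowsum(fragments$count * is_mito, fragments$barcode)
  nfrag <- rowsum(rep(1, nrow(fragments)), fragments$barcode)
  bc <- rownames(total)
  data.frame(
    barcode = bc,
    n_reads = as.numeric(total),
    n_features = as.numeric(nfrag),
    frac_promoter = as.numeric(ifelse(total > 0, prom_reads / total, 0)),
    frac_mito = as.numeric(ifelse(total > 0, mito_reads / total, 0)),
    stringsAsFactors = FALSE
  )
}

#' QC thresholds
#'
#' Defaults follow the workflow's barcode-selection rules: a barcode passes
#' when it has strictly more than `min_reads` reads/UMIs, at least
#' `min_features` detected genes (RNA), at least `min_frac_promoter` of its
#' reads in promoter windows (ATAC), no more than `max_frac_mito`
#' mitochondrial reads, and no more than `max_frac_spikein` spike-in reads.
#'
#' @param modality `"rna"` or `"atac"`; selects the default set
#'   (RNA: 1000 reads / 500 genes / 5\% mito / 5\% spike-in;
#'   ATAC: 1000 reads / 10\% promoter fraction / 10\% mito).
#' @param min_reads,min_features,min_frac_promoter,max_frac_mito,max_frac_spikein
#'   Override individual thresholds; `NULL` disables a check.
#' @return A named list of thresholds.
#' @export
qc_thresholds <- function(modality = c("rna", "atac"),
                          min_reads = NULL, min_features = NULL,
                          min_frac_promoter = NULL, max_frac_mito = NULL,
                          max_frac_spikein = NULL) {
  modality <- match.arg(modality)
  def <- if (modality == "rna") {
    list(min_reads = 1000, min_features = 500, min_frac_promoter = NULL,
         max_frac_mito = 0.05, max_frac_spikein = 0.05)
  } else {
    list(min_reads = 1000, min_features = NULL, min_frac_promoter = 0.10,
         max_frac_mito = 0.10, max_frac_spikein = NULL)
  }
  given <- list(min_reads = min_reads, min_features = min_features,
                min_frac_promoter = min_frac_promoter,
                max_frac_mito = max_frac_mito,
                max_frac_spikein = max_frac_spikein)
  for (k in names(given)) if (!is.null(given[[k]])) def[[k]] <- given[[k]]
  def$modality <- modality
  def
}

#' Filter barcodes on QC metrics
#'
#' Comparison directions are deliberate: `min_reads` is strict (`>`),
#' `min_features` and `min_frac_promoter` are inclusive (`>=`), the
#' maximum-fraction limits are inclusive (`<=`).
#'
#' @param metrics Metrics data frame from [rna_cell_metrics()] or
#'   [atac_cell_metrics()].
#' @param thresholds Threshold list from [qc_thresholds()].
#' @return Character vector of passing barcodes (in input order).
#' @export
filter_cells <- function(metrics, thresholds) {
  pass <- rep(TRUE, nrow(metrics))
  if (!is.null(thresholds$min_reads)) {
    pass <- pass & metrics$n_reads > thresholds$min_reads
  }
  if (!is.null(thresholds$min_features) && "n_features" %in% names(metrics)) {
    pass <- pass & metrics$n_features >= thresholds$min_features
  }
  if (!is.null(thresholds$min_frac_promoter) &&
      "frac_promoter" %in% names(metrics)) {
    pass <- pass & metrics$frac_promoter >= thresholds$min_frac_promoter
  }
  if (!is.null(thresholds$max_frac_mito) && "frac_mito" %in% names(metrics)) {
    pass <- pass & metrics$frac_mito <= thresholds$max_frac_mito
  }
  if (!is.null(thresholds$max_frac_spikein) &&
      "frac_spikein" %in% names(metrics)) {
    pass <- pass & metrics$frac_spikein <= thresholds$max_frac_spikein
  }
  metrics$barcode[pass]
}

#' Binarize a peak count matrix
#'
#' Accessibility in a diploid cell is treated as on/off: any positive count
#' becomes 1.
#'
#' @param m Peaks x cells matrix with nonnegative entries.
#' @return Sparse matrix with the same dimnames and entries in \{0, 1\}.
#' @export
binarize <- function(m) {
  m <- methods::as(Matrix::Matrix(m * 1, sparse = TRUE), "CsparseMatrix")
  if (any(m@x < 0)) stop("matrix has negative entries")
  m@x <- as.numeric(m@x > 0)
  Matrix::drop0(m)
}
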