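#' Simulation configuration for coupled scRNA/scATAC toy datasets
#'
#' The generator plants a small genome (genes with promoter, exon, distal
#' and background peaks), cell types defined by marker genes whose peaks
#' are more often accessible, a binary peak-by-cell matrix, and RNA counts
#' whose per-type means are proportional to the regulatory potential of the
#' type's accessibility profile — the coupling the RP model assumes.
#'
#' @param n_genes Number of genes (default 100).
#' @param n_peaks Total peaks including background (default 600).
#' @param n_cell_types Number of planted cell types (default 4).
#' @param rna_cells_per_type,atac_cells_per_type Cells per type per
#'   modality (default 100 each).
#' @param markers_per_type Marker genes per cell type (default 10).
#' @param p_base Baseline peak accessibility probability (default 0.15).
#' @param p_background Accessibility of background peaks (default 0.05).
#' @param effect_size Accessibility fold-change of marker-gene peaks in
#'   their own cell type, capped so probabilities stay below 0.95
#'   (default 4; 1 removes all structure).
#' @param depth_factor_range Per-cell depth multipliers drawn uniformly
#'   from this range (default 0.8-1.2).
#' @param gene_baseline_range Per-gene accessibility scale drawn uniformly
#'   from this range (default 0.3-1.0), shared across cell types: genes
#'   differ in overall activity, as real genes do.
#' @param rna_depth Mean RNA library size (default 5000).
#' @param dispersion Negative-binomial dispersion of RNA counts
#'   (default 0.2).
#' @param seed Mandatory random seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 100, n_peaks = 600, n_cell_types = 4,
                       rna_cells_per_type = 100, atac_cells_per_type = 100,
                       markers_per_type = 10, p_base = 0.15,
                       p_background = 0.05, effect_size = 4,
                       depth_factor_range = c(0.8, 1.2),
                       gene_baseline_range = c(0.3, 1.0), rna_depth = 5000,
                       dispersion = 0.2, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (effect_size < 1) stop("effect_size must be >= 1")
  if (n_genes < n_cell_types * markers_per_type) {
    stop("need at least n_cell_types * markers_per_type genes")
  }
  structure(list(n_genes = n_genes, n_peaks = n_peaks,
                 n_cell_types = n_cell_types,
                 rna_cells_per_type = rna_cells_per_type,
                 atac_cells_per_type = atac_cells_per_type,
                 markers_per_type = markers_per_type, p_base = p_base,
                 p_background = p_background, effect_size = effect_size,
                 depth_factor_range = depth_factor_range,
                 gene_baseline_range = gene_baseline_range,
                 rna_depth = rna_depth, dispersion = dispersion,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a toy genome: gene models, peaks and peak-to-gene truth
#'
#' Genes are tiled on one synthetic chromosome (10 kb bodies every 400 kb,
#' alternating strand, three exons each). Every gene gets one promoter
#' peak centered on its TSS, one exonic peak, and 1-5 distal peaks
#' 20-140 kb upstream; the remaining peaks are background placed more than
#' 150 kb from every TSS.
#'
#' @param config A [sim_config()].
#' @return List with `genes` (a `gene_models` object), `peaks` (interval
#'   data frame) and `truth` (data frame `peak_id`, `gene_id`, `class`).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  ng <- config$n_genes
  spacing <- 400000
  body_len <- 10000
  body_start <- 200000 + (seq_len(ng) - 1) * spacing
  strand <- rep(c("+", "-"), length.out = ng)
  gene_id <- sprintf("gene%03d", seq_len(ng))

  exon_off <- list(c(0, 1000), c(4000, 5500), c(8500, 10000))
  exons <- do.call(rbind, lapply(seq_len(ng), function(i) {
    do.call(rbind, lapply(exon_off, function(e) {
      data.frame(gene_id = gene_id[i], chrom = "chrS",
                 start = body_start[i] + e[1], end = body_start[i] + e[2],
                 stringsAsFactors = FALSE)
    }))
  }))
  genes_df <- data.frame(gene_id = gene_id, gene_name = gene_id,
                         chrom = "chrS", start = body_start,
                         end = body_start + body_len, strand = strand,
                         stringsAsFactors = FALSE)
  models <- finish_gene_models(genes_df, exons)
  models$promoter_flank <- 2000
  class(models) <- "gene_models"
  tss <- models$genes$tss

  peak <- function(start, end, gene, class) {
    data.frame(chrom = "chrS", start = start, end = end, gene_id = gene,
               class = class, stringsAsFactors = FALSE)
  }
  plist <- list()
  for (i in seq_len(ng)) {
    plist[[length(plist) + 1]] <- peak(tss[i] - 250, tss[i] + 250,
                                       gene_id[i], "promoter")
    # inside the middle exon, clear of the promoter window
    plist[[length(plist) + 1]] <- peak(body_start[i] + 4100,
                                       body_start[i] + 4600,
                                       gene_id[i], "exon")
    n_distal <- sample(1:5, 1)
    if (n_distal > 0) {
      d <- sample(seq(20000, 140000, by = 500), n_distal)
      up <- if (strand[i] == "+") tss[i] - d else tss[i] + d
      for (s in up) {
        plist[[length(plist) + 1]] <- peak(s - 250, s + 250,
                                           gene_id[i], "distal")
      }
    }
  }
  gene_peaks <- do.call(rbind, plist)
  n_bg <- config$n_peaks - nrow(gene_peaks)
  if (n_bg < 0) {
    stop("n_peaks too small: ", nrow(gene_peaks),
         " gene-linked peaks already required")
  }
  # background slots live > 150 kb from the two flanking TSSs
  slots <- unlist(lapply(seq_len(ng), function(i) {
    zone_lo <- max(tss[i], body_start[i] + body_len) + 155000
    zone_hi <- body_start[i] + spacing - 160000
    seq(zone_lo, zone_hi, by = 1000)
  }))
  if (n_bg > length(slots)) stop("not enough background slots for n_peaks")
  bg_start <- sort(sample(slots, n_bg))
  bg <- peak(bg_start, bg_start + 500, NA_character_, "background")
  all_peaks <- rbind(gene_peaks, bg)
  all_peaks <- all_peaks[order(all_peaks$start), ]
  peaks <- genomic_intervals(all_peaks$chrom, all_peaks$start, all_peaks$end)
  truth <- data.frame(peak_id = interval_ids(peaks),
                      gene_id = all_peaks$gene_id, class = all_peaks$class,
                      stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(genes = models, peaks = peaks, truth = truth)
}

#' Simulate coupled RNA counts and binary ATAC accessibility
#'
#' Per cell type, the peaks of the type's marker genes are accessible with
#' probability `min(0.95, effect_size * p_base)`, other gene-linked peaks
#' with `p_base`, background with `p_background`; Bernoulli draws are
#' scaled by a per-cell depth factor. RNA means per gene are proportional
#' to the regulatory potential (simple decay model) of the cell type's
#' expected accessibility profile, and counts are negative binomial.
#'
#' @param config A [sim_config()].
#' @param genome Output of [simulate_genome()].
#' @return List: `rna_counts` (genes x RNA cells), `atac_binary` (peaks x
#'   ATAC cells), `rna_labels`, `atac_labels` (named cell-type vectors),
#'   `signatures` (marker list), `marker_genes` (per-type list), and
#'   `open_prob` (peaks x types expected accessibility).
#' @export
simulate_cells <- function(config, genome) {
  set.seed(config$seed + 1L)
  nt <- config$n_cell_types
  types <- paste0("type", seq_len(nt))
  gene_id <- genome$genes$genes$gene_id
  markers <- lapply(seq_len(nt), function(t) {
    gene_id[seq((t - 1) * config$markers_per_type + 1,
                t * config$markers_per_type)]
  })
  names(markers) <- types

  baseline <- stats::setNames(
    stats::runif(length(gene_id), config$gene_baseline_range[1],
                 config$gene_baseline_range[2]), gene_id)
  open_prob <- vapply(types, function(tp) {
    p <- rep(config$p_background, nrow(genome$truth))
    linked <- !is.na(genome$truth$gene_id)
    p[linked] <- config$p_base * baseline[genome$truth$gene_id[linked]]
    # promoters are constitutively more accessible than distal elements
    prom <- genome$truth$class %in% "promoter"
    p[prom] <- pmin(0.95, 2 * p[prom])
    hot <- linked & genome$truth$gene_id %in% markers[[tp]]
    p[hot] <- pmin(0.95, config$effect_size * config$p_base *
                     ifelse(prom[hot], 2, 1))
    p
  }, numeric(nrow(genome$truth)))
  rownames(open_prob) <- genome$truth$peak_id

  # ATAC cells
  na <- config$atac_cells_per_type
  atac_bc <- as.vector(vapply(types, function(tp) {
    sprintf("ATAC_%s_c%03d", tp, seq_len(na))
  }, character(na)))
  atac_type <- rep(types, each = na)
  depth_a <- stats::runif(length(atac_bc), config$depth_factor_range[1],
                          config$depth_factor_range[2])
  B <- vapply(seq_along(atac_bc), function(j) {
    p <- pmin(0.95, open_prob[, atac_type[j]] * depth_a[j])
    stats::rbinom(nrow(open_prob), 1, p)
  }, numeric(nrow(open_prob)))
  dimnames(B) <- list(genome$truth$peak_id, atac_bc)
  B <- methods::as(Matrix::Matrix(B, sparse = TRUE), "CsparseMatrix")

  # RNA cells: means proportional to the planted regulatory potential
  W <- build_weight_matrix(genome$peaks, genome$genes,
                           rp_config(model = "simple"))
  planted_rp <- as.matrix(Matrix::t(W) %*% open_prob)
  nr <- config$rna_cells_per_type
  rna_bc <- as.vector(vapply(types, function(tp) {
    sprintf("RNA_%s_c%03d", tp, seq_len(nr))
  }, character(nr)))
  rna_type <- rep(types, each = nr)
  depth_r <- stats::runif(length(rna_bc), config$depth_factor_range[1],
                          config$depth_factor_range[2])
  X <- vapply(seq_along(rna_bc), function(j) {
    mu <- planted_rp[, rna_type[j]]
    mu <- config$rna_depth * depth_r[j] * mu / sum(mu)
    stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
  }, numeric(nrow(planted_rp)))
  dimnames(X) <- list(gene_id, rna_bc)
  X <- methods::as(Matrix::Matrix(X, sparse = TRUE), "CsparseMatrix")

  list(rna_counts = X, atac_binary = B,
       rna_labels = stats::setNames(rna_type, rna_bc),
       atac_labels = stats::setNames(atac_type, atac_bc),
       signatures = markers, marker_genes = markers,
       open_prob = open_prob, planted_rp = planted_rp)
}

#' Simulate a fragments file with planted low-quality barcodes
#'
#' Each ATAC cell emits 1-3 fragments inside every open peak, with
#' duplicate counts scaled so good barcodes total roughly 2500 reads,
#' comfortably above the read-depth threshold at any genome size. Three kinds of bad barcodes are appended: too few
#' reads, too small a promoter fraction (fragments only in background
#' peaks), and too many mitochondrial (chrM) reads.
#'
#' @param config A [sim_config()].
#' @param atac_binary Binary peaks x cells matrix from [simulate_cells()].
#' @param genome Output of [simulate_genome()].
#' @param n_bad Number of planted bad barcodes per failure mode
#'   (default 5).
#' @return List: `fragments` (data frame), `manifest` (data frame
#'   `barcode`, `fate` in good/low_count/low_promoter/high_mito).
#' @export
simulate_fragments <- function(config, atac_binary, genome, n_bad = 5) {
  set.seed(config$seed + 2L)
  peaks <- genome$peaks
  peak_id <- interval_ids(peaks)
  stopifnot(identical(rownames(atac_binary), peak_id))
  frag_in_peak <- function(idx, n) {
    s <- floor(stats::runif(n, peaks$start[idx], peaks$end[idx] - 60))
    data.frame(chrom = peaks$chrom[idx], start = s, end = s + 60,
               stringsAsFactors = FALSE)
  }
  out <- list()
  target_reads <- 2500  # good barcodes aim well above the 1000-read cutoff
  for (j in seq_len(ncol(atac_binary))) {
    open <- which(atac_binary[, j] > 0)
    nf <- sample(1:3, length(open), replace = TRUE)
    idx <- rep(open, nf)
    f <- frag_in_peak(idx, length(idx))
    f$barcode <- colnames(atac_binary)[j]
    base_count <- max(2, ceiling(target_reads / max(1, length(idx))))
    f$count <- base_count + sample(0:3, nrow(f), replace = TRUE)
    out[[j]] <- f
  }
  bg_peaks <- which(is.na(genome$truth$gene_id))
  bad <- list()
  if (n_bad > 0) {
    for (b in seq_len(n_bad)) {
      # too few reads
      idx <- sample(seq_len(nrow(peaks)), 30, replace = TRUE)
      f <- frag_in_peak(idx, length(idx))
      f$barcode <- sprintf("BAD_lowcount_%02d", b)
      f$count <- sample(3:5, nrow(f), replace = TRUE)
      bad[[length(bad) + 1]] <- f
      # promoter-poor: background peaks only
      idx <- sample(bg_peaks, 150, replace = TRUE)
      f <- frag_in_peak(idx, length(idx))
      f$barcode <- sprintf("BAD_lowprom_%02d", b)
      f$count <- sample(15:20, nrow(f), replace = TRUE)
      bad[[length(bad) + 1]] <- f
      # mitochondrial: half the reads on chrM
      idx <- sample(seq_len(nrow(peaks)), 75, replace = TRUE)
      f <- frag_in_peak(idx, length(idx))
      f$barcode <- sprintf("BAD_mito_%02d", b)
      f$count <- sample(15:20, nrow(f), replace = TRUE)
      s <- floor(stats::runif(75, 0, 16000))
      fm <- data.frame(chrom = "chrM", start = s, end = s + 60,
                       barcode = f$barcode[1],
                       count = sample(15:20, 75, replace = TRUE),
                       stringsAsFactors = FALSE)
      bad[[length(bad) + 1]] <- rbind(f, fm)
    }
  }
  fragments <- do.call(rbind, c(out, bad))
  rownames(fragments) <- NULL
  manifest <- rbind(
    data.frame(barcode = colnames(atac_binary), fate = "good",
               stringsAsFactors = FALSE),
    if (n_bad > 0) data.frame(
      barcode = c(sprintf("BAD_lowcount_%02d", seq_len(n_bad)),
                  sprintf("BAD_lowprom_%02d", seq_len(n_bad)),
                  sprintf("BAD_mito_%02d", seq_len(n_bad))),
      fate = rep(c("low_count", "low_promoter", "high_mito"), each = n_bad),
      stringsAsFactors = FALSE)
  )
  list(fragments = fragments, manifest = manifest)
}

#' Simulate reference regulator peak sets
#'
#' One planted regulator per cell type whose reference peaks coincide with
#' the peaks of that type's marker genes, plus decoy regulators drawn from
#' background peaks; used to exercise peak-set enrichment end to end.
#'
#' @param genome Output of [simulate_genome()].
#' @param cells Output of [simulate_cells()] (for the marker gene lists).
#' @param n_decoys Number of decoy regulators (default 6).
#' @param seed Random seed (default 1).
#' @return Named list regulator -> interval data frame. Planted regulators
#'   are named `TF_<type>`.
#' @export
simulate_reference_sets <- function(genome, cells, n_decoys = 6, seed = 1) {
  set.seed(seed)
  sets <- list()
  for (tp in names(cells$marker_genes)) {
    sel <- genome$truth$gene_id %in% cells$marker_genes[[tp]]
    sets[[paste0("TF_", tp)]] <- genome$peaks[sel, , drop = FALSE]
  }
  bg <- which(is.na(genome$truth$gene_id))
  for (d in seq_len(n_decoys)) {
    sel <- sample(bg, max(3, length(bg) %/% 3))
    sets[[sprintf("decoy%02d", d)]] <- genome$peaks[sort(sel), , drop = FALSE]
  }
  sets
}

#' Simulate position weight matrices with planted families
#'
#' Generates sharp random base motifs and, for some, jittered variants
#' that stay within the same motif family (pairwise similarity above the
#' clustering threshold).
#'
#' @param n_families Number of base motifs (default 4).
#' @param variants_per_family Extra jittered copies per family
#'   (default 1).
#' @param motif_length Motif length (default 8).
#' @param seed Random seed (default 1).
#' @return List of `pwm` objects named `M<f>_<v>`.
#' @export
simulate_pwms <- function(n_families = 4, variants_per_family = 1,
                          motif_length = 8, seed = 1) {
  set.seed(seed)
  draw_base <- function() {
    vapply(seq_len(motif_length), function(i) {
      p <- rep(0.04, 4)
      p[sample(4, 1)] <- 0.88
      p
    }, numeric(4))
  }
  # rejection sampling keeps planted families well separated, so the
  # similarity threshold can actually recover them
  bases <- list()
  tries <- 0
  while (length(bases) < n_families && tries < 1000) {
    tries <- tries + 1
    cand <- pwm("cand", draw_base())
    sep <- all(vapply(bases, function(b) {
      pwm_similarity(cand, b) < 0.5
    }, logical(1)))
    if (sep) bases[[length(bases) + 1]] <- cand
  }
  if (length(bases) < n_families) stop("could not draw separated motifs")
  out <- list()
  for (f in seq_len(n_families)) {
    base <- bases[[f]]$probs
    out[[length(out) + 1]] <- pwm(sprintf("M%d_1", f), base)
    for (v in seq_len(variants_per_family)) {
      jit <- base + matrix(stats::runif(4 * motif_length, 0, 0.05), 4)
      jit <- sweep(jit, 2, colSums(jit), "/")
      out[[length(out) + 1]] <- pwm(sprintf("M%d_%d", f, v + 1), jit)
    }
  }
  out
}
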