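default_run_config <- function() {
  list(
    inputs = list(genes = NULL, peaks = NULL, rna_counts = NULL,
                  atac_counts = NULL, fragments = NULL, signatures = NULL,
                  reference_sets = NULL),
    qc = list(
      rna = list(min_reads = 1000, min_features = 500, max_frac_mito = 0.05,
                 max_frac_spikein = 0.05),
      atac = list(min_reads = 1000, min_frac_promoter = 0.10,
                  max_frac_mito = 0.10)
    ),
    rp = list(d0 = 10000, distance_cutoff = 150000, model = "enhanced",
              exon_length_scale = 1000, promoter_flank = 2000),
    cluster = list(
      rna = list(k = 15, n_variable_genes = 2000, n_neighbors = 20,
                 resolution = 0.6, seed = 2020),
      atac = list(k = 50, n_neighbors = 20, resolution = 0.6, seed = 2020)
    ),
    diff = list(
      genes = list(min_logfc = 0.25, min_pct = 0.25, max_p = 1e-5),
      peaks = list(min_logfc = 0.1, min_pct = 0.01, max_p = 1e-5)
    ),
    regulators = list(top_n = 100, motif_threshold = 0.7, min_rp = 0.5),
    integrate = list(k = 20, k_anchor = 5, k_weight = 10,
                     prediction_cutoff = 0.5)
  )
}

merge_config <- function(base, user, path = "") {
  for (k in names(user)) {
    if (!k %in% names(base)) {
      stop("unknown configuration key: ", paste0(path, k))
    }
    if (is.list(base[[k]]) && is.list(user[[k]])) {
      base[[k]] <- merge_config(base[[k]], user[[k]], paste0(path, k, "."))
    } else {
      base[k] <- list(user[[k]])  # single-bracket form keeps NULL values
    }
  }
  base
}

#' Read (or build) a run configuration
#'
#' Unknown keys are rejected; every omitted value falls back to the
#' workflow default documented in the corresponding function.
#'
#' @param path Optional YAML file of overrides.
#' @param overrides Optional named list of overrides (applied after the
#'   file).
#' @return A complete `run_config` list.
#' @export
read_run_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) cfg <- merge_config(cfg, yaml::read_yaml(path))
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  structure(cfg, class = "run_config")
}

#' Serialize a run configuration to YAML
#' @param config A `run_config`.
#' @param path Output path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

need_input <- function(config, key, stage) {
  p <- config$inputs[[key]]
  if (is.null(p) || !file.exists(p)) {
    stop(sprintf("stage '%s' requires input '%s' (%s)", stage, key,
                 if (is.null(p)) "not configured" else p))
  }
  p
}

#' Run the workflow end to end (or a subset of stages)
#'
#' A linear in-process runner over the package's functions: QC, gene
#' activity modeling, per-modality clustering, marker detection,
#' annotation, regulator inference, label transfer and evaluation. Each
#' stage writes plain-text artifacts into `out_dir` and logs its
#' parameters; a `report.txt` summarizes cell counts before/after QC,
#' cluster sizes, annotations and top regulators.
#'
#' @param config A `run_config` from [read_run_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of
#'   `c("qc", "rp", "cluster_rna", "cluster_atac", "markers", "annotate",
#'      "regulators", "integrate", "evaluate")`.
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("qc", "rp", "cluster_rna",
                                    "cluster_atac", "markers", "annotate",
                                    "regulators", "integrate", "evaluate")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  report <- c("workflow summary", "================")
  tsv <- function(x, name) {
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  genes <- NULL
  load_genes <- function() {
    if (is.null(genes)) {
      genes <<- read_gene_models(need_input(config, "genes", "rp"),
                                 promoter_flank = config$rp$promoter_flank)
    }
    genes
  }
  rna <- NULL
  load_rna <- function() {
    if (is.null(rna)) {
      rna <<- read_matrix(need_input(config, "rna_counts", "qc"))
    }
    rna
  }
  atac <- NULL
  load_atac <- function() {
    if (is.null(atac)) {
      atac <<- binarize(read_matrix(need_input(config, "atac_counts", "qc")))
    }
    atac
  }

  if ("qc" %in% stages) {
    stage_log("qc", "computing barcode metrics and filtering")
    rna_m <- rna_cell_metrics(load_rna())
    rth <- do.call(qc_thresholds, c(list(modality = "rna"), config$qc$rna))
    rna_pass <- filter_cells(rna_m, rth)
    tsv(rna_m, "rna_metrics.tsv")
    writeLines(rna_pass, file.path(out_dir, "rna_barcodes.txt"))
    report <- c(report, sprintf("RNA barcodes: %d before QC, %d after",
                                nrow(rna_m), length(rna_pass)))
    atac_pass <- NULL
    if (!is.null(config$inputs$fragments)) {
      frags <- read_fragments(need_input(config, "fragments", "qc"))
      atac_m <- atac_cell_metrics(frags, load_genes())
      ath <- do.call(qc_thresholds, c(list(modality = "atac"),
                                      config$qc$atac))
      atac_pass <- filter_cells(atac_m, ath)
      tsv(atac_m, "atac_metrics.tsv")
      writeLines(atac_pass, file.path(out_dir, "atac_barcodes.txt"))
      report <- c(report, sprintf("ATAC barcodes: %d before QC, %d after",
                                  nrow(atac_m), length(atac_pass)))
    }
    res$qc <- list(rna_pass = rna_pass, atac_pass = atac_pass)
    rna <- rna[, colnames(rna) %in% rna_pass, drop = FALSE]
    if (!is.null(res$qc$atac_pass)) {
      keep <- colnames(load_atac()) %in% res$qc$atac_pass
      if (any(keep)) atac <- atac[, keep, drop = FALSE]
    }
  }

  if (any(c("rp", "cluster_atac", "annotate", "regulators", "integrate",
            "evaluate") %in% stages)) {
    stage_log("rp", sprintf("building %s RP model (d0=%d, cutoff=%d)",
                            config$rp$model, config$rp$d0,
                            config$rp$distance_cutoff))
    peaks <- read_peaks(need_input(config, "peaks", "rp"))
    rpc <- rp_config(d0 = config$rp$d0,
                     distance_cutoff = config$rp$distance_cutoff,
                     model = config$rp$model,
                     exon_length_scale = config$rp$exon_length_scale,
                     promoter_flank = config$rp$promoter_flank)
    W <- build_weight_matrix(peaks, load_genes(), rpc)
    activity <- regulatory_potential(W, load_atac())
    if ("rp" %in% stages) {
      write_matrix(activity, file.path(out_dir, "activity.mtx"))
    }
    res$rp <- list(W = W, activity = activity, peaks = peaks)
  }

  if ("cluster_rna" %in% stages) {
    cc <- config$cluster$rna
    stage_log("cluster_rna", sprintf("PCA k=%d, resolution=%.2f", cc$k,
                                     cc$resolution))
    normed <- normalize_log(load_rna())
    hvg <- select_variable_genes(normed, min(cc$n_variable_genes,
                                             nrow(normed) - 1))
    emb <- pca_embed(normed, hvg, k = cc$k)
    lab <- cluster_cells(emb, cc$n_neighbors, cc$resolution, seed = cc$seed)
    tsv(data.frame(barcode = names(lab), cluster = lab), "rna_clusters.tsv")
    report <- c(report, paste("RNA cluster sizes:",
                              paste(table(lab), collapse = ", ")))
    res$cluster_rna <- list(normed = normed, hvg = hvg, emb = emb,
                            labels = lab)
  }

  if ("cluster_atac" %in% stages) {
    cc <- config$cluster$atac
    stage_log("cluster_atac", sprintf("LSI k=%d, resolution=%.2f", cc$k,
                                      cc$resolution))
    emb <- lsi_embed(load_atac(), k = min(cc$k, min(dim(load_atac())) - 1))
    lab <- cluster_cells(emb, cc$n_neighbors, cc$resolution, seed = cc$seed)
    tsv(data.frame(barcode = names(lab), cluster = lab), "atac_clusters.tsv")
    report <- c(report, paste("ATAC cluster sizes:",
                              paste(table(lab), collapse = ", ")))
    res$cluster_atac <- list(emb = emb, labels = lab)
  }

  if ("markers" %in% stages && !is.null(res$cluster_rna)) {
    stage_log("markers", "Wilcoxon one-vs-rest tests")
    mk <- wilcoxon_markers(res$cluster_rna$normed, res$cluster_rna$labels,
                           config$diff$genes)
    tsv(mk, "rna_markers.tsv")
    res$markers <- list(rna = mk)
    if (!is.null(res$cluster_atac)) {
      # depth-normalized values rescaled to a typical cell's peak count so
      # the logFC threshold acts on an interpretable scale
      pd <- normalize_peak_depth(load_atac()) *
        stats::median(Matrix::colSums(load_atac()))
      pk <- wilcoxon_markers(pd, res$cluster_atac$labels,
                             config$diff$peaks, delogged = TRUE)
      tsv(pk, "atac_peak_markers.tsv")
      res$markers$atac_peaks <- pk
    }
  }

  signatures <- NULL
  if (any(c("annotate", "integrate", "evaluate") %in% stages) &&
      !is.null(config$inputs$signatures)) {
    signatures <- read_signatures(need_input(config, "signatures",
                                             "annotate"))
  }

  if ("annotate" %in% stages && !is.null(signatures)) {
    stage_log("annotate", "signature scoring of clusters")
    if (!is.null(res$cluster_rna)) {
      ann <- annotate_clusters(res$cluster_rna$normed,
                               res$cluster_rna$labels, signatures)
      tsv(ann, "rna_annotations.tsv")
      res$annotate$rna <- ann
      report <- c(report, paste("RNA annotations:",
                                paste(ann$cell_type, collapse = ", ")))
    }
    if (!is.null(res$cluster_atac) && !is.null(res$rp)) {
      act_norm <- normalize_log(res$rp$activity)
      ann <- annotate_clusters(act_norm, res$cluster_atac$labels, signatures)
      tsv(ann, "atac_annotations.tsv")
      res$annotate$atac <- ann
      report <- c(report, paste("ATAC annotations:",
                                paste(ann$cell_type, collapse = ", ")))
    }
  }

  if ("regulators" %in% stages && !is.null(config$inputs$reference_sets) &&
      !is.null(res$markers$atac_peaks) && !is.null(res$rp)) {
    stage_log("regulators", "peak-set enrichment per ATAC cluster")
    ref_dir <- need_input(config, "reference_sets", "regulators")
    beds <- list.files(ref_dir, pattern = "\\.bed$", full.names = TRUE)
    refs <- lapply(beds, read_peaks)
    names(refs) <- sub("\\.bed$", "", basename(beds))
    pk <- res$markers$atac_peaks
    univ_ids <- interval_ids(res$rp$peaks)
    for (cl in unique(pk$cluster)) {
      cl_peaks <- res$rp$peaks[univ_ids %in% pk$feature[pk$cluster == cl], ,
                               drop = FALSE]
      enr <- peakset_enrichment(cl_peaks, res$rp$peaks, refs, cluster = cl)
      enr <- utils::head(enr, config$regulators$top_n)
      tsv(enr, sprintf("regulators_cluster%s.tsv", cl))
      res$regulators[[as.character(cl)]] <- enr
      report <- c(report, sprintf(
        "cluster %s top regulators: %s", cl,
        paste(utils::head(enr$regulator, 10), collapse = ", ")))
    }
  }

  if (any(c("integrate", "evaluate") %in% stages) &&
      !is.null(res$cluster_rna) && !is.null(res$rp)) {
    ic <- config$integrate
    stage_log("integrate", sprintf("CCA k=%d, %d anchors searched", ic$k,
                                   ic$k_anchor))
    act_norm <- normalize_log(res$rp$activity)
    hvg <- res$cluster_rna$hvg
    emb <- cca_embed(res$cluster_rna$normed[hvg, , drop = FALSE],
                     act_norm[intersect(hvg, rownames(act_norm)), ,
                              drop = FALSE], k = ic$k)
    anchors <- find_anchors(emb, ic$k_anchor)
    rna_ann <- res$annotate$rna
    rna_lab <- if (!is.null(rna_ann)) {
      stats::setNames(
        rna_ann$cell_type[match(res$cluster_rna$labels, rna_ann$cluster)],
        names(res$cluster_rna$labels))
    } else res$cluster_rna$labels
    transfer <- transfer_labels(anchors, rna_lab, emb, ic$k_weight)
    tsv(transfer, "transfer.tsv")
    res$integrate <- list(emb = emb, anchors = anchors, transfer = transfer,
                          rna_labels = rna_lab)
    hi <- mean(transfer$max_score > ic$prediction_cutoff)
    report <- c(report, sprintf(
      "label transfer: %d anchors, %.1f%% cells above %.2f prediction score",
      nrow(anchors), 100 * hi, ic$prediction_cutoff))
  }

  if ("evaluate" %in% stages && !is.null(res$integrate)) {
    stage_log("evaluate", "integration consistency metrics")
    transfer <- res$integrate$transfer
    atac_lab <- stats::setNames(transfer$predicted_label, transfer$barcode)
    rho <- tryCatch(
      expression_activity_correlation(
        res$cluster_rna$normed, normalize_log(res$rp$activity),
        res$integrate$rna_labels, atac_lab),
      error = function(e) NULL)
    metrics <- data.frame(
      metric = c("fraction_high_quality_prediction",
                 if (!is.null(rho)) paste0("spearman_", names(rho))),
      value = c(mean(transfer$max_score > config$integrate$prediction_cutoff),
                if (!is.null(rho)) as.numeric(rho)))
    tsv(metrics, "metrics.tsv")
    res$evaluate <- metrics
  }

  writeLines(report, file.path(out_dir, "report.txt"))
  invisible(res)
}
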