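#' Read gene models from GTF or BED12
#'
#' Parses gene annotations into strand-aware gene models: one record per
#' `gene_id` with its genomic span, transcription start site (TSS), merged
#' exons and total merged exon length. GTF input (1-based, inclusive) is
#' converted to the package-internal 0-based half-open convention; BED12 is
#' already 0-based. The TSS is the 0-based position of the first transcribed
#' base: `start` for `+` genes and `end - 1` for `-` genes.
#'
#' Only one TSS per gene is kept (the annotated gene start); isoform-level
#' alternative TSSs are not modeled.
#'
#' @param path Path to a `.gtf`/`.gff` or 12-column `.bed` file.
#' @param promoter_flank Promoter half-width in bp; the promoter window is
#'   `TSS - promoter_flank` to `TSS + promoter_flank`. Default 2000 bp
#'   (2 kb up/downstream of the TSS).
#' @return An object of class `gene_models`: a list with
#'   \describe{
#'     \item{genes}{data frame: `gene_id`, `gene_name`, `chrom`, `start`,
#'       `end`, `strand`, `tss`, `total_exon_length`.}
#'     \item{exons}{data frame of merged exon intervals with `gene_id`.}
#'     \item{promoter_flank}{the flank used for promoter windows.}
#'   }
#' @export
read_gene_models <- function(path, promoter_flank = 2000) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gtf", "gff")) {
    models <- read_gene_models_gtf(path)
  } else if (ext == "bed") {
    models <- read_gene_models_bed12(path)
  } else {
    stop("unsupported gene annotation format: ", ext)
  }
  models$promoter_flank <- promoter_flank
  class(models) <- "gene_models"
  models
}

read_gene_models_gtf <- function(path) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield < 9)) {
    bad <- which(body)[which(nfield < 9)[1]]
    stop(sprintf("malformed GTF line %d: expected 9 tab-separated fields", bad))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  if (is.null(gr$gene_id)) stop("GTF lacks gene_id attributes")
  exon <- gr[gr$type == "exon"]
  if (length(exon) == 0) stop("GTF contains no exon records")
  gene_rows <- gr[gr$type == "gene"]

  exon_df <- data.frame(
    gene_id = as.character(exon$gene_id),
    chrom = as.character(GenomicRanges::seqnames(exon)),
    start = GenomicRanges::start(exon) - 1,
    end = as.numeric(GenomicRanges::end(exon)),
    stringsAsFactors = FALSE
  )
  ids <- unique(if (length(gene_rows)) as.character(gene_rows$gene_id)
                else exon_df$gene_id)
  missing_exons <- setdiff(ids, unique(exon_df$gene_id))
  if (length(missing_exons)) {
    stop("gene(s) with no exons: ", paste(missing_exons, collapse = ", "))
  }

  # gene span from the 'gene' record when present, else the exon range
  span <- lapply(ids, function(id) {
    g <- gene_rows[as.character(gene_rows$gene_id) == id]
    if (length(g) == 0) {
      e <- exon_df[exon_df$gene_id == id, ]
      ex <- exon[as.character(exon$gene_id) == id]
      list(chrom = e$chrom[1], start = min(e$start), end = max(e$end),
           strand = as.character(GenomicRanges::strand(ex))[1],
           name = if (!is.null(ex$gene_name)) as.character(ex$gene_name)[1] else id)
    } else {
      list(chrom = as.character(GenomicRanges::seqnames(g))[1],
           start = GenomicRanges::start(g)[1] - 1,
           end = as.numeric(GenomicRanges::end(g)[1]),
           strand = as.character(GenomicRanges::strand(g))[1],
           name = if (!is.null(g$gene_name)) as.character(g$gene_name)[1] else id)
    }
  })
  genes <- data.frame(
    gene_id = ids,
    gene_name = vapply(span, `[[`, "", "name"),
    chrom = vapply(span, `[[`, "", "chrom"),
    start = vapply(span, `[[`, 0, "start"),
    end = vapply(span, `[[`, 0, "end"),
    strand = vapply(span, `[[`, "", "strand"),
    stringsAsFactors = FALSE
  )
  finish_gene_models(genes, exon_df)
}

read_gene_models_bed12 <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 12) stop("BED12 gene annotation requires 12 columns")
  genes <- data.frame(
    gene_id = as.character(tab[[4]]),
    gene_name = as.character(tab[[4]]),
    chrom = as.character(tab[[1]]),
    start = as.numeric(tab[[2]]),
    end = as.numeric(tab[[3]]),
    strand = as.character(tab[[6]]),
    stringsAsFactors = FALSE
  )
  exon_df <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    n <- as.integer(tab[i, 10])
    sizes <- as.numeric(strsplit(as.character(tab[i, 11]), ",")[[1]][seq_len(n)])
    offs <- as.numeric(strsplit(as.character(tab[i, 12]), ",")[[1]][seq_len(n)])
    if (anyNA(sizes) || anyNA(offs)) {
      stop(sprintf("malformed BED12 line %d: bad block fields", i))
    }
    data.frame(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
               start = genes$start[i] + offs,
               end = genes$start[i] + offs + sizes,
               stringsAsFactors = FALSE)
  }))
  finish_gene_models(genes, exon_df)
}

# Shared tail of the gene-model readers: strand-aware TSS, exon merging,
# total merged exon length.
finish_gene_models <- function(genes, exon_df) {
  if (any(!genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-': ",
         paste(genes$gene_id[!genes$strand %in% c("+", "-")], collapse = ", "))
  }
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)

  gr <- as_granges(exon_df)
  grl <- S4Vectors::split(gr, factor(exon_df$gene_id, levels = genes$gene_id))
  red <- GenomicRanges::reduce(grl)
  flat <- unlist(red)
  merged <- data.frame(
    gene_id = rep(names(red), lengths(red)),
    chrom = as.character(GenomicRanges::seqnames(flat)),
    start = GenomicRanges::start(flat) - 1,
    end = as.numeric(GenomicRanges::end(flat)),
    stringsAsFactors = FALSE
  )
  rownames(merged) <- NULL
  tot <- stats::setNames(as.numeric(sum(IRanges::width(red))), names(red))
  genes$total_exon_length <- tot[genes$gene_id]
  genes$total_exon_length <- unname(genes$total_exon_length)
  if (any(genes$total_exon_length <= 0)) {
    stop("gene(s) with zero exon length: ",
         paste(genes$gene_id[genes$total_exon_length <= 0], collapse = ", "))
  }
  list(genes = genes, exons = merged)
}

#' Promoter windows of gene models
#'
#' @param models A `gene_models` object.
#' @param flank Promoter half-width in bp; defaults to the flank stored in
#'   `models`.
#' @return Interval data frame (one window per gene, `TSS +/- flank`,
#'   clipped at 0) with a `gene_id` column.
#' @export
promoter_windows <- function(models, flank = models$promoter_flank) {
  g <- models$genes
  out <- genomic_intervals(g$chrom, pmax(0, g$tss - flank), g$tss + flank,
                           g$strand)
  out$gene_id <- g$gene_id
  out
}

#' Read peak intervals from a BED file
#'
#' @param path Path to a BED3+ file (0-based half-open).
#' @return Interval data frame in file order; zero rows for an empty file.
#' @export
read_peaks <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0) return(genomic_intervals(character(0), numeric(0), numeric(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("malformed BED line %d: fewer than 3 fields", which(nf < 3)[1]))
  }
  starts <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  ends <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  if (anyNA(starts) || anyNA(ends)) {
    stop(sprintf("malformed BED line %d: non-numeric coordinates",
                 which(is.na(starts) | is.na(ends))[1]))
  }
  if (any(starts >= ends)) {
    stop(sprintf("BED line %d has start >= end", which(starts >= ends)[1]))
  }
  gr <- rtracklayer::import(path, format = "bed")
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  genomic_intervals(as.character(GenomicRanges::seqnames(gr)),
                    GenomicRanges::start(gr) - 1,
                    as.numeric(GenomicRanges::end(gr)),
                    strand)
}

#' Write peak intervals as BED
#' @param intervals Interval data frame.
#' @param path Output path.
#' @export
write_peaks <- function(intervals, path) {
  utils::write.table(
    data.frame(intervals$chrom, as.integer(intervals$start),
               as.integer(intervals$end)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a named matrix
#'
#' Reads either a MatrixMarket triplet file (`.mtx`) with sidecar row/column
#' name files (`.rows` / `.cols`, one name per line, replacing the `.mtx`
#' extension), or a dense TSV with row names in the first column and column
#' names in the header.
#'
#' @param path Path to a `.mtx` or `.tsv` file.
#' @return A sparse `dgCMatrix` with unique row and column names.
#' @export
read_matrix <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    m <- Matrix::readMM(path) * 1
    m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
    rows <- readLines(sub("\\.mtx$", ".rows", path, ignore.case = TRUE))
    cols <- readLines(sub("\\.mtx$", ".cols", path, ignore.case = TRUE))
    if (length(rows) != nrow(m) || length(cols) != ncol(m)) {
      stop(sprintf("name files (%d rows, %d cols) do not match matrix %d x %d",
                   length(rows), length(cols), nrow(m), ncol(m)))
    }
    dimnames(m) <- list(rows, cols)
  } else {
    tab <- utils::read.delim(path, header = TRUE, row.names = NULL,
                             check.names = FALSE, stringsAsFactors = FALSE)
    rows <- as.character(tab[[1]])
    m <- Matrix::Matrix(as.matrix(tab[, -1, drop = FALSE]),
                        sparse = TRUE, dimnames = list(rows, colnames(tab)[-1]))
    m <- methods::as(m, "CsparseMatrix")
  }
  if (anyDuplicated(rownames(m))) stop("duplicate row names in matrix")
  if (anyDuplicated(colnames(m))) stop("duplicate column names in matrix")
  m
}

#' Write a named matrix as MatrixMarket triplet plus name sidecars
#' @param m Matrix with row and column names.
#' @param path Output `.mtx` path; `.rows` and `.cols` sidecars are written
#'   alongside.
#' @export
write_matrix <- function(m, path) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("matrix must carry row and column names")
  }
  sp <- methods::as(Matrix::Matrix(m * 1, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(methods::as(sp, "generalMatrix"), path)
  writeLines(rownames(m), sub("\\.mtx$", ".rows", path, ignore.case = TRUE))
  writeLines(colnames(m), sub("\\.mtx$", ".cols", path, ignore.case = TRUE))
  invisible(path)
}

#' Read cell-type marker signatures
#'
#' @param path Two-column TSV (`cell_type`, `gene`), no header. Exact
#'   duplicate rows are dropped; a gene may appear under several cell types.
#' @return Named list mapping cell type to its ordered marker gene vector.
#' @export
read_signatures <- function(path) {
  tab <- tryCatch(
    utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("empty or unreadable signature file: ", path))
  if (nrow(tab) == 0) stop("empty signature file: ", path)
  if (ncol(tab) < 2) stop("signature file needs two columns (cell_type, gene)")
  tab <- tab[!duplicated(tab[, 1:2]), , drop = FALSE]
  split(as.character(tab[[2]]), factor(tab[[1]], levels = unique(tab[[1]])))
}

#' Write marker signatures as two-column TSV
#' @param signatures Named list of marker gene vectors.
#' @param path Output path.
#' @export
write_signatures <- function(signatures, path) {
  tab <- data.frame(cell_type = rep(names(signatures), lengths(signatures)),
                    gene = unlist(signatures, use.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a position weight matrix
#'
#' @param name Motif name.
#' @param probs 4 x L numeric matrix of per-position nucleotide
#'   probabilities (rows A, C, G, T); every column must sum to 1.
#' @return A `pwm` object.
#' @export
pwm <- function(name, probs) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4) stop("PWM must have 4 nucleotide rows")
  if (ncol(probs) < 4) stop("PWM must have at least 4 positions")
  if (any(probs < 0)) stop("PWM entries must be nonnegative")
  csum <- colSums(probs)
  if (any(abs(csum - 1) > 1e-6)) stop("PWM columns must each sum to 1")
  rownames(probs) <- c("A", "C", "G", "T")
  structure(list(name = name, probs = probs), class = "pwm")
}

#' Read position weight matrices
#'
#' The file holds one block per motif: a `>name` header line followed by L
#' rows of 4 whitespace-separated counts or frequencies (columns A, C, G,
#' T). Rows are normalized to probabilities.
#'
#' @param path Path to the motif file.
#' @return List of `pwm` objects.
#' @export
read_pwms <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  headers <- which(startsWith(lines, ">"))
  if (length(headers) == 0) stop("no '>' motif headers found in ", path)
  bounds <- c(headers, length(lines) + 1L)
  lapply(seq_along(headers), function(i) {
    name <- sub("^>\\s*", "", lines[headers[i]])
    block <- lines[seq(headers[i] + 1L, bounds[i + 1L] - 1L)]
    vals <- lapply(block, function(l) {
      v <- suppressWarnings(as.numeric(strsplit(l, "\\s+")[[1]]))
      if (length(v) != 4 || anyNA(v)) {
        stop("malformed PWM row for motif ", name, ": ", l)
      }
      if (any(v < 0)) stop("negative PWM entry for motif ", name)
      s <- sum(v)
      if (s == 0) stop("all-zero PWM row for motif ", name)
      v / s
    })
    pwm(name, t(do.call(rbind, vals)))
  })
}

#' Write position weight matrices
#' @param pwms List of `pwm` objects.
#' @param path Output path.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$name), con)
    utils::write.table(t(p$probs), con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write gene models as GTF
#'
#' Emits one `gene` and per-exon `exon` record per gene, converting the
#' internal 0-based half-open coordinates back to 1-based inclusive GTF.
#'
#' @param models A `gene_models` object.
#' @param path Output path.
#' @export
write_gene_models <- function(models, path) {
  g <- models$genes
  ex <- models$exons
  attr_of <- function(id, name) {
    sprintf("gene_id \"%s\"; gene_name \"%s\";", id, name)
  }
  gene_lines <- sprintf("%s\tscregpot\tgene\t%d\t%d\t.\t%s\t.\t%s",
                        g$chrom, as.integer(g$start) + 1L, as.integer(g$end),
                        g$strand, attr_of(g$gene_id, g$gene_name))
  idx <- match(ex$gene_id, g$gene_id)
  exon_lines <- sprintf("%s\tscregpot\texon\t%d\t%d\t.\t%s\t.\t%s",
                        ex$chrom, as.integer(ex$start) + 1L,
                        as.integer(ex$end), g$strand[idx],
                        attr_of(ex$gene_id, g$gene_name[idx]))
  writeLines(c(gene_lines, exon_lines), path)
  invisible(path)
}
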