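# Shared fixture builders. Everything is generated in code; the standard
# coupled dataset is cached per session because several files reuse it.

write_toy_gtf <- function(path, strand = "+") {
  lines <- c(
    sprintf("chr1\ttest\tgene\t1001\t2000\t.\t%s\t.\tgene_id \"g1\"; gene_name \"G1\";", strand),
    sprintf("chr1\ttest\texon\t1001\t1200\t.\t%s\t.\tgene_id \"g1\"; gene_name \"G1\";", strand),
    sprintf("chr1\ttest\texon\t1801\t2000\t.\t%s\t.\tgene_id \"g1\"; gene_name \"G1\";", strand)
  )
  writeLines(lines, path)
  path
}

# Two-gene annotation with overlapping exons in gene g2 (tests merging).
write_two_gene_gtf <- function(path) {
  lines <- c(
    "chr1\ttest\tgene\t1001\t2000\t.\t+\t.\tgene_id \"g1\";",
    "chr1\ttest\texon\t1001\t2000\t.\t+\t.\tgene_id \"g1\";",
    "chr1\ttest\tgene\t5001\t6000\t.\t-\t.\tgene_id \"g2\";",
    "chr1\ttest\texon\t5001\t5100\t.\t-\t.\tgene_id \"g2\";",
    "chr1\ttest\texon\t5051\t5150\t.\t-\t.\tgene_id \"g2\";"
  )
  writeLines(lines, path)
  path
}

toy_matrix <- function(values, rows, cols) {
  m <- Matrix::Matrix(values, nrow = length(rows), sparse = TRUE,
                      dimnames = list(rows, cols))
  methods::as(m, "CsparseMatrix")
}

# The standard coupled dataset used by the downstream suites.
standard_fixture <- local({
  cache <- NULL
  function(seed = 42) {
    if (!is.null(cache) && cache$seed == seed) return(cache)
    cfg <- sim_config(seed = seed)
    genome <- simulate_genome(cfg)
    cells <- simulate_cells(cfg, genome)
    cache <<- list(seed = seed, cfg = cfg, genome = genome, cells = cells)
    cache
  }
})

# Majority true type per cluster (for scoring annotations).
majority_type <- function(labels, truth) {
  vapply(split(truth[names(labels)], labels),
         function(x) names(which.max(table(x))), character(1))
}
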