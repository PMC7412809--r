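test_that("decay weight analytics: anchors, bound, truncation", {
  expect_equal(decay_weight(0, 10000), 1)
  expect_equal(decay_weight(10000, 10000), 0.5)
  # exact value at the truncation boundary, below the documented bound
  expect_equal(decay_weight(150000, 10000), 2^-15)
  expect_lt(decay_weight(150000, 10000), 0.0005)
  expect_identical(decay_weight(150001, 10000), 0)
  expect_error(decay_weight(-1, 10000), "nonnegative")
})

test_that("decay weight halves every d0 and decreases on [0, cutoff]", {
  d <- seq(0, 140000, by = 5000)
  w <- decay_weight(d, 10000)
  expect_true(all(diff(w) < 0))
  expect_equal(decay_weight(d + 10000, 10000), w / 2)
  # every retained weight at the default cutoff stays above 2^-15
  expect_true(all(decay_weight(seq(0, 150000, by = 1), 10000) >= 2^-15))
})

# tiny genome used by the weight-matrix oracles:
# gene A ('+', tss 10000) with exons [10000,10500) and [13000,14500),
# gene B ('-', tss 61999) with exon [60000,62000)
toy_models <- function(flank = 2000) {
  genes <- data.frame(
    gene_id = c("A", "B"), gene_name = c("A", "B"), chrom = "chr1",
    start = c(10000, 60000), end = c(15000, 62000), strand = c("+", "-"),
    tss = c(10000, 61999), total_exon_length = c(2000, 2000))
  exons <- data.frame(
    gene_id = c("A", "A", "B"), chrom = "chr1",
    start = c(10000, 13000, 60000), end = c(10500, 14500, 62000))
  structure(list(genes = genes, exons = exons, promoter_flank = flank),
            class = "gene_models")
}

test_that("simple-model weights equal the per-pair brute force", {
  models <- toy_models()
  peaks <- genomic_intervals("chr1",
                             c(9900, 20000, 13100, 140000, 300000),
                             c(10100, 20400, 13400, 140500, 300500))
  cfg <- rp_config(model = "simple")
  W <- build_weight_matrix(peaks, models, cfg)
  # brute force: every pair through the decay formula
  centers <- interval_centers(peaks)
  for (i in seq_len(nrow(peaks))) {
    for (j in 1:2) {
      d <- abs(centers[i] - models$genes$tss[j])
      expect_equal(W[i, j], if (d > cfg$distance_cutoff) 0
                   else 2^(-d / cfg$d0))
    }
  }
  # peak centered exactly on the TSS gets weight 1
  expect_equal(W[1, "A"], 1)
})

test_that("enhanced model applies exon, exclusion and decay rules in order", {
  models <- toy_models()
  peaks <- genomic_intervals(
    "chr1",
    c(13100,   # inside A's exon
      61000,   # inside B's exon, 51 kb from A's tss
      30000,   # plain distal peak for both genes
      9000),   # in A's promoter window: decays for A, excluded for B
    c(13400, 61400, 30400, 9400))
  W <- build_weight_matrix(peaks, models, rp_config(model = "enhanced"))
  # own exon: exon_length_scale / total_exon_length = 1000 / 2000
  expect_equal(W[1, "A"], 0.5)
  expect_equal(W[2, "B"], 0.5)
  # peak in another gene's exon contributes nothing, whatever the distance
  expect_equal(W[2, "A"], 0)
  expect_equal(W[1, "B"], 0)
  # plain distal peak: ordinary decay for both
  cA <- abs(30200 - 10000)
  expect_equal(W[3, "A"], 2^(-cA / 10000))
  # own promoter window is not excluded
  expect_equal(W[4, "A"], 2^(-abs(9200 - 10000) / 10000))
  # raw-bp exon normalization via the scale knob
  W1 <- build_weight_matrix(peaks, models,
                            rp_config(model = "enhanced",
                                      exon_length_scale = 1))
  expect_equal(W1[1, "A"], 1 / 2000)
})

test_that("empty inputs give empty weight matrices without error", {
  models <- toy_models()
  none <- genomic_intervals(character(0), numeric(0), numeric(0))
  expect_equal(dim(build_weight_matrix(none, models, rp_config())), c(0, 2))
})

test_that("R = t(W) B matches the triple-loop oracle and is linear", {
  set.seed(5)
  W <- Matrix::Matrix(matrix(round(runif(4 * 2), 2), 4, 2,
                             dimnames = list(paste0("p", 1:4), c("gA", "gB"))),
                      sparse = TRUE)
  B <- toy_matrix(rbinom(12, 1, 0.5), paste0("p", 1:4), paste0("c", 1:3))
  R <- regulatory_potential(W, B)
  oracle <- matrix(0, 2, 3)
  for (g in 1:2) for (cc in 1:3) for (p in 1:4) {
    oracle[g, cc] <- oracle[g, cc] + W[p, g] * B[p, cc]
  }
  expect_equal(unname(as.matrix(R)), oracle)

  # all-zero B -> all-zero R
  B0 <- toy_matrix(rep(0, 12), paste0("p", 1:4), paste0("c", 1:3))
  expect_equal(max(abs(regulatory_potential(W, B0))), 0)

  # linearity over disjoint-support binary matrices
  B1 <- B; B1[, 2:3] <- 0
  B2 <- B; B2[, 1] <- 0
  expect_equal(as.matrix(regulatory_potential(W, B1) +
                           regulatory_potential(W, B2)),
               as.matrix(R))

  # misaligned peak lists are rejected
  B_bad <- B
  rownames(B_bad) <- paste0("q", 1:4)
  expect_error(regulatory_potential(W, B_bad), "not aligned")
})

test_that("gene activity tracks planted expression on coupled fixtures", {
  fx <- standard_fixture()
  W <- build_weight_matrix(fx$genome$peaks, fx$genome$genes, rp_config())
  act <- regulatory_potential(W, fx$cells$atac_binary)
  for (tp in unique(fx$cells$atac_labels)) {
    a <- Matrix::rowMeans(act[, fx$cells$atac_labels == tp])
    e <- Matrix::rowMeans(fx$cells$rna_counts[, fx$cells$rna_labels == tp])
    expect_gt(cor(a, e, method = "spearman"), 0.8)
  }
  # background peaks carry no weight to any gene
  bg <- is.na(fx$genome$truth$gene_id)
  expect_equal(max(Matrix::rowSums(W[bg, ])), 0)
  # promoter peaks sit on the TSS: simple-model weight 1 to their own gene
  Ws <- build_weight_matrix(fx$genome$peaks, fx$genome$genes,
                            rp_config(model = "simple"))
  prom <- which(fx$genome$truth$class == "promoter")
  own <- match(fx$genome$truth$gene_id[prom], colnames(Ws))
  expect_equal(unname(Ws[cbind(prom, own)]), rep(1, length(prom)))
})
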