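test_that("log normalization rescales every cell to the target library", {
  m <- toy_matrix(c(10, 0, 0, 0, 3, 1), c("g1", "g2"), c("c1", "c2", "c3"))
  out <- normalize_log(m)
  expect_equal(out[1, 1], log(10001))
  expect_equal(out[2, 1], 0)
  # all-zero cell maps to zero
  expect_equal(as.numeric(out[, 2]), c(0, 0))
  # de-logged columns sum back to the scale for nonzero cells
  expect_equal(sum(expm1(out[, 3])), 10000)
  # scale equivariance: multiplying a column leaves its output unchanged
  m2 <- m
  m2[, 3] <- m2[, 3] * 7
  expect_equal(as.numeric(normalize_log(m2)[, 3]), as.numeric(out[, 3]))
})

test_that("peak-depth normalization matches a per-column loop", {
  m <- toy_matrix(c(1, 1, 1, 1, 0, 1, 0, 0, 0, 0, 0, 0),
                  paste0("p", 1:4), c("c1", "c2", "c3"))
  out <- normalize_peak_depth(m)
  expect_equal(as.numeric(out[, 1]), rep(0.25, 4))
  expect_equal(Matrix::colSums(out), c(c1 = 1, c2 = 1, c3 = 0))
  dense <- as.matrix(m)
  for (j in 1:3) {
    s <- sum(dense[, j])
    expect_equal(as.numeric(out[, j]),
                 if (s > 0) dense[, j] / s else dense[, j],
                 ignore_attr = TRUE)
  }
})

test_that("variable-gene selection recovers planted overdispersed genes", {
  set.seed(21)
  n_cells <- 120
  n_genes <- 1000
  # baseline genes: Poisson at means spread over a continuum
  mu <- runif(n_genes, 2, 20)
  base <- matrix(rpois(n_genes * n_cells, rep(mu, n_cells)), n_genes, n_cells,
                 dimnames = list(sprintf("g%04d", 1:n_genes),
                                 paste0("c", 1:n_cells)))
  # overdispersed genes at matched means: gamma-Poisson with heavy noise
  hot <- sample(n_genes, 50)
  base[hot, ] <- rnbinom(50 * n_cells, mu = rep(mu[hot], n_cells), size = 0.5)
  normed <- normalize_log(Matrix::Matrix(base, sparse = TRUE))
  top <- select_variable_genes(normed, 50)
  expect_gte(length(intersect(top, rownames(base)[hot])), 45)
  # constant genes are never selected
  base2 <- base
  base2[1:10, ] <- 3
  rownames(base2)[1:10] <- paste0("const", 1:10)
  top2 <- select_variable_genes(log1p(Matrix::Matrix(base2, sparse = TRUE)),
                                200)
  expect_length(intersect(top2, paste0("const", 1:10)), 0)
  # asking for everything returns a permutation of the informative genes
  expect_warning(all_genes <- select_variable_genes(normed, 2000),
                 "nonzero variance")
  expect_true(all(all_genes %in% rownames(base)))
})

test_that("LSI embedding separates planted populations and reports rank", {
  set.seed(8)
  # two populations with disjoint peak blocks
  b1 <- matrix(rbinom(50 * 30, 1, 0.6), 50, 30)
  b2 <- matrix(rbinom(50 * 30, 1, 0.6), 50, 30)
  B <- rbind(cbind(b1, matrix(rbinom(50 * 30, 1, 0.02), 50, 30)),
             cbind(matrix(rbinom(50 * 30, 1, 0.02), 50, 30), b2))
  dimnames(B) <- list(paste0("p", 1:100), paste0("c", 1:60))
  emb <- lsi_embed(Matrix::Matrix(B, sparse = TRUE), k = 10)
  grp <- rep(1:2, each = 30)
  # the component space must linearly separate the populations
  fit <- suppressWarnings(
    glm(factor(grp) ~ emb$coords, family = binomial))
  expect_gt(mean((predict(fit) > 0) + 1 == grp), 0.95)

  # rank-1 matrix: first singular value dominates
  Br <- Matrix::Matrix(matrix(rep(c(1, 0), 50), 100, 20), sparse = TRUE,
                       dimnames = list(paste0("p", 1:100), paste0("c", 1:20)))
  embr <- lsi_embed(Br, k = 3, drop_first = FALSE)
  expect_gt(embr$singular_values[1]^2 / sum(embr$singular_values^2), 0.99)
  expect_error(lsi_embed(Br, k = 25), "smaller")
})

test_that("graph clustering resolves well-separated Gaussian blobs exactly", {
  set.seed(13)
  blob <- function(center, n = 200) {
    sweep(matrix(rnorm(n * 5, sd = 0.3), n, 5), 2, center, "+")
  }
  coords <- rbind(blob(c(0, 0, 0, 0, 0)), blob(c(10, 10, 0, 0, 0)))
  rownames(coords) <- paste0("c", seq_len(nrow(coords)))
  emb <- structure(list(coords = coords, method = "pca"),
                   class = "sc_embedding")
  lab <- cluster_cells(emb)
  truth <- rep(1:2, each = 200)
  expect_length(unique(lab), 2)
  expect_equal(nmi(lab, truth), 1)
  # duplicating one blob's points never mixes the two blobs: every
  # resulting cluster stays pure even if the enlarged blob subdivides
  coords2 <- rbind(coords, coords[1:200, ])
  rownames(coords2) <- paste0("c", seq_len(nrow(coords2)))
  emb2 <- structure(list(coords = coords2, method = "pca"),
                    class = "sc_embedding")
  lab2 <- cluster_cells(emb2)
  truth2 <- c(truth, rep(1, 200))
  purity <- vapply(split(truth2, lab2),
                   function(x) max(table(x)) / length(x), numeric(1))
  expect_equal(unname(purity), rep(1, length(purity)))
  expect_error(cluster_cells(emb, n_neighbors = 500), "fewer cells")
})

test_that("Wilcoxon p-values match exact enumeration for small groups", {
  # exact oracle: enumerate all assignments of ranks to the in-group
  exact_p <- function(x, in_group) {
    n1 <- sum(in_group)
    r <- rank(x)
    u_obs <- sum(r[in_group]) - n1 * (n1 + 1) / 2
    combos <- utils::combn(length(x), n1)
    u_all <- apply(combos, 2, function(idx) {
      sum(r[idx]) - n1 * (n1 + 1) / 2
    })
    mu <- n1 * (length(x) - n1) / 2
    mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
  }
  cases <- list(
    list(x = c(1, 2, 3, 10, 11, 12), g = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)),
    list(x = c(5, 1, 4, 2, 8, 3, 9, 7), g = rep(c(TRUE, FALSE), 4)),
    list(x = c(1, 1, 2, 2, 3, 3, 4, 4), g = rep(c(TRUE, FALSE), each = 4)),
    list(x = rnorm(8), g = rep(c(TRUE, FALSE), each = 4)))
  set.seed(3)
  for (cs in cases) {
    mat <- matrix(cs$x, 1, dimnames = list("g1", paste0("c", seq_along(cs$x))))
    rt <- scregpot:::row_ranks_and_ties(mat)
    p <- scregpot:::wilcoxon_p(rt$ranks, rt$ties, cs$g)
    expect_lt(abs(p - exact_p(cs$x, cs$g)), 0.02)
  }
  # the large-sample path agrees with the reference implementation of the
  # tie-corrected normal approximation
  x <- round(rnorm(300), 1)
  g <- rep(c(TRUE, FALSE), 150)
  mat <- matrix(x, 1, dimnames = list("g1", paste0("c", 1:300)))
  rt <- scregpot:::row_ranks_and_ties(mat)
  p_approx <- scregpot:::wilcoxon_p(rt$ranks, rt$ties, g)
  p_ref <- stats::wilcox.test(x[g], x[!g], correct = FALSE,
                              exact = FALSE)$p.value
  expect_equal(unname(p_approx), p_ref, tolerance = 1e-10)
})

test_that("marker detection honours thresholds and skips tiny clusters", {
  set.seed(9)
  n <- 60
  x <- matrix(rpois(5 * n, 5), 5, n,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:n)))
  labels <- setNames(rep(1:2, each = n / 2), colnames(x))
  x["g1", labels == 1] <- rpois(n / 2, 40)  # strong marker of cluster 1
  normed <- normalize_log(Matrix::Matrix(x, sparse = TRUE))
  mk <- wilcoxon_markers(normed, labels)
  # cluster 1's only marker is the planted gene (library-size composition
  # can legitimately make other genes markers of cluster 2)
  expect_equal(mk$feature[mk$cluster == 1], "g1")
  rec <- mk[mk$feature == "g1" & mk$cluster == 1, ]
  expect_gt(rec$logFC, 0.25)
  expect_lt(rec$p_value, 1e-5)
  # identical distributions: nothing reported
  flat <- normalize_log(Matrix::Matrix(
    matrix(rpois(5 * n, 5), 5, n,
           dimnames = dimnames(x)), sparse = TRUE))
  expect_equal(nrow(wilcoxon_markers(flat, labels)), 0)
  # logFC below threshold excluded even when significant
  mk_hi <- wilcoxon_markers(normed, labels,
                            list(min_logfc = 5, min_pct = 0.25, max_p = 1e-5))
  expect_equal(nrow(mk_hi), 0)
  # a cluster smaller than 3 cells is skipped with a warning
  labels2 <- labels
  labels2[1:2] <- 3
  labels2 <- setNames(ifelse(seq_len(n) <= 2, 3,
                             rep(1:2, each = n / 2)[seq_len(n)]),
                      colnames(x))
  expect_warning(wilcoxon_markers(normed, labels2), "fewer than 3")
})

test_that("cluster logFC matches hand computation and keeps both signs", {
  x <- matrix(c(2, 2, 0, 0,
                1, 1, 3, 3), 2, 4, byrow = TRUE,
              dimnames = list(c("up", "down"), paste0("c", 1:4)))
  normed <- log1p(x)  # pre-logged values, bypass library scaling
  labels <- setNames(c(1, 1, 2, 2), colnames(x))
  lfc <- cluster_logfc(Matrix::Matrix(normed, sparse = TRUE), labels)
  expect_equal(lfc["up", "1"], log((2 + 1) / (0 + 1)))
  expect_equal(lfc["down", "1"], log((1 + 1) / (3 + 1)))
  expect_lt(lfc["down", "1"], 0)
})
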