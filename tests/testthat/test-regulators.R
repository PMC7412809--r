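test_that("PWM similarity: self, reverse complement, oracle, symmetry", {
  pwms <- simulate_pwms(3, 0, motif_length = 6, seed = 5)
  a <- pwms[[1]]
  expect_equal(pwm_similarity(a, a), 1)
  rc <- pwm(paste0(a$name, "_rc"),
            a$probs[c("T", "G", "C", "A"), rev(seq_len(ncol(a$probs)))])
  expect_equal(pwm_similarity(a, rc), 1)
  for (i in 1:2) for (j in (i + 1):3) {
    s <- pwm_similarity(pwms[[i]], pwms[[j]])
    expect_equal(s, oracle_pwm_similarity(pwms[[i]], pwms[[j]]),
                 tolerance = 1e-10)
    expect_equal(s, pwm_similarity(pwms[[j]], pwms[[i]]), tolerance = 1e-10)
    expect_gte(s, -1); expect_lte(s, 1)
  }
  short <- pwm("short", matrix(0.25, 4, 4))
  expect_error(pwm_similarity(short, a, min_overlap = 5), "too short")
})

test_that("motif clustering groups near-identical PWMs, leaves others single", {
  pwms <- simulate_pwms(2, 1, seed = 6)  # M1_1 ~ M1_2, M2_1 ~ M2_2
  fam <- cluster_motifs(pwms, threshold = 0.7)
  memb <- setNames(rep(names(fam), lengths(fam)), unlist(fam))
  expect_equal(memb[["M1_1"]], memb[["M1_2"]])
  expect_equal(memb[["M2_1"]], memb[["M2_2"]])
  expect_false(memb[["M1_1"]] == memb[["M2_1"]])
  # families partition the motif set
  expect_setequal(unlist(fam), vapply(pwms, `[[`, "", "name"))
  # pairwise similarity check: members of one family exceed the threshold
  expect_gt(pwm_similarity(pwms[[1]], pwms[[2]]), 0.7)
  # a threshold nothing clears gives all singletons
  fam1 <- cluster_motifs(pwms, threshold = 0.999999)
  expect_true(all(lengths(fam1) == 1))
})

test_that("peak-set enrichment p equals the hypergeometric tail", {
  # universe engineered to yield the table a=8, b=2, c=2, d=8
  universe <- genomic_intervals("chr1", seq(0, 19000, by = 1000) + 1,
                                seq(0, 19000, by = 1000) + 500)
  cluster_peaks <- universe[1:10, ]
  ref <- universe[c(1:8, 11:12), ]    # 8 in cluster, 2 outside
  enr <- peakset_enrichment(cluster_peaks, universe, list(tf = ref))
  # oracle: hypergeometric tail sum P(X >= 8)
  p_oracle <- sum(dhyper(8:10, 10, 10, 10))
  expect_equal(enr$p_value, p_oracle, tolerance = 1e-12)
  or <- (8.5 * 8.5) / (2.5 * 2.5)
  expect_equal(enr$odds_ratio, or)
  expect_equal(enr$score, -log10(p_oracle) * log2(or))

  # reference identical to the cluster peaks dominates all other candidates
  refs <- list(perfect = cluster_peaks, partial = ref,
               off = universe[11:20, ])
  enr3 <- peakset_enrichment(cluster_peaks, universe, refs)
  expect_equal(enr3$regulator[1], "perfect")
  # fully disjoint reference: enrichment-tail p is exactly 1, score 0;
  # partial depletion (odds ratio < 1 with p < 1) goes negative
  expect_lte(enr3$score[enr3$regulator == "off"], 0)
  depl <- peakset_enrichment(cluster_peaks, universe,
                             list(tf = universe[c(1, 11:18), ]))
  expect_lt(depl$odds_ratio, 1)
  expect_lt(depl$score, 0)
  expect_error(peakset_enrichment(cluster_peaks, universe[0, ], refs),
               "empty")
})

test_that("enrichment p-values match the hypergeometric oracle on random draws", {
  set.seed(14)
  for (rep in 1:5) {
    n_u <- sample(20:50, 1)
    universe <- genomic_intervals("chr1", (1:n_u) * 1000, (1:n_u) * 1000 + 400)
    cl <- sort(sample(n_u, sample(5:12, 1)))
    rf <- sort(sample(n_u, sample(5:20, 1)))
    enr <- peakset_enrichment(universe[cl, ], universe,
                              list(tf = universe[rf, ]))
    a <- length(intersect(cl, rf))
    p_oracle <- sum(dhyper(a:min(length(cl), length(rf)),
                           length(rf), n_u - length(rf), length(cl)))
    expect_equal(enr$p_value, p_oracle, tolerance = 1e-10)
  }
})

test_that("family score propagation is a max, idempotent, rank-refreshing", {
  rec <- data.frame(regulator = c("A", "B", "C"), cluster = 1,
                    p_value = c(1e-5, 0.5, 1e-3),
                    odds_ratio = c(4, 1.2, 2),
                    score = c(5, 1, 3), rank = 1:3)
  fam <- list(family1 = c("A", "B"), family2 = "C")
  out <- propagate_family_scores(rec, fam)
  expect_equal(out$score[out$regulator == "B"], 5)
  expect_equal(out$score[out$regulator == "A"], 5)
  expect_equal(out$score[out$regulator == "C"], 3)
  # never decreases a score
  expect_true(all(out$score[match(rec$regulator, out$regulator)] >= rec$score))
  # idempotent
  again <- propagate_family_scores(out, fam)
  expect_equal(again$score[order(again$regulator)],
               out$score[order(out$regulator)])
  # ranks recomputed: A and B tie at 5, ties broken by name
  expect_equal(out$regulator[1:2], c("A", "B"))
})

test_that("rank product combination is symmetric and sorts as documented", {
  rna <- data.frame(regulator = c("X", "Y", "Z"), rank = c(1, 2, 8))
  atac <- data.frame(regulator = c("X", "Y", "Z"), rank = c(1, 8, 3))
  out <- rank_product_combine(rna, atac)
  expect_equal(out$regulator[1], "X")
  expect_equal(out$rank_product[out$regulator == "X"], 1)
  # (2,8) vs (8,3): sqrt(16) = 4 beats sqrt(24)
  expect_equal(out$rank_product[out$regulator == "Y"], 4)
  expect_lt(out$rank[out$regulator == "Y"], out$rank[out$regulator == "Z"])
  # swapping modalities leaves the combined ranking unchanged
  swapped <- rank_product_combine(atac, rna)
  expect_equal(swapped$regulator, out$regulator)
  expect_equal(swapped$rank_product, out$rank_product)
  # a regulator missing from one list takes that list's worst rank + 1
  out2 <- rank_product_combine(rna, atac[1:2, ])
  expect_equal(out2$rank_atac[out2$regulator == "Z"], 9)
})

test_that("regulator filtering drops unexpressed factors and re-ranks", {
  rec <- data.frame(regulator = c("A", "B", "C", "D"), cluster = 1,
                    p_value = 1e-4, odds_ratio = 2, score = 4:1, rank = 1:4)
  expr <- c(A = 2, B = 0, C = 1, D = 5)
  rp <- c(A = 0.6, B = 2, C = 0.4, D = 1)
  out <- filter_regulators(rec, expr, rp, context = "rna")
  expect_setequal(out$regulator, c("A", "D"))   # B: expr 0; C: rp < 0.5
  expect_equal(out$regulator[out$rank == 1], "D")  # re-ranked by expression
  out_atac <- filter_regulators(rec, expr, rp, context = "atac")
  expect_equal(out_atac$regulator[out_atac$rank == 1], "D")
})

test_that("a planted regulator ranks first in its cluster across seeds", {
  for (seed in 1:10) {
    cfg <- sim_config(seed = seed, n_genes = 60, n_peaks = 400,
                      atac_cells_per_type = 60, markers_per_type = 8)
    genome <- simulate_genome(cfg)
    cells <- simulate_cells(cfg, genome)
    refs <- simulate_reference_sets(genome, cells, seed = seed)
    B <- cells$atac_binary
    pd <- normalize_peak_depth(B) * stats::median(Matrix::colSums(B))
    lab <- setNames(match(cells$atac_labels, unique(cells$atac_labels)),
                    names(cells$atac_labels))
    pk <- wilcoxon_markers(pd, lab, marker_thresholds("peaks"),
                           delogged = TRUE)
    cl <- match("type1", unique(cells$atac_labels))
    ids <- interval_ids(genome$peaks)
    clp <- genome$peaks[ids %in% pk$feature[pk$cluster == cl], , drop = FALSE]
    enr <- peakset_enrichment(clp, genome$peaks, refs, cluster = cl)
    expect_equal(enr$regulator[1], "TF_type1")
  }
})
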