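# brute-force PWM similarity: every offset, both orientations, explicit sums
oracle_pwm_similarity <- function(a, b, min_overlap = 5) {
  ic <- function(p) {
    q <- p[p > 0]
    2 + sum(q * log2(q))
  }
  rc <- function(m) m[c(4, 3, 2, 1), rev(seq_len(ncol(m)))]
  best <- -Inf
  for (pb in list(b$probs, rc(b$probs))) {
    la <- ncol(a$probs); lb <- ncol(pb)
    for (off in -(lb):la) {
      cols <- list()
      for (i in seq_len(la)) {
        j <- i - off
        if (j >= 1 && j <= lb) cols[[length(cols) + 1]] <- c(i, j)
      }
      if (length(cols) < min_overlap) next
      num <- 0; den <- 0
      for (cj in cols) {
        pa <- a$probs[, cj[1]]; pbb <- pb[, cj[2]]
        r <- suppressWarnings(stats::cor(pa, pbb))
        if (is.na(r)) r <- 0
        w <- (ic(pa) + ic(pbb)) / 2
        num <- num + w * r; den <- den + w
      }
      if (den > 0) best <- max(best, num / den)
    }
  }
  best
}
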