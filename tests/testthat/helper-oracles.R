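# Independent brute-force oracles, deliberately naive: plain loops over
# joint distributions, no code shared with the package internals.

oracle_entropy <- function(p, base = 2) {
  h <- 0
  for (x in p) if (x > 0) h <- h - x * log(x, base)
  h
}

# Mutual information of a joint count table via sum p log(p / (px * py)).
oracle_mi <- function(tab, base = 2) {
  n <- sum(tab)
  mi <- 0
  for (r in seq_len(nrow(tab))) for (k in seq_len(ncol(tab))) {
    pxy <- tab[r, k] / n
    if (pxy > 0)
      mi <- mi + pxy * log(pxy / ((sum(tab[r, ]) / n) * (sum(tab[, k]) / n)), base)
  }
  unname(mi)
}

# IG(A;B;C) from raw genotype/class vectors by explicit cell counting.
oracle_ig <- function(ga, gb, cls, base = 2) {
  jt <- matrix(0, 9, 2)
  at <- matrix(0, 3, 2)
  bt <- matrix(0, 3, 2)
  for (k in seq_along(ga)) {
    cc <- if (cls[k] == "case") 1L else 2L
    jt[3L * ga[k] + gb[k] + 1L, cc] <- jt[3L * ga[k] + gb[k] + 1L, cc] + 1L
    at[ga[k] + 1L, cc] <- at[ga[k] + 1L, cc] + 1L
    bt[gb[k] + 1L, cc] <- bt[gb[k] + 1L, cc] + 1L
  }
  oracle_mi(jt, base) - oracle_mi(at, base) - oracle_mi(bt, base)
}

oracle_mode <- function(x) {
  x <- x[!is.na(x)]
  counts <- vapply(0:2, function(g) sum(x == g), integer(1))
  (0:2)[counts == max(counts)][1]  # lowest code among the tied maxima
}

# Tiny random dataset with both classes guaranteed present.
random_tiny_ds <- function(n, m, seed) {
  set.seed(seed)
  repeat {
    g <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
    cls <- sample(c("case", "control"), n, replace = TRUE)
    if (length(unique(cls)) == 2L) break
  }
  genotype_dataset(g, cls, sprintf("S%d", seq_len(m)))
}
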