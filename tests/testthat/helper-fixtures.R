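# Shared fixtures, all built in code.

# Nine individuals, one per genotype combination; class is the XOR of the
# two genotype parities. The classic pure-epistasis configuration: each
# SNP alone is nearly uninformative, the pair almost fully determines
# the class.
xor9_ds <- function() {
  g <- as.matrix(expand.grid(A = 0:2, B = 0:2))
  cls <- ifelse((g[, 1] %% 2) != (g[, 2] %% 2), "case", "control")
  genotype_dataset(g, cls, c("A", "B"))
}

# The published real-data degree distribution of the 319-vertex network:
# p(d) columns scaled back to integer vertex counts.
table1_dd <- function() {
  degree_dist_from_counts(c(1, 2, 3, 4, 5, 6, 8, 11),
                          c(216, 64, 17, 11, 4, 4, 2, 1))
}

table1_p <- function() {
  c(0.677, 0.201, 0.0533, 0.0345, 0.0125, 1.25e-2, 0, 6.27e-3, 0, 0, 3.13e-3)
}

# Hand-built pair-weight table: `edges` is a list of c(a, b, weight);
# unspecified pairs get weight -1 so they never appear at t >= 0.
make_pw <- function(ids, edges = list(), default = -1) {
  idx <- pair_indices(length(ids))
  df <- data.frame(i = idx$i, j = idx$j,
                   snp_a = ids[idx$i], snp_b = ids[idx$j],
                   ig = default, stringsAsFactors = FALSE)
  for (e in edges) {
    k <- which((df$snp_a == e[[1]] & df$snp_b == e[[2]]) |
                 (df$snp_a == e[[2]] & df$snp_b == e[[1]]))
    stopifnot(length(k) == 1L)
    df$ig[k] <- as.numeric(e[[3]])
  }
  structure(df, snp_ids = ids, base = 2,
            class = c("pair_weight_table", "data.frame"))
}

# Degree "distribution" with arbitrary (possibly non-count) p values,
# for exact-recovery fit tests.
dd_exact <- function(degree, p, n_vertices = 100L) {
  structure(list(degree = as.integer(degree), count = rep(1L, length(degree)),
                 p = p, n_vertices = n_vertices),
            class = "degree_distribution_table")
}

write_toy_tsv <- function(path, lines) {
  writeLines(lines, path)
  path
}
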