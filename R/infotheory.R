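# Entropy-based main-effect and pairwise-interaction weights.
#
# The weight of a SNP A is the mutual information I(A;C) between its
# genotype and the case/control class C: I(A;C) = H(C) - H(C|A). The
# weight of an unordered pair (A, B) is the information gain
# IG(A;B;C) = I(A,B;C) - I(A;C) - I(B;C), i.e. the class information the
# joint genotype carries beyond the two marginal genotypes: positive for
# synergy, negative for redundancy. All probabilities are plug-in
# (empirical) frequencies; no bias correction or pseudocounts.

#' Shannon entropy of a probability vector
#'
#' `H = sum p * log(1/p)` with the `0 * log(1/0) := 0` convention.
#'
#' @param p non-negative numeric vector summing to 1 (tolerance 1e-9).
#' @param base logarithm base: 2 (bits, the default) or `exp(1)` (nats).
#' @return Non-negative entropy in the chosen unit.
#' @export
shannon_entropy <- function(p, base = 2) {
  if (any(p < 0))
    stop_validation("probabilities must be non-negative; got %g", min(p))
  if (abs(sum(p) - 1) > 1e-9)
    stop_validation("probabilities must sum to 1 within 1e-9; got %.12g", sum(p))
  pos <- p > 0
  -sum(p[pos] * log(p[pos], base = base))
}

# Entropy of the distribution implied by a vector/matrix of counts.
entropy_counts <- function(n, base = 2) {
  total <- sum(n)
  if (total <= 0) stop_validation("all-zero count table")
  pos <- n > 0
  log(total, base = base) - sum(n[pos] * log(n[pos], base = base)) / total
}

# H(C | rows): rows of `counts` are conditioning levels, columns classes.
cond_entropy_counts <- function(counts, base = 2) {
  total <- sum(counts)
  row_tot <- rowSums(counts)
  sum(xlog_ratio(counts, counts * 0 + row_tot, base)) / total
}

#' Mutual information between a genotype and the class from counts
#'
#' Evaluates `I = H(C) - H(C|A)` from a genotype-by-class contingency
#' table (3 x 2 for one SNP, 9 x 2 for a joint pair genotype). The
#' conditional entropy sums over every (genotype, class) cell — six for a
#' single SNP. Plug-in mutual information is non-negative; tiny negative
#' rounding residues (> -1e-12) are clamped to zero.
#'
#' @param counts non-negative integer matrix with 2 class columns
#'   (case, control) and one row per genotype level.
#' @param base logarithm base (2 = bits).
#' @return `I(A;C)` in the chosen unit.
#' @export
mutual_information <- function(counts, base = 2) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 2L)
    stop_validation("count table must have 2 class columns, got %d", ncol(counts))
  if (any(counts < 0)) stop_validation("negative cell in count table")
  if (sum(counts) < 1) stop_validation("all-zero count table")
  cls <- colSums(counts)
  if (any(cls == 0))
    stop_validation("both class marginals must be positive; got (%s)",
                    paste(cls, collapse = ", "))
  i <- entropy_counts(cls, base) - cond_entropy_counts(counts, base)
  if (i < 0 && i > -1e-12) i <- 0
  i
}

#' Information gain of a SNP pair from contingency counts
#'
#' `IG(A;B;C) = I(A,B;C) - I(A;C) - I(B;C)`, the synergetic class
#' information of the pair. The three tables must describe the same
#' individuals (equal totals and class marginals). A negative value means
#' the two genotypes carry redundant class information (they tend to vary
#' together); zero means independence or a synergy/redundancy balance.
#'
#' @param pair_counts 9 x 2 joint genotype-by-class counts
#'   (see [class_counts()]).
#' @param a_counts,b_counts the 3 x 2 marginal tables of the two SNPs.
#' @param base logarithm base (2 = bits).
#' @return `IG(A;B;C)` in the chosen unit; may be negative.
#' @export
information_gain <- function(pair_counts, a_counts, b_counts, base = 2) {
  tot <- vapply(list(pair_counts, a_counts, b_counts), sum, numeric(1))
  if (length(unique(tot)) != 1L)
    stop_validation("tables describe different totals: %s",
                    paste(tot, collapse = ", "))
  cls <- vapply(list(pair_counts, a_counts, b_counts),
                function(x) colSums(as.matrix(x)), numeric(2))
  if (any(cls[, 1] != cls[, 2]) || any(cls[, 1] != cls[, 3]))
    stop_validation("tables have inconsistent class marginals")
  mutual_information(pair_counts, base) -
    mutual_information(a_counts, base) -
    mutual_information(b_counts, base)
}

# Per-genotype-level indicator matrices split by class; shared by the
# vectorised all-SNPs / all-pairs scorers. Returns list(case, control),
# each a list of three n_class x m numeric matrices.
class_indicators <- function(ds) {
  g <- ds$genotypes
  if (anyNA(g))
    stop_validation("dataset has missing genotypes; run impute_missing() first")
  case <- ds$phenotype == "case"
  split_one <- function(keep) lapply(0:2, function(lev) {
    m <- g[keep, , drop = FALSE] == lev
    mode(m) <- "numeric"
    m
  })
  list(case = split_one(case), control = split_one(!case))
}

#' Main-effect weights for every SNP
#'
#' Computes `I(A;C)` for each SNP of an imputed dataset. A SNP whose
#' genotype is constant, or independent of the class, scores 0.
#'
#' @param ds an imputed [genotype_dataset()].
#' @param base logarithm base (2 = bits).
#' @return A named numeric vector (class `main_effect_table`) aligned to
#'   `ds$snp_ids`, with attribute `base`.
#' @export
main_effects <- function(ds, base = 2) {
  ind <- class_indicators(ds)
  n <- n_individuals(ds)
  hc <- entropy_counts(c(n_cases(ds), n_controls(ds)), base)
  acc <- 0
  for (lev in 1:3) {
    n_case <- colSums(ind$case[[lev]])
    n_ctrl <- colSums(ind$control[[lev]])
    n_tot <- n_case + n_ctrl
    acc <- acc + xlog_ratio(n_case, n_tot, base) + xlog_ratio(n_ctrl, n_tot, base)
  }
  mi <- hc - acc / n
  mi[mi < 0 & mi > -1e-12] <- 0
  names(mi) <- ds$snp_ids
  structure(mi, base = base, class = "main_effect_table")
}

#' @export
print.main_effect_table <- function(x, ...) {
  cat(sprintf("main_effect_table: %d SNPs, base %s; max I(A;C) = %.5g (%s)\n",
              length(x), format(attr(x, "base")), max(x), names(x)[which.max(x)]))
  invisible(x)
}

#' Enumerate the unordered SNP pairs of an m-SNP panel
#'
#' Canonical pair order used throughout the package: column-major upper
#' triangle, i.e. (1,2), (1,3), (2,3), (1,4), ... with `i < j`.
#'
#' @param m number of SNPs.
#' @return A data frame with integer columns `i`, `j` and
#'   `choose(m, 2)` rows.
#' @export
pair_indices <- function(m) {
  m <- as.integer(m)
  if (m < 2L) stop_validation("need at least 2 SNPs, got %d", m)
  j <- rep.int(2:m, 1:(m - 1L))
  i <- sequence(1:(m - 1L))
  data.frame(i = i, j = j)
}

#' Information gain for every unordered SNP pair
#'
#' Exhaustively scores all `choose(m, 2)` pairs of an imputed dataset.
#' The computation is vectorised over the pair space via per-genotype
#' class indicator cross-products, so memory stays proportional to the
#' number of pairs and never to pairs x individuals; the result is
#' independent of pair evaluation order.
#'
#' @param ds an imputed [genotype_dataset()] with at least 2 SNPs.
#' @param base logarithm base (2 = bits).
#' @return A data frame of class `pair_weight_table` with columns `i`,
#'   `j` (indices, `i < j`), `snp_a`, `snp_b`, `ig`, in [pair_indices()]
#'   order; attributes `snp_ids` and `base`. A `p_value` column is added
#'   by [pair_pvalues()].
#' @export
pair_weights <- function(ds, base = 2) {
  m <- n_snps(ds)
  if (m < 2L) stop_validation("need at least 2 SNPs, got %d", m)
  n <- n_individuals(ds)
  ind <- class_indicators(ds)
  hc <- entropy_counts(c(n_cases(ds), n_controls(ds)), base)
  mains <- main_effects(ds, base)

  acc <- matrix(0, m, m)
  for (a in 1:3) for (b in 1:3) {
    n_case <- crossprod(ind$case[[a]], ind$case[[b]])
    n_ctrl <- crossprod(ind$control[[a]], ind$control[[b]])
    n_tot <- n_case + n_ctrl
    acc <- acc + xlog_ratio(n_case, n_tot, base) + xlog_ratio(n_ctrl, n_tot, base)
  }
  i_joint <- hc - acc / n            # I(A,B;C), m x m symmetric
  ig_mat <- i_joint - outer(as.numeric(mains), as.numeric(mains), "+")

  idx <- pair_indices(m)
  out <- data.frame(i = idx$i, j = idx$j,
                    snp_a = ds$snp_ids[idx$i], snp_b = ds$snp_ids[idx$j],
                    ig = ig_mat[cbind(idx$i, idx$j)],
                    stringsAsFactors = FALSE)
  structure(out, snp_ids = ds$snp_ids, base = base,
            class = c("pair_weight_table", "data.frame"))
}

#' Look up the weight of one pair in a pair-weight table
#'
#' Symmetric access: `pair_weight(pw, a, b)` equals `pair_weight(pw, b, a)`.
#'
#' @param pw a [pair_weights()] table.
#' @param a,b SNP ids (character) or indices.
#' @return The information gain of the pair.
#' @export
pair_weight <- function(pw, a, b) {
  ids <- attr(pw, "snp_ids")
  to_idx <- function(x) {
    if (is.character(x)) {
      k <- match(x, ids)
      if (is.na(k)) stop_validation("unknown SNP id '%s'", x)
      k
    } else as.integer(x)
  }
  i <- to_idx(a); j <- to_idx(b)
  if (i == j) stop_validation("a pair needs two distinct SNPs")
  lo <- min(i, j); hi <- max(i, j)
  pw$ig[pw$i == lo & pw$j == hi]
}

#' Write main-effect and pair-weight tables as TSV
#'
#' The vertex file has columns `snp_id`, `mutual_information`; the edge
#' file `snp_a`, `snp_b`, `information_gain` and, when present,
#' `p_value`. A provenance comment header is prepended; [read_pair_weights()]
#' reverses the edge writer.
#'
#' @param mains a [main_effects()] table.
#' @param pw a [pair_weights()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_main_effects <- function(mains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(extra = sprintf("log base=%s", format(attr(mains, "base")))), con)
  writeLines("snp_id\tmutual_information", con)
  writeLines(sprintf("%s\t%.17g", names(mains), as.numeric(mains)), con)
  invisible(path)
}

#' @rdname write_main_effects
#' @export
write_pair_weights <- function(pw, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(extra = sprintf("log base=%s", format(attr(pw, "base")))), con)
  has_p <- "p_value" %in% names(pw)
  writeLines(paste(c("snp_a", "snp_b", "information_gain",
                     if (has_p) "p_value"), collapse = "\t"), con)
  body <- sprintf("%s\t%s\t%.17g", pw$snp_a, pw$snp_b, pw$ig)
  if (has_p) body <- sprintf("%s\t%.17g", body, pw$p_value)
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_main_effects
#' @export
read_pair_weights <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  ids <- sort(unique(c(tab$snp_a, tab$snp_b)))
  out <- data.frame(i = match(tab$snp_a, ids), j = match(tab$snp_b, ids),
                    snp_a = tab$snp_a, snp_b = tab$snp_b,
                    ig = tab$information_gain, stringsAsFactors = FALSE)
  if ("p_value" %in% names(tab)) out$p_value <- tab$p_value
  structure(out, snp_ids = ids, base = NA_real_,
            class = c("pair_weight_table", "data.frame"))
}
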