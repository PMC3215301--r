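# Phenotype-permutation null for pair weights and network properties.
#
# Shuffling the case/control labels severs every genotype-phenotype
# association while preserving the genotype matrix and the class counts,
# so any structure surviving the shuffle is attributable to sampling
# noise alone. No multiple-testing correction is applied across the
# ~m^2/2 pairs: edge filtering uses the raw per-pair p-value (default
# alpha 0.01), which is deliberate and should be kept in mind when
# interpreting individual edges.

#' Shuffle the phenotype labels
#'
#' Returns the same dataset with the phenotype replaced by a uniformly
#' random permutation of itself: genotypes untouched, case and control
#' counts preserved exactly. Deterministic given `seed`.
#'
#' @param ds a [genotype_dataset()].
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return A [genotype_dataset()].
#' @export
permute_phenotype <- function(ds, seed = NULL) {
  ds$phenotype <- with_seed(seed, sample(ds$phenotype))
  ds
}

#' Build the permutation null ensemble
#'
#' For each of `n_replicates` phenotype shuffles, all pair weights are
#' recomputed and reduced to (a) optionally the full weight vector
#' (needed for matched-pair p-values), (b) per-threshold network
#' summaries on `thresholds`, and (c) the replicate's maximum weight.
#' Replicates are independent (seed of replicate r is `seed + r`), so
#' the ensemble is reproducible and order-invariant.
#'
#' Full weight storage requires `choose(m, 2) * n_replicates` doubles;
#' when that exceeds `budget` (and `keep_weights = "auto"`), only the
#' summaries are kept and a warning notes that matched-pair p-values are
#' unavailable.
#'
#' @param ds an imputed [genotype_dataset()].
#' @param n_replicates number of shuffles (the study-scale default is
#'   1000; tests use far fewer).
#' @param seed base integer seed.
#' @param thresholds optional threshold vector for per-replicate network
#'   summaries.
#' @param keep_weights `"auto"` (respect `budget`), `"always"`, `"never"`.
#' @param budget maximum number of stored null weights under `"auto"`.
#' @param base logarithm base passed to [pair_weights()].
#' @return An object of class `null_ensemble`: list with `n_replicates`,
#'   `seed`, `snp_ids`, `weights` (pairs x replicates matrix or `NULL`),
#'   `max_weight`, `thresholds`, `summaries` (long data frame:
#'   `replicate`, `threshold`, `n_edges`, `n_vertices`, `lcc_size`) and
#'   `degrees` (per replicate, per threshold degree-count tables).
#' @export
build_null <- function(ds, n_replicates = 1000, seed = 1, thresholds = NULL,
                       keep_weights = c("auto", "always", "never"),
                       budget = 5e7, base = 2) {
  keep_weights <- match.arg(keep_weights)
  if (n_replicates < 1L) stop_validation("n_replicates must be >= 1")
  m <- n_snps(ds)
  npairs <- m * (m - 1L) / 2
  keep <- switch(keep_weights,
                 always = TRUE,
                 never = FALSE,
                 auto = npairs * n_replicates <= budget)
  if (keep_weights == "auto" && !keep)
    warning(sprintf(paste0("storing %d x %d null weights exceeds the budget (%g); ",
                           "keeping summaries only - matched-pair p-values will be unavailable"),
                    npairs, n_replicates, budget))
  weights <- if (keep) matrix(NA_real_, npairs, n_replicates) else NULL
  max_weight <- numeric(n_replicates)
  summaries <- vector("list", n_replicates)
  degrees <- vector("list", n_replicates)
  idx <- pair_indices(m)
  for (r in seq_len(n_replicates)) {
    ds_r <- permute_phenotype(ds, seed = seed + r)
    w <- pair_weights(ds_r, base = base)$ig
    if (keep) weights[, r] <- w
    max_weight[r] <- max(w)
    if (!is.null(thresholds)) {
      st <- sweep_stats(idx$i, idx$j, w, thresholds)
      summaries[[r]] <- cbind(replicate = r, st$stats)
      degrees[[r]] <- st$degrees
    }
  }
  structure(list(n_replicates = n_replicates, seed = seed,
                 snp_ids = ds$snp_ids, base = base,
                 weights = weights, max_weight = max_weight,
                 thresholds = thresholds,
                 summaries = if (!is.null(thresholds))
                   do.call(rbind, summaries) else NULL,
                 degrees = if (!is.null(thresholds)) degrees else NULL),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("null_ensemble: %d replicates (seed %d), %d SNPs, weights %s, %s\n",
              x$n_replicates, x$seed, length(x$snp_ids),
              if (is.null(x$weights)) "summarised" else "stored",
              if (is.null(x$thresholds)) "no threshold summaries"
              else sprintf("%d thresholds", length(x$thresholds))))
  invisible(x)
}

#' Per-pair permutation p-values
#'
#' Matched by pair: the p-value of pair (i, j) is the fraction of null
#' replicates whose weight for that same pair exceeds the observed one.
#' The default `"strict"` estimator counts strictly greater null
#' weights, so an observation above every replicate scores exactly 0;
#' `"nonstrict"` counts ties as exceedances; `"add_one"` is
#' `(b + 1) / (R + 1)`, which never returns 0 and is the conventional
#' finite-sample-valid estimator.
#'
#' @param pw the observed [pair_weights()] table.
#' @param null a [build_null()] ensemble with stored weights.
#' @param method p-value estimator (see Details).
#' @return `pw` with a `p_value` column filled in.
#' @export
pair_pvalues <- function(pw, null, method = c("strict", "nonstrict", "add_one")) {
  method <- match.arg(method)
  if (is.null(null$weights))
    stop_validation("null ensemble has no stored weights; rebuild with keep_weights = 'always'")
  if (!identical(attr(pw, "snp_ids"), null$snp_ids))
    stop_validation("pair table and null ensemble describe different SNP panels")
  if (nrow(pw) != nrow(null$weights))
    stop_validation("pair missing from null: %d observed pairs vs %d null rows",
                    nrow(pw), nrow(null$weights))
  R <- null$n_replicates
  exceed <- rowSums(null$weights > pw$ig)
  pw$p_value <- switch(method,
                       strict = exceed / R,
                       nonstrict = rowSums(null$weights >= pw$ig) / R,
                       add_one = (exceed + 1) / (R + 1))
  pw
}

#' Permutation p-values for network-level properties
#'
#' For each threshold of the grid and each of the properties edge count,
#' vertex count and largest-component size, the p-value is the fraction
#' of null replicates whose property value is at least the observed one.
#'
#' @param sweep_real a [threshold_sweep()] of the observed data.
#' @param null a [build_null()] ensemble whose `thresholds` match
#'   `sweep_real$threshold` exactly.
#' @return A data frame with columns `threshold`, `p_edges`,
#'   `p_vertices`, `p_lcc`.
#' @export
property_pvalues <- function(sweep_real, null) {
  if (is.null(null$summaries))
    stop_validation("null ensemble was built without threshold summaries")
  if (!isTRUE(all.equal(sweep_real$threshold, null$thresholds)))
    stop_validation("threshold grids of the sweep and the null ensemble differ")
  R <- null$n_replicates
  s <- null$summaries
  one <- function(prop, k) {
    t_k <- sweep_real$threshold[k]
    mean(s[s$threshold == t_k, prop] >= sweep_real[[prop]][k])
  }
  data.frame(threshold = sweep_real$threshold,
             p_edges = vapply(seq_len(nrow(sweep_real)),
                              function(k) one("n_edges", k), numeric(1)),
             p_vertices = vapply(seq_len(nrow(sweep_real)),
                                 function(k) one("n_vertices", k), numeric(1)),
             p_lcc = vapply(seq_len(nrow(sweep_real)),
                            function(k) one("lcc_size", k), numeric(1)))
}

#' Write null-ensemble summaries as TSV
#'
#' One row per (replicate, threshold): `replicate`, `threshold`,
#' `n_edges`, `n_vertices`, `lcc_size`. Degree histograms go to a second
#' file as `replicate`, `threshold`, `degree`, `count` when present.
#'
#' @param null a [build_null()] ensemble with threshold summaries.
#' @param path summary TSV path.
#' @param degree_path optional degree-histogram TSV path.
#' @return `path`, invisibly.
#' @export
write_null_summaries <- function(null, path, degree_path = NULL) {
  if (is.null(null$summaries))
    stop_validation("null ensemble was built without threshold summaries")
  con <- file(path, "w")
  writeLines(provenance_header(seed = null$seed,
                               extra = sprintf("replicates=%d", null$n_replicates)), con)
  utils::write.table(null$summaries, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  if (!is.null(degree_path)) {
    rows <- list()
    for (r in seq_along(null$degrees))
      for (k in seq_along(null$thresholds)) {
        dc <- null$degrees[[r]][[k]]
        if (length(dc))
          rows[[length(rows) + 1L]] <- data.frame(
            replicate = r, threshold = null$thresholds[k],
            degree = as.integer(names(dc)), count = as.integer(dc))
      }
    con <- file(degree_path, "w")
    writeLines(provenance_header(seed = null$seed), con)
    utils::write.table(do.call(rbind, rows) %||%
                         data.frame(replicate = integer(), threshold = numeric(),
                                    degree = integer(), count = integer()),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(path)
}
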