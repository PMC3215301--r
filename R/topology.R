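# Degree-distribution models: power law (scale-free) vs zero-truncated
# Poisson (random attachment), least-squares fits and Kolmogorov-Smirnov
# tests with parametric-bootstrap p-values.
#
# The scientific question: does the degree distribution of the network
# look like c * d^-gamma (hubs present, scale-free) or like a Poisson
# distribution conditioned on d >= 1 (what random edge attachment to all
# m SNPs yields after discarding the isolated ones)? The detection flag
# is "power law plausible AND truncated Poisson rejected".

#' Fit a power law to a degree distribution
#'
#' Fits `p(d) = c * d^-gamma` by least squares. Two protocols are
#' shipped because a single least-squares sentence underdetermines the
#' procedure:
#' \describe{
#'   \item{`nonlinear_lsq_with_zeros` (default)}{minimises
#'     `sum_{d=1}^{d_max} (p(d) - c d^-gamma)^2` over the full degree
#'     range 1..d_max, including degrees with no vertices (`p(d) = 0`) —
#'     the literal reading of fitting the points for d from 1 to the
#'     highest nonzero degree.}
#'   \item{`loglog_linear_regression`}{ordinary least squares of
#'     `log p(d)` on `log d` over the nonzero points only.}
#' }
#' Reports always name the protocol used.
#'
#' @param dd a [degree_dist()] object with at least 3 distinct degrees.
#' @param protocol fit protocol (see Details).
#' @return An object of class `power_law_fit`: list with `c`, `gamma`,
#'   `protocol`, `domain` (`1:d_max`).
#' @export
fit_power_law <- function(dd,
                          protocol = c("nonlinear_lsq_with_zeros",
                                       "loglog_linear_regression")) {
  protocol <- match.arg(protocol)
  if (length(dd$degree) < 3L)
    stop_validation("power-law fit needs at least 3 distinct degrees, got %d",
                    length(dd$degree))
  d_max <- max(dd$degree)
  # log-log OLS over nonzero points; closed form, also the NLS start
  ll <- stats::lm.fit(cbind(1, log(dd$degree)), log(dd$p))
  c_ll <- unname(exp(ll$coefficients[1]))
  g_ll <- unname(max(-ll$coefficients[2], 0))
  if (protocol == "loglog_linear_regression") {
    fit <- list(c = unname(c_ll), gamma = unname(g_ll))
  } else {
    d_all <- seq_len(d_max)
    p_all <- numeric(d_max)
    p_all[dd$degree] <- dd$p
    df <- data.frame(d = d_all, p = p_all)
    fit <- tryCatch({
      nl <- minpack.lm::nlsLM(p ~ cc * d^(-gg), data = df,
                              start = list(cc = c_ll, gg = max(g_ll, 1e-6)),
                              lower = c(1e-12, 0),
                              control = minpack.lm::nls.lm.control(maxiter = 200))
      co <- stats::coef(nl)
      list(c = unname(co["cc"]), gamma = unname(co["gg"]))
    }, error = function(e) {
      sse <- function(par) sum((p_all - exp(par[1]) * d_all^(-par[2]))^2)
      op <- stats::optim(c(log(c_ll), max(g_ll, 1e-6)), sse,
                         method = "Nelder-Mead",
                         control = list(reltol = 1e-14, maxit = 5000))
      list(c = exp(op$par[1]), gamma = op$par[2])
    })
  }
  structure(c(fit, list(protocol = protocol, domain = seq_len(d_max))),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power-law fit (%s): p(d) = %.4g * d^-%.4g on d = 1..%d\n",
              x$protocol, x$c, x$gamma, max(x$domain)))
  invisible(x)
}

# Model pmf of a power-law fit normalised over its fit domain (the
# constant c cancels in the normalisation).
power_law_pmf <- function(fit, domain = fit$domain) {
  q <- domain^(-fit$gamma)
  q / sum(q)
}

# KS statistic between a degree distribution and a model pmf given over
# the same support grid: sup over grid points of |ECDF - model CDF|.
ks_stat_discrete <- function(dd, support, pmf) {
  emp <- numeric(length(support))
  emp[match(dd$degree, support)] <- dd$p
  max(abs(cumsum(emp) - cumsum(pmf)))
}

# Asymptotic (continuous-case) Kolmogorov p-value, for reference only:
# degrees are discrete and parameters estimated, so the bootstrap p is
# the one to use.
kolmogorov_p <- function(stat, n) {
  x <- (sqrt(n) + 0.12 + 0.11 / sqrt(n)) * stat
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2))
  min(max(p, 0), 1)
}

# Parametric bootstrap KS p-value: sample n degrees from the fitted
# model, refit by the same protocol, recompute the statistic. Shared by
# both model families via closures.
ks_bootstrap <- function(obs_stat, n, sample_fn, stat_fn, n_boot, seed) {
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      for (try in 1:20) {
        smp <- sample_fn(n)
        st <- stat_fn(smp)
        if (!is.na(st)) return(st)
      }
      NA_real_  # degenerate resamples 20 times in a row: drop replicate
    }, numeric(1))
  })
  boot <- boot[!is.na(boot)]
  list(ks_p = mean(boot >= obs_stat), n_boot = length(boot))
}

#' Kolmogorov-Smirnov test of a power-law degree fit
#'
#' Statistic: the largest absolute difference between the empirical
#' degree CDF and the model CDF, with the model normalised over the fit
#' domain `1..d_max`. Because the parameters are estimated from the same
#' data and degrees are discrete, the p-value is estimated by parametric
#' bootstrap: `n_boot` samples of `n_vertices` degrees are drawn from
#' the fitted model, the model is refitted to each by the same protocol,
#' and the p-value is the fraction of bootstrap statistics at least as
#' large as the observed one. The asymptotic continuous-case p-value is
#' also reported, for reference only.
#'
#' @param dd the [degree_dist()] the fit was computed from.
#' @param fit a [fit_power_law()] result.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return List with `ks_stat`, `ks_p`, `ks_p_asymptotic`, `n_boot`,
#'   `seed`.
#' @export
power_law_ks <- function(dd, fit, n_boot = 1000, seed = 1) {
  support <- fit$domain
  pmf <- power_law_pmf(fit)
  obs <- ks_stat_discrete(dd, support, pmf)
  n <- dd$n_vertices
  sample_fn <- function(n) sample(support, n, replace = TRUE, prob = pmf)
  stat_fn <- function(smp) {
    tb <- table(smp)
    dd_b <- degree_dist_from_counts(as.integer(names(tb)), as.integer(tb))
    if (length(dd_b$degree) < 3L) return(NA_real_)
    fit_b <- fit_power_law(dd_b, protocol = fit$protocol)
    ks_stat_discrete(dd_b, fit_b$domain, power_law_pmf(fit_b))
  }
  bt <- ks_bootstrap(obs, n, sample_fn, stat_fn, n_boot, seed)
  list(ks_stat = obs, ks_p = bt$ks_p,
       ks_p_asymptotic = kolmogorov_p(obs, n),
       n_boot = bt$n_boot, seed = seed)
}

#' Zero-truncated (adjusted) Poisson probability mass function
#'
#' The degree law of random edge attachment after removing degree-zero
#' vertices: `P0(d) = lambda^d e^-lambda / (k d!)` for `d >= 1` and
#' `P0(0) = 0`, where `k = 1 - e^-lambda` renormalises the distribution.
#'
#' @param d non-negative integer degree(s).
#' @param lambda positive Poisson mean (the average degree over all SNPs
#'   before zero-degree removal).
#' @return `P0(d)`.
#' @export
truncated_poisson_pmf <- function(d, lambda) {
  if (any(d < 0)) stop_validation("degree must be >= 0, got %s", min(d))
  if (lambda <= 0) stop_validation("lambda must be positive, got %g", lambda)
  ifelse(d == 0, 0, stats::dpois(d, lambda) / (1 - exp(-lambda)))
}

# Truncation point covering all but < 1e-12 of the P0 tail.
tp_support_cap <- function(lambda) max(stats::qpois(1 - 1e-13, lambda) + 2L, 10L)

#' Fit the zero-truncated Poisson degree model
#'
#' Random attachment of `|E|` edges to all `m_total` SNPs gives mean
#' degree `lambda = 2|E| / m_total`; removing the degree-zero vertices
#' leaves the zero-truncated Poisson [truncated_poisson_pmf()]. The
#' denominator is the total SNP count, not the surviving vertex count,
#' because the attachment happens before isolated vertices are removed.
#' The KS test against `P0` uses the same parametric bootstrap as
#' [power_law_ks()] (sample `n_vertices` degrees from `P0`, re-estimate
#' `lambda` from the bootstrap degree sum, recompute the statistic).
#'
#' @param dd a [degree_dist()] object.
#' @param m_total total number of SNPs in the panel (>= `n_vertices`).
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return An object of class `truncated_poisson_fit`: list with
#'   `lambda`, `k` (`= 1 - e^-lambda`), `ks_stat`, `ks_p`,
#'   `ks_p_asymptotic`, `n_boot`, `seed`.
#' @export
fit_truncated_poisson <- function(dd, m_total, n_boot = 1000, seed = 1) {
  if (m_total < dd$n_vertices)
    stop_validation("m_total (%d) is smaller than the vertex count (%d)",
                    m_total, dd$n_vertices)
  lambda <- sum(dd$degree * dd$count) / m_total
  d_max <- max(dd$degree)
  support <- seq_len(max(d_max, tp_support_cap(lambda)))
  obs <- ks_stat_discrete(dd, support, truncated_poisson_pmf(support, lambda))
  cap <- tp_support_cap(lambda * 3 + 1)
  samp_support <- seq_len(cap)
  samp_pmf <- truncated_poisson_pmf(samp_support, lambda)
  samp_pmf <- samp_pmf / sum(samp_pmf)
  sample_fn <- function(n) sample(samp_support, n, replace = TRUE, prob = samp_pmf)
  stat_fn <- function(smp) {
    lam_b <- sum(smp) / m_total
    tb <- table(smp)
    dd_b <- degree_dist_from_counts(as.integer(names(tb)), as.integer(tb))
    sup_b <- seq_len(max(max(dd_b$degree), tp_support_cap(lam_b)))
    ks_stat_discrete(dd_b, sup_b, truncated_poisson_pmf(sup_b, lam_b))
  }
  bt <- ks_bootstrap(obs, dd$n_vertices, sample_fn, stat_fn, n_boot, seed)
  structure(list(lambda = lambda, k = 1 - exp(-lambda),
                 ks_stat = obs, ks_p = bt$ks_p,
                 ks_p_asymptotic = kolmogorov_p(obs, dd$n_vertices),
                 n_boot = bt$n_boot, seed = seed),
            class = "truncated_poisson_fit")
}

#' @export
print.truncated_poisson_fit <- function(x, ...) {
  cat(sprintf("zero-truncated Poisson fit: lambda = %.4g (k = %.4g), KS = %.4g, bootstrap p = %.4g\n",
              x$lambda, x$k, x$ks_stat, x$ks_p))
  invisible(x)
}

#' Ranked threshold report over the sweep grid
#'
#' For every threshold of the grid this combines, per network:
#' permutation p-values of the edge count, vertex count and largest
#' component ([property_pvalues()]); the dominant-component indicator
#' (largest component more than twice the size of the second largest);
#' and, where the degree distribution supports a fit, the power-law and
#' zero-truncated-Poisson KS outcomes. Three flags are derived:
#' \describe{
#'   \item{`flag_properties`}{edge and vertex counts significant at
#'     `prop_alpha` (default 0.01) against the permutation null;}
#'   \item{`flag_dominant`}{a dominant largest component is present;}
#'   \item{`flag_scale_free`}{power law plausible (`ks_p > alpha`) while
#'     the truncated Poisson is rejected (`ks_p <= alpha`), at
#'     `alpha` = 0.05 by default.}
#' }
#' Thresholds are ranked by the number of satisfied flags (ties to the
#' higher threshold); no scalar score is invented — the choice among
#' top-ranked thresholds is left to the user.
#'
#' When the pair table carries p-values, the degree-distribution fits
#' are computed on the significance-filtered network (edges with
#' `p <= edge_alpha`), mirroring the use of the filtered graph for
#' topology reading; property comparisons always use the unfiltered
#' network, matching how the null summaries are built.
#'
#' @param pw observed [pair_weights()], optionally with `p_value`.
#' @param mains a [main_effects()] table.
#' @param null a [build_null()] ensemble with summaries on the same
#'   grid.
#' @param m_total total SNP count (for the Poisson mean).
#' @param alpha significance level for the topology (KS) flags.
#' @param prop_alpha significance level for the property flag.
#' @param edge_alpha per-edge significance filter for the fitted graph.
#' @param n_boot KS bootstrap replicates per threshold (kept modest by
#'   default; raise for final reports).
#' @param seed integer seed.
#' @return A data frame of class `topology_report`, one row per
#'   threshold, ranked; columns include the properties, p-values, fit
#'   parameters, `protocol`, the three flags and `n_flags`.
#' @export
topology_report <- function(pw, mains, null, m_total = length(attr(pw, "snp_ids")),
                            alpha = 0.05, prop_alpha = 0.01, edge_alpha = 0.01,
                            n_boot = 200, seed = 1) {
  if (is.null(null$summaries))
    stop_validation("null ensemble was built without threshold summaries")
  grid <- null$thresholds
  sweep_real <- threshold_sweep(pw, t_max = max(grid), t_min = min(grid),
                                step = if (length(grid) > 1L)
                                  round(grid[1] - grid[2], 12) else 1)
  if (!isTRUE(all.equal(sweep_real$threshold, grid)))
    stop_validation("threshold grid of the null is not a uniform descending grid")
  pp <- property_pvalues(sweep_real, null)
  comp <- attr(sweep_real, "components")
  has_p <- "p_value" %in% names(pw)
  rows <- lapply(seq_along(grid), function(k) {
    cs <- comp[[k]]
    second <- if (length(cs) >= 2L) cs[2] else 0L
    dominant <- length(cs) >= 1L && cs[1] > 2 * second
    g <- build_graph(pw, mains, grid[k])
    if (has_p) g <- filter_significant(g, edge_alpha)
    fitted <- igraph::vcount(g) > 0L
    pl_g <- pl_ksp <- tp_lam <- tp_ksp <- NA_real_
    protocol <- NA_character_
    if (fitted) {
      dd <- degree_dist(g)
      if (length(dd$degree) >= 3L) {
        fit <- fit_power_law(dd)
        protocol <- fit$protocol
        pl_g <- fit$gamma
        pl_ksp <- power_law_ks(dd, fit, n_boot = n_boot,
                               seed = seed + k)$ks_p
        tp <- fit_truncated_poisson(dd, m_total, n_boot = n_boot,
                                    seed = seed + 1000L + k)
        tp_lam <- tp$lambda
        tp_ksp <- tp$ks_p
      }
    }
    data.frame(threshold = grid[k],
               n_edges = sweep_real$n_edges[k],
               n_vertices = sweep_real$n_vertices[k],
               lcc_size = sweep_real$lcc_size[k],
               second_component = second,
               p_edges = pp$p_edges[k], p_vertices = pp$p_vertices[k],
               p_lcc = pp$p_lcc[k],
               powerlaw_gamma = pl_g, powerlaw_ks_p = pl_ksp,
               poisson_lambda = tp_lam, poisson_ks_p = tp_ksp,
               protocol = protocol,
               flag_properties = pp$p_edges[k] <= prop_alpha &&
                 pp$p_vertices[k] <= prop_alpha,
               flag_dominant = dominant,
               flag_scale_free = !is.na(pl_ksp) && !is.na(tp_ksp) &&
                 pl_ksp > alpha && tp_ksp <= alpha,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rep$n_flags <- rep$flag_properties + rep$flag_dominant + rep$flag_scale_free
  rep <- rep[order(-rep$n_flags, -rep$threshold), ]
  rownames(rep) <- NULL
  structure(rep, class = c("topology_report", "data.frame"))
}
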