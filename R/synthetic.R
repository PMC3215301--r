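# Synthetic case-control genotype data with known planted structure.
#
# The generator emulates a candidate-gene case-control panel: background
# SNPs draw genotypes from Hardy-Weinberg proportions independently of
# each other and of the phenotype (no linkage disequilibrium), while a
# minority of SNP pairs carries a planted penetrance model. Individuals
# are sampled retrospectively: population draws are accepted until the
# requested case and control quotas fill, so the sample case fraction is
# fixed by design, exactly as in a case-control study.

#' Penetrance model for one SNP or one SNP pair
#'
#' Specifies `P(case | genotype)` for 3 genotypes (one SNP) or a 3 x 3
#' genotype-combination table (a pair), together with the minor-allele
#' frequencies that imply Hardy-Weinberg genotype priors
#' `((1-q)^2, 2q(1-q), q^2)`. Custom genotype priors may override HWE
#' (e.g. equiprobable genotypes for analytic fixtures).
#'
#' @param table numeric vector of length 3 or 3 x 3 matrix of
#'   probabilities in `[0, 1]`; rows index the first SNP's genotype.
#' @param mafs allele frequencies in `(0, 0.5]`, one per SNP slot.
#' @param genotype_priors optional list of per-SNP genotype prior
#'   vectors (each length 3, summing to 1) replacing HWE.
#' @return An object of class `penetrance_model`.
#' @export
penetrance_model <- function(table, mafs = rep(0.5, if (is.matrix(table)) 2L else 1L),
                             genotype_priors = NULL) {
  if (is.matrix(table)) {
    if (!all(dim(table) == c(3L, 3L)))
      stop_validation("pair penetrance table must be 3 x 3")
    k <- 2L
  } else {
    if (length(table) != 3L)
      stop_validation("single-SNP penetrance table must have 3 entries")
    k <- 1L
  }
  if (any(table < 0 | table > 1))
    stop_validation("penetrances must lie in [0, 1]")
  if (length(mafs) != k)
    stop_validation("%d maf(s) supplied for a %d-SNP model", length(mafs), k)
  if (any(mafs <= 0 | mafs > 0.5))
    stop_validation("minor allele frequencies must lie in (0, 0.5]")
  priors <- if (is.null(genotype_priors)) {
    lapply(mafs, function(q) c((1 - q)^2, 2 * q * (1 - q), q^2))
  } else {
    if (length(genotype_priors) != k)
      stop_validation("need %d genotype prior vectors", k)
    lapply(genotype_priors, function(p) {
      if (length(p) != 3L || abs(sum(p) - 1) > 1e-9 || any(p < 0))
        stop_validation("each genotype prior must be 3 non-negative values summing to 1")
      p
    })
  }
  structure(list(table = table, mafs = mafs, n_snps = k, priors = priors),
            class = "penetrance_model")
}

#' Named penetrance presets
#'
#' \describe{
#'   \item{`parity_xor`}{pair model: `P(case) = high` when the two
#'     genotypes have opposite parity (one heterozygous, one not),
#'     `low` otherwise. At `maf = 0.5` the marginal penetrances are
#'     flat, so the pair is detectable only through its interaction.}
#'   \item{`pure_epistasis`}{the parity checkerboard with `maf` pinned
#'     at 0.5 — zero marginal penetrance difference by construction,
#'     exercising the observation that interaction hubs need not carry
#'     main effects.}
#'   \item{`main_effect`}{single-SNP additive model:
#'     `P(case | g) = low + g (high - low) / 2`.}
#' }
#'
#' @param name preset name.
#' @param high,low penetrances of the risk / baseline genotype classes.
#'   Defaults 0.7 / 0.3: a strong, clearly detectable planted effect.
#' @param maf allele frequency (ignored by `pure_epistasis`).
#' @return A [penetrance_model()].
#' @export
penetrance_preset <- function(name = c("parity_xor", "pure_epistasis", "main_effect"),
                              high = 0.7, low = 0.3, maf = 0.5) {
  name <- match.arg(name)
  parity <- outer(0:2, 0:2, function(a, b) (a %% 2) != (b %% 2))
  switch(name,
         parity_xor = penetrance_model(ifelse(parity, high, low),
                                       mafs = c(maf, maf)),
         pure_epistasis = penetrance_model(ifelse(parity, high, low),
                                           mafs = c(0.5, 0.5)),
         main_effect = penetrance_model(low + (0:2) * (high - low) / 2,
                                        mafs = maf))
}

#' Simulation design for a synthetic case-control panel
#'
#' Holds the panel size, the case/control quotas, the planted models
#' with their SNP-slot assignments, and the background allele-frequency
#' range. The default scale (100 SNPs, 200 cases / 300 controls) is the
#' reduced test scale; `study_scale = TRUE` switches to the full
#' candidate-panel scale of 1422 SNPs with 491 cases and 791 controls.
#' SNP slots must be distinct within a model; models may share slots
#' (that is how line and star motifs arise).
#'
#' @param m_snps panel size.
#' @param n_cases,n_controls class quotas.
#' @param models list of `list(model = <penetrance_model>, snps = <indices>)`.
#' @param maf_range background minor-allele-frequency range; each
#'   background SNP draws its frequency uniformly from it.
#' @param seed integer seed stored with the design.
#' @param study_scale if `TRUE`, override the size arguments with the
#'   full study scale.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(m_snps = 100, n_cases = 200, n_controls = 300,
                              models = list(), maf_range = c(0.05, 0.5),
                              seed = 1, study_scale = FALSE) {
  if (study_scale) {
    m_snps <- 1422L; n_cases <- 491L; n_controls <- 791L
  }
  if (n_cases < 1L || n_controls < 1L)
    stop_validation("need at least one case and one control")
  for (pm in models) {
    if (!inherits(pm$model, "penetrance_model"))
      stop_validation("each planted entry needs a `model` of class penetrance_model")
    if (length(pm$snps) != pm$model$n_snps)
      stop_validation("model spans %d SNP(s) but %d slot(s) assigned",
                      pm$model$n_snps, length(pm$snps))
    if (anyDuplicated(pm$snps))
      stop_validation("a model's SNP slots must be distinct")
    if (any(pm$snps < 1L | pm$snps > m_snps))
      stop_validation("planted SNP slot outside 1..%d", m_snps)
  }
  structure(list(m_snps = as.integer(m_snps), n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls), models = models,
                 maf_range = maf_range, seed = as.integer(seed)),
            class = "simulation_design")
}

#' Plant a motif of penetrance models
#'
#' Builds the model list for the interaction motifs seen in component
#' structure: an isolated `pair`, a `line` (consecutive SNPs chained by
#' pair models sharing interior SNPs) or a `star` (one hub SNP paired
#' with every leaf).
#'
#' @param type motif shape.
#' @param snps SNP indices: 2 for a pair, >= 3 for a line, hub first
#'   then leaves for a star.
#' @param model a two-SNP [penetrance_model()] reused for every edge of
#'   the motif.
#' @return A list suitable for the `models` argument of
#'   [simulation_design()].
#' @export
plant_motif <- function(type = c("pair", "line", "star"), snps,
                        model = penetrance_preset("parity_xor")) {
  type <- match.arg(type)
  if (model$n_snps != 2L) stop_validation("motifs are built from two-SNP models")
  edges <- switch(type,
                  pair = {
                    if (length(snps) != 2L) stop_validation("a pair motif needs 2 SNPs")
                    list(snps)
                  },
                  line = {
                    if (length(snps) < 3L) stop_validation("a line motif needs >= 3 SNPs")
                    lapply(seq_len(length(snps) - 1L),
                           function(k) snps[k:(k + 1L)])
                  },
                  star = {
                    if (length(snps) < 3L) stop_validation("a star motif needs a hub and >= 2 leaves")
                    lapply(snps[-1], function(leaf) c(snps[1], leaf))
                  })
  lapply(edges, function(e) list(model = model, snps = as.integer(e)))
}

# P(case | planted genotypes) for a block of draws; `pg` is draws x
# planted-slots. Multiple models covering an individual contribute the
# mean of their penetrances (an averaging rule, so shared-SNP motifs
# stay well-defined probabilities).
planted_penetrance <- function(design, pg, slot_of) {
  k <- nrow(pg)
  if (!length(design$models)) return(rep(0.5, k))
  acc <- matrix(0, k, length(design$models))
  for (mi in seq_along(design$models)) {
    pm <- design$models[[mi]]
    cols <- slot_of[as.character(pm$snps)]
    if (pm$model$n_snps == 1L) {
      acc[, mi] <- pm$model$table[pg[, cols[1]] + 1L]
    } else {
      acc[, mi] <- pm$model$table[cbind(pg[, cols[1]] + 1L, pg[, cols[2]] + 1L)]
    }
  }
  rowMeans(acc)
}

draw_hwe <- function(n, prior) sample(0:2, n, replace = TRUE, prob = prior)

#' Generate a synthetic case-control genotype dataset
#'
#' Retrospective rejection sampling: population individuals are drawn
#' (planted-SNP genotypes from the model priors, disease status from
#' the planted penetrance, background SNPs phenotype-independent) until
#' exactly `n_cases` cases and `n_controls` controls accumulate.
#' Sampling is capped at 10^7 population draws; an unsatisfiable design
#' (e.g. all-zero penetrance with a positive case quota) errors out
#' early. Deterministic given the seed. With no planted models all SNPs
#' are null and the phenotype is assigned independently of every
#' genotype.
#'
#' @param design a [simulation_design()].
#' @param seed integer seed; defaults to the design's.
#' @return A [genotype_dataset()] with attribute `planted` (list of the
#'   planted SNP index vectors) and attribute `design`.
#' @export
generate_dataset <- function(design, seed = design$seed) {
  with_seed(seed, {
    m <- design$m_snps
    n_cases <- design$n_cases
    n_controls <- design$n_controls
    n <- n_cases + n_controls
    planted <- sort(unique(unlist(lapply(design$models, `[[`, "snps"))))
    slot_of <- stats::setNames(seq_along(planted), as.character(planted))

    # per-planted-SNP genotype priors (first model mentioning the SNP wins)
    planted_prior <- lapply(planted, function(s) {
      for (pm in design$models) {
        hit <- match(s, pm$snps)
        if (!is.na(hit)) return(pm$model$priors[[hit]])
      }
    })

    if (length(design$models)) {
      probe <- as.matrix(expand.grid(rep(list(0:2), length(planted))))
      pen_range <- range(planted_penetrance(design, probe, slot_of))
      if (pen_range[2] == 0 && n_cases > 0)
        stop_validation("unsatisfiable design: planted penetrance is identically 0")
      if (pen_range[1] == 1 && n_controls > 0)
        stop_validation("unsatisfiable design: planted penetrance is identically 1")
    }

    if (!length(design$models)) {
      geno_p <- matrix(integer(0), n, 0)
      phen <- sample(rep(c("case", "control"), c(n_cases, n_controls)))
    } else {
      got_case <- 0L; got_ctrl <- 0L; drawn <- 0L
      keep_g <- vector("list", 0)
      keep_c <- logical(0)
      batch <- max(1000L, 4L * n)
      while ((got_case < n_cases || got_ctrl < n_controls) && drawn < 1e7) {
        pg <- vapply(planted_prior, function(pr) draw_hwe(batch, pr),
                     integer(batch))
        pg <- matrix(pg, nrow = batch)
        pen <- planted_penetrance(design, pg, slot_of)
        is_case <- stats::runif(batch) < pen
        need_case <- is_case & (got_case + cumsum(is_case) <= n_cases)
        need_ctrl <- !is_case & (got_ctrl + cumsum(!is_case) <= n_controls)
        take <- need_case | need_ctrl
        if (any(take)) {
          keep_g[[length(keep_g) + 1L]] <- pg[take, , drop = FALSE]
          keep_c <- c(keep_c, is_case[take])
          got_case <- got_case + sum(need_case)
          got_ctrl <- got_ctrl + sum(need_ctrl)
        }
        drawn <- drawn + batch
      }
      if (got_case < n_cases || got_ctrl < n_controls)
        stop_validation("unsatisfiable design: quotas unmet after %d population draws", drawn)
      geno_p <- do.call(rbind, keep_g)
      phen <- ifelse(keep_c, "case", "control")
    }

    geno <- matrix(NA_integer_, n, m)
    if (length(planted)) geno[, planted] <- geno_p
    background <- setdiff(seq_len(m), planted)
    if (length(background)) {
      mafs_bg <- stats::runif(length(background), design$maf_range[1],
                              design$maf_range[2])
      for (k in seq_along(background)) {
        q <- mafs_bg[k]
        geno[, background[k]] <- draw_hwe(n, c((1 - q)^2, 2 * q * (1 - q), q^2))
      }
    }
    rownames(geno) <- sprintf("ind_%d", seq_len(n))
    ds <- genotype_dataset(geno, phen, sprintf("SNP_%04d", seq_len(m)))
    attr(ds, "planted") <- lapply(design$models, `[[`, "snps")
    attr(ds, "design") <- design
    ds
  })
}

#' Exact population information gain of a planted pair
#'
#' The analytic oracle for the pair weight under retrospective sampling:
#' with genotype-combination priors `prior(g)` and penetrance
#' `P(case | g)`, the within-class genotype distributions are
#' proportional to `prior(g) P(case|g)` (cases) and
#' `prior(g) (1 - P(case|g))` (controls), and the class prior is the
#' sample case fraction. The information gain is evaluated by exhaustive
#' enumeration of the 9 genotype combinations; finite-sample estimates
#' from [generate_dataset()] converge to this value as the sample grows.
#'
#' @param model a two-SNP [penetrance_model()].
#' @param case_fraction sample case fraction in `(0, 1)`.
#' @param base logarithm base (2 = bits).
#' @return The exact `IG(A;B;C)` in the chosen unit.
#' @export
expected_ig <- function(model, case_fraction, base = 2) {
  if (!inherits(model, "penetrance_model") || model$n_snps != 2L)
    stop_validation("expected_ig() requires a two-SNP penetrance model")
  if (case_fraction <= 0 || case_fraction >= 1)
    stop_validation("case_fraction must lie strictly between 0 and 1")
  prior <- outer(model$priors[[1]], model$priors[[2]])  # P(g_A, g_B)
  pen <- model$table
  w_case <- prior * pen
  w_ctrl <- prior * (1 - pen)
  if (sum(w_case) == 0 || sum(w_ctrl) == 0)
    stop_validation("degenerate model: one class has zero population probability")
  p_case <- case_fraction * w_case / sum(w_case)   # joint P(g, case)
  p_ctrl <- (1 - case_fraction) * w_ctrl / sum(w_ctrl)
  joint <- cbind(case = as.vector(p_case), control = as.vector(p_ctrl))
  h <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p, base = base))
  }
  hc <- h(colSums(joint))
  i_of <- function(marg) hc - sum(vapply(seq_len(nrow(marg)), function(r) {
    pr <- sum(marg[r, ])
    if (pr == 0) 0 else pr * h(marg[r, ] / pr)
  }, numeric(1)))
  # marginalise the 9-cell joint over each SNP
  ga <- rep(1:3, 3)  # row index of prior matrix for each joint cell (a-major? see below)
  gb <- rep(1:3, each = 3)
  # as.vector on a 3x3 matrix is column-major: cell k has g_A = ga[k], g_B = gb[k]
  marg_a <- rowsum(joint, ga)
  marg_b <- rowsum(joint, gb)
  i_of(joint) - i_of(marg_a) - i_of(marg_b)
}

#' Read or write a simulation design as JSON
#'
#' Serialises the design (sizes, quotas, planted models with their
#' penetrance tables, mafs and slots, background maf range, seed) so
#' simulated datasets are reproducible from a small text config.
#'
#' @param design a [simulation_design()].
#' @param path JSON path.
#' @return `write_design()` returns `path` invisibly; `read_design()`
#'   the reconstructed [simulation_design()].
#' @export
write_design <- function(design, path) {
  payload <- list(
    m_snps = design$m_snps, n_cases = design$n_cases,
    n_controls = design$n_controls, maf_range = design$maf_range,
    seed = design$seed,
    models = lapply(design$models, function(pm) list(
      snps = pm$snps,
      table = if (is.matrix(pm$model$table)) unclass(pm$model$table)
              else as.numeric(pm$model$table),
      mafs = pm$model$mafs,
      priors = pm$model$priors)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  models <- lapply(p$models, function(pm) {
    raw <- pm$table
    tab <- if (length(raw) && length(raw[[1]]) == 3L) {
      # pair model: rows were written as arrays of 3
      do.call(rbind, lapply(raw, function(r) as.numeric(unlist(r))))
    } else as.numeric(unlist(raw))
    priors <- lapply(pm$priors, function(x) as.numeric(unlist(x)))
    list(model = penetrance_model(tab, mafs = as.numeric(unlist(pm$mafs)),
                                  genotype_priors = priors),
         snps = as.integer(unlist(pm$snps)))
  })
  simulation_design(m_snps = p$m_snps, n_cases = p$n_cases,
                    n_controls = p$n_controls, models = models,
                    maf_range = as.numeric(unlist(p$maf_range)), seed = p$seed)
}
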