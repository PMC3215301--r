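---
title: "Statistical epistasis networks: models, choices and limits"
author: "episnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical epistasis networks: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episnet)
```

## The model

`episnet` treats a case-control genotype panel as a joint distribution
over a three-level genotype variable per SNP and a binary class. The
main-effect weight of SNP $A$ is the mutual information
$I(A;C) = H(C) - H(C|A)$, with $H(C|A)$ summed over the six
(genotype, class) cells; the pair weight is the information gain

$$IG(A;B;C) = I(A,B;C) - I(A;C) - I(B;C),$$

where the joint term runs over the nine two-SNP genotype combinations.
$IG$ is positive when the pair is synergetic (the joint genotype says
more about disease status than its parts), negative when the two
genotypes carry redundant class information, and zero under independence
or a synergy/redundancy balance. All probabilities are plug-in
frequencies: no pseudocounts, no bias correction. That choice keeps the
estimator simple and exactly reproducible, at the price of the usual
positive bias of plug-in information estimates — which is precisely why
all downstream inference is calibrated against phenotype permutations
of the *same* data rather than against asymptotic distributions.

Networks $G_t$ connect pairs with $IG \ge t$ (ties at exactly $t$ are
included); a SNP is a vertex only while it has at least one incident
edge. This membership convention matters: vertex counts, component
sizes and degree distributions all refer to the sub-panel that actually
interacts at level $t$, and every degree is $\ge 1$ by construction.
Isolated SNPs are not "degree-zero vertices" but non-members.

## Assumptions

* The phenotype is strictly binary; multi-class phenotypes are refused
  at validation.
* Genotypes are a 3-level categorical. The 0/1/2 codes are allele
  counts by convention, but nothing in the method depends on allele
  orientation, dosage ordering, or which allele is minor — so the
  package performs no orientation logic.
* Under the permutation null, individuals are exchangeable: the
  shuffle preserves genotypes and class totals and severs every
  genotype-phenotype association. Covariate structure (age or sex
  matching, population stratification) is *not* preserved; stratified
  permutations are out of scope.
* No multiple-testing correction is applied across the $\binom{m}{2}$
  pairs. The edge filter is the raw per-pair permutation p-value
  (default $\alpha = 0.01$), matching how the filtered network
  $\hat G_t$ is defined. Individual edges should therefore never be
  read as genome-wide-significant findings; the inferential unit is the
  network-level comparison against the permutation ensemble.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| log base | 2 | bits | "log" is ambiguous in information measures; bits are the convention in the interaction-analysis literature. Nats (`base = exp(1)`) are supported, and all thresholds in a run are read in the configured unit. |
| threshold grid | 0.02 → 0 by 0.001 | bits | spans the observable pair-weight range of candidate-panel data; a finer grid costs nothing but adds nothing below the weight resolution. |
| permutations `R` | 1000 | — | resolves p-values to 0.001, the scale at which the edge filter (0.01) operates comfortably. |
| edge significance `alpha` | 0.01 | — | the $\hat G_t$ filter. |
| topology flags `alpha` | 0.05 | — | conventional level for the KS decisions; the property flag uses the stricter 0.01 because it feeds the threshold choice directly. |
| KS bootstrap `n_boot` | 1000 (200 in reports) | — | 1000 resolves p to 0.001 for final numbers; per-threshold reports default lower since they are screened, not quoted. |

## Permutation p-values

Three estimators are available for the per-pair p-value. The default is
the strict exceedance fraction $\#\{w_r > w_{obs}\}/R$ — the literal
matched-pair definition, under which a pair above every replicate gets
exactly 0. Because $p = 0$ is awkward for downstream consumers, the
add-one estimator $(b+1)/(R+1)$ (never zero, finite-sample valid) and
the non-strict variant are offered. Nulls are *matched by pair*: each
pair is compared against its own permutation distribution. A pooled
mode would mix pairs with different genotype margins and is not the
default reading of the per-pair comparison; matched-pair mode requires
storing the full $\binom{m}{2} \times R$ weight matrix, so
`build_null()` falls back to summary-only storage (with a warning) when
the configured budget is exceeded.

## Degree-distribution models

Two hypotheses are fitted to the degree distribution of each network:

* **Power law** $p(d) = c\,d^{-\gamma}$, the scale-free signature.
  Least squares underdetermines the procedure, so two protocols ship
  and every report names the one used:
  `nonlinear_lsq_with_zeros` (default) minimises the squared pmf error
  over the full range $1..d_{max}$ including degrees with no vertices;
  `loglog_linear_regression` regresses $\log p$ on $\log d$ over the
  nonzero points.
* **Zero-truncated Poisson** $P_0(d) = \lambda^d e^{-\lambda} /
  ((1-e^{-\lambda})\,d!)$, the degree law of attaching $|E|$ edges at
  random to all $m$ SNPs and then discarding isolated vertices. The
  mean uses the all-SNP denominator, $\lambda = 2|E|/m$, because the
  attachment happens *before* zero-degree removal; using the surviving
  vertex count instead would conflate the model with its conditioning.

Goodness of fit is a discrete KS statistic (sup over support points of
the CDF gap, model normalised over the fit domain) with a parametric
bootstrap: sample `n_vertices` degrees from the fitted model, refit by
the same protocol, recompute. This accounts for both discreteness and
parameter estimation, neither of which the classical KS p-value
tolerates; the asymptotic p is still reported, marked as reference
only.

The two protocols genuinely differ in calibration, and on the published
319-vertex degree table they bracket the published analysis: the
zero-inclusive nonlinear protocol reproduces the reported exponent
($\gamma \approx 2.01$) but its bootstrap test is stringent enough to
reject, while the log-log protocol ($\gamma \approx 2.31$) yields a
bootstrap KS p-value in close agreement with the reported plausibility
of the power law. The acceptance script therefore quotes the exponent
from the nonlinear protocol and the directional KS conclusion (power
law plausible, truncated Poisson firmly rejected) under the log-log
calibration, and prints both. Users comparing against published network
analyses should expect exactly this kind of protocol sensitivity and
always report the protocol.

## The synthetic-data generator

The generator emulates a candidate-gene case-control panel:

* background SNPs draw genotypes from Hardy-Weinberg proportions with
  allele frequencies uniform on (0.05, 0.5), independent across SNPs
  and of the phenotype — i.e. **no linkage disequilibrium**, matching a
  method that makes no LD adjustment;
* planted penetrance models assign $P(\text{case} \mid \text{genotype})$
  for chosen SNP slots; when several models cover an individual (line
  and star motifs share SNPs), their penetrances are **averaged**, the
  simplest rule that keeps shared-slot motifs well-defined
  probabilities without inflating marginal effects;
* individuals are sampled retrospectively: population draws are
  accepted until the case and control quotas fill (capped at $10^7$
  draws, with an early unsatisfiability check), so the sample case
  fraction is a design constant, exactly as in a case-control study.

The default planted effect (`parity_xor`, penetrances 0.7/0.3 at
maf 0.5) is a pure interaction: marginal penetrances are flat, so the
pair is invisible to single-SNP scans — the configuration the method
exists to find. `expected_ig()` gives the exact population information
gain of any planted pair under retrospective sampling by enumerating
the nine genotype cells, serving as an analytic oracle that
finite-sample estimates must approach.

What passing tests on this generator do **not** show: robustness to LD
(correlated background SNPs can produce clusters of redundant negative-
or positive-IG pairs), to covariate confounding, to genotyping error
beyond missingness, or to penetrance models outside the planted family.
Real panels should expect the permutation machinery to remain valid
(it conditions on the observed genotypes) but the synthetic recovery
rates to be optimistic.

## Numerical choices

* Entropy sums use the $0 \log(1/0) = 0$ convention throughout —
  required for sparse 9×2 tables.
* Plug-in mutual information is mathematically non-negative; floating
  residues in $(-10^{-12}, 0)$ are clamped to 0. Information gains are
  left unclamped (they are legitimately negative).
* Probability-vector validation tolerates $10^{-9}$ in the sum;
  truncated-Poisson normalisation is verified to $10^{-9}$ with the
  tail cut below $10^{-12}$ mass.
* Threshold grids are snapped to 12 decimals so that descending
  arithmetic never drops a grid point to floating-point drift.
* Modal-genotype imputation breaks ties toward the lowest genotype
  code: deterministic and reproducible, and pooled over cases and
  controls (per-class imputation would leak phenotype information into
  the genotypes).
* Exhaustive pair scoring is vectorised as per-genotype class-indicator
  cross-products, keeping memory at $O(m^2)$ (the size of the answer)
  rather than $O(m^2 n)$, and making the result independent of pair
  evaluation order.
* Per-replicate permutation seeds are `seed + replicate`, so replicates
  are independent, reproducible, and order-invariant under any
  execution schedule.
* Degenerate inputs fail with typed validation errors naming the
  offending row/column/SNP: non-{0,1,2,NA} genotype cells, single-class
  phenotypes, all-missing SNPs, inconsistent count tables, power-law
  fits on fewer than 3 distinct degrees.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` run at sizes the package
treats as its reference conditions: the study-scale bookkeeping panel
(1,422 SNPs, 491 cases / 791 controls) for counting identities; a
20-SNP / 200-individual / 200-permutation configuration (pooled over
ten panels) for null-calibration of p-values; 50 panels of 100 SNPs and
500 individuals for planted-pair recovery; and a 50,000-individual
two-SNP panel for oracle convergence. These sizes make every check
cheap enough to run routinely while keeping the statistical content of
each claim.

## Known limitations

* Strictly pairwise: higher-order interactions enter only insofar as
  they induce pairwise signal; a pure three-way interaction with flat
  two-way margins is invisible. Connected components are a heuristic
  guide to where higher-order structure may live, not a test for it.
* Quadratic cost in panel size; designed for candidate panels, not
  GWAS-scale data.
* No automated motif census beyond component sizes, and no layout
  (DOT export delegates rendering to Graphviz).
* The threshold report ranks by count of satisfied flags and
  deliberately refuses to collapse them into a single score; the final
  threshold choice is a judgement call left to the analyst.
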