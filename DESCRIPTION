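Package: episnet
Title: Statistical Epistasis Networks from Case-Control SNP Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and analyses statistical epistasis networks from
    case-control genotype data. Every single-nucleotide polymorphism (SNP)
    receives a main-effect weight (mutual information with the disease
    class) and every unordered SNP pair an interaction weight (information
    gain), computed exhaustively. Phenotype permutations provide per-pair
    significance and a null distribution for network-level properties.
    Networks are assembled over a descending threshold grid; connected
    components and vertex degree distributions are compared against the
    permutation null, and degree distributions are tested against
    power-law (scale-free) and zero-truncated Poisson (random attachment)
    models with parametric-bootstrap Kolmogorov-Smirnov procedures. A
    synthetic-data generator with known planted epistatic penetrance
    models, plus an exact population-level information-gain oracle, makes
    the whole pipeline testable without access to protected genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
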