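# Case-control genotype container, readers/writers, imputation, counting.

#' Construct a case-control genotype dataset
#'
#' The container every other function in the package consumes: an
#' individuals-by-SNPs matrix of diploid genotypes coded 0/1/2 (allele
#' counts; the method only needs a 3-level categorical, so no allele
#' orientation is attempted), a binary case/control phenotype, and unique
#' SNP identifiers. Missing genotypes are held as `NA` until
#' [impute_missing()] replaces them.
#'
#' @param genotypes integer (or coercible) matrix, one row per individual,
#'   one column per SNP; entries in `{0, 1, 2, NA}`.
#' @param phenotype character or factor of length `nrow(genotypes)` with
#'   values `"case"`/`"control"`.
#' @param snp_ids character vector of unique SNP identifiers; defaults to
#'   `colnames(genotypes)`.
#' @return An object of class `genotype_dataset`: a list with elements
#'   `snp_ids`, `genotypes` (integer matrix) and `phenotype` (factor with
#'   levels case, control).
#' @seealso [read_genotypes()], [impute_missing()], [class_counts()]
#' @export
genotype_dataset <- function(genotypes, phenotype, snp_ids = colnames(genotypes)) {
  if (!is.matrix(genotypes))
    stop_validation("`genotypes` must be a matrix, got %s", class(genotypes)[1])
  storage.mode(genotypes) <- "integer"
  bad <- matrix(!(genotypes %in% c(0L, 1L, 2L, NA_integer_)),
                nrow(genotypes))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop_validation("genotype value '%s' at row %d, column %d is not in {0,1,2,NA}",
                    genotypes[idx[1], idx[2]], idx[1], idx[2])
  }
  if (is.null(snp_ids))
    snp_ids <- sprintf("SNP_%04d", seq_len(ncol(genotypes)))
  snp_ids <- as.character(snp_ids)
  if (length(snp_ids) != ncol(genotypes))
    stop_validation("%d snp_ids for %d genotype columns",
                    length(snp_ids), ncol(genotypes))
  dup <- snp_ids[duplicated(snp_ids)]
  if (length(dup))
    stop_validation("duplicate SNP id(s): %s", paste(unique(dup), collapse = ", "))
  phenotype <- as.character(phenotype)
  if (length(phenotype) != nrow(genotypes))
    stop_validation("phenotype length %d does not match %d individuals",
                    length(phenotype), nrow(genotypes))
  if (!all(phenotype %in% c("case", "control")))
    stop_validation("phenotype values must be 'case' or 'control'; got '%s'",
                    setdiff(unique(phenotype), c("case", "control"))[1])
  phenotype <- factor(phenotype, levels = c("case", "control"))
  if (nrow(genotypes) < 2L)
    stop_validation("need at least 2 individuals, got %d", nrow(genotypes))
  if (nlevels(droplevels(phenotype)) < 2L)
    stop_validation("phenotype has a single class ('%s'); both cases and controls are required",
                    as.character(phenotype[1]))
  colnames(genotypes) <- snp_ids
  structure(list(snp_ids = snp_ids, genotypes = genotypes, phenotype = phenotype),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d individuals (%d cases / %d controls), %d SNPs, %d missing genotypes\n",
              n_individuals(x), n_cases(x), n_controls(x), n_snps(x),
              sum(is.na(x$genotypes))))
  invisible(x)
}

#' Dataset dimensions
#'
#' @param ds a [genotype_dataset()].
#' @return Integer counts.
#' @export
n_individuals <- function(ds) nrow(ds$genotypes)

#' @rdname n_individuals
#' @export
n_snps <- function(ds) ncol(ds$genotypes)

#' @rdname n_individuals
#' @export
n_cases <- function(ds) sum(ds$phenotype == "case")

#' @rdname n_individuals
#' @export
n_controls <- function(ds) sum(ds$phenotype == "control")

#' Read a case-control genotype table
#'
#' Parses the package's delimited dialect: a header row
#' `ID, STATUS, <snp1>, ..., <snpM>` followed by one row per individual.
#' `STATUS` is 1 for cases and 0 for controls; genotype cells are
#' `0`, `1`, `2`, `NA` or empty (missing). Lines starting with `#` are
#' treated as comments. Malformed cells raise a validation error naming
#' the offending row and column.
#'
#' @param path path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A [genotype_dataset()].
#' @export
read_genotypes <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  if (!file.exists(path)) stop_validation("file does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop_validation("file %s has no data rows", path)
  header <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  if (length(header) < 3L || toupper(header[1]) != "ID" || toupper(header[2]) != "STATUS")
    stop_validation("malformed header in %s: expected 'ID%sSTATUS%s<snp ids>'",
                    path, sep, sep)
  snp_ids <- header[-(1:2)]
  rows <- strsplit(lines[-1], sep, fixed = TRUE)
  n <- length(rows)
  m <- length(snp_ids)
  geno <- matrix(NA_integer_, n, m)
  status <- integer(n)
  ids <- character(n)
  for (r in seq_len(n)) {
    f <- rows[[r]]
    # a trailing empty field is dropped by strsplit; pad it back
    if (length(f) == m + 1L) f <- c(f, "")
    if (length(f) != m + 2L)
      stop_validation("row %d has %d fields, expected %d", r, length(f), m + 2L)
    ids[r] <- f[1]
    if (!f[2] %in% c("0", "1"))
      stop_validation("row %d (%s): STATUS '%s' is not 0 or 1", r, f[1], f[2])
    status[r] <- as.integer(f[2])
    cells <- f[-(1:2)]
    cells[cells == "" | toupper(cells) == "NA"] <- NA_character_
    ok <- is.na(cells) | cells %in% c("0", "1", "2")
    if (!all(ok)) {
      j <- which(!ok)[1]
      stop_validation("row %d (%s), column %s: genotype '%s' is not in {0,1,2,NA}",
                      r, f[1], snp_ids[j], cells[j])
    }
    geno[r, ] <- as.integer(cells)
  }
  rownames(geno) <- ids
  genotype_dataset(geno, ifelse(status == 1L, "case", "control"), snp_ids)
}

#' Write a genotype dataset in the package's delimited dialect
#'
#' Output re-reads identically with [read_genotypes()] (missing genotypes
#' round-trip as `NA`). A provenance comment header is prepended.
#'
#' @param ds a [genotype_dataset()].
#' @param path output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @param header extra comment lines (without the leading `#`).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(ds, path, dialect = c("tsv", "csv"), header = NULL) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(extra = header), con)
  writeLines(paste(c("ID", "STATUS", ds$snp_ids), collapse = sep), con)
  ids <- rownames(ds$genotypes) %||% sprintf("ind_%d", seq_len(n_individuals(ds)))
  status <- ifelse(ds$phenotype == "case", "1", "0")
  cells <- ds$genotypes
  mode(cells) <- "character"
  cells[is.na(cells)] <- "NA"
  body <- apply(cbind(ids, status, cells), 1L, paste, collapse = sep)
  writeLines(body, con)
  invisible(path)
}

#' Read a PLINK additive-coded .raw file
#'
#' Secondary input dialect: whitespace-delimited with columns
#' `FID IID PAT MAT SEX PHENOTYPE` followed by one column per SNP holding
#' additive genotype codes 0/1/2 (`NA` allowed). `PHENOTYPE` 2 maps to
#' case, 1 to control.
#'
#' @param path path to the `.raw` file.
#' @return A [genotype_dataset()].
#' @export
read_plink_raw <- function(path) {
  if (!file.exists(path)) stop_validation("file does not exist: %s", path)
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                      check.names = FALSE),
    error = function(e) stop_validation("malformed .raw file %s: %s", path,
                                        conditionMessage(e)))
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (ncol(tab) < 7L || !identical(toupper(colnames(tab)[1:6]), fixed))
    stop_validation("malformed .raw header: expected columns %s then SNPs",
                    paste(fixed, collapse = " "))
  phen <- tab$PHENOTYPE
  if (!all(phen %in% c(1, 2)))
    stop_validation("PHENOTYPE values must be 1 (control) or 2 (case); got %s",
                    setdiff(unique(phen), c(1, 2))[1])
  geno <- as.matrix(tab[, -(1:6), drop = FALSE])
  rownames(geno) <- tab$IID
  genotype_dataset(geno, ifelse(phen == 2, "case", "control"),
                   colnames(tab)[-(1:6)])
}

#' Impute missing genotypes with the population modal genotype
#'
#' Each missing entry of a SNP is replaced by the most common genotype of
#' that SNP computed over the non-missing entries of the whole sample,
#' cases and controls pooled. Ties between equally common genotypes break
#' toward the lowest genotype code, so the result is deterministic. The
#' operation is idempotent.
#'
#' @param ds a [genotype_dataset()].
#' @return A [genotype_dataset()] with no missing entries.
#' @export
impute_missing <- function(ds) {
  geno <- ds$genotypes
  for (j in seq_len(ncol(geno))) {
    col <- geno[, j]
    nas <- is.na(col)
    if (!any(nas)) next
    if (all(nas))
      stop_validation("SNP %s has no observed genotypes; cannot impute", ds$snp_ids[j])
    counts <- tabulate(col[!nas] + 1L, nbins = 3L)
    # which.max returns the first maximum: lowest genotype code wins ties
    geno[nas, j] <- which.max(counts) - 1L
  }
  ds$genotypes <- geno
  ds
}

#' Genotype-by-class contingency counts
#'
#' For a single SNP, the 3 x 2 table of genotype (0/1/2) by class
#' (case/control) counts; for an ordered SNP pair, the 9 x 2 table over
#' joint genotypes `(g_A, g_B)`. These tables carry the empirical
#' frequencies that the entropy-based weights are computed from; their
#' cells always sum to the number of individuals.
#'
#' @param ds an imputed [genotype_dataset()].
#' @param snps one index (or SNP id) for a single-SNP table, or two for a
#'   pair table.
#' @return An integer matrix with genotype rows and columns
#'   `case`, `control`.
#' @export
class_counts <- function(ds, snps) {
  if (is.character(snps)) {
    idx <- match(snps, ds$snp_ids)
    if (anyNA(idx))
      stop_validation("unknown SNP id(s): %s",
                      paste(snps[is.na(idx)], collapse = ", "))
    snps <- idx
  }
  snps <- as.integer(snps)
  if (!length(snps) %in% 1:2)
    stop_validation("`snps` must name one SNP or one pair, got %d entries",
                    length(snps))
  if (any(snps < 1L | snps > n_snps(ds)))
    stop_validation("SNP index out of range 1..%d: %s", n_snps(ds),
                    paste(snps[snps < 1L | snps > n_snps(ds)], collapse = ", "))
  g <- ds$genotypes[, snps, drop = FALSE]
  if (anyNA(g))
    stop_validation("dataset has missing genotypes; run impute_missing() first")
  case <- ds$phenotype == "case"
  if (length(snps) == 1L) {
    lev <- factor(g[, 1], levels = 0:2)
    out <- cbind(case = tabulate(as.integer(lev[case]), 3L),
                 control = tabulate(as.integer(lev[!case]), 3L))
    rownames(out) <- as.character(0:2)
  } else {
    joint <- 3L * g[, 1] + g[, 2] + 1L  # a-major: (g_A, g_B)
    out <- cbind(case = tabulate(joint[case], 9L),
                 control = tabulate(joint[!case], 9L))
    rownames(out) <- paste(rep(0:2, each = 3), rep(0:2, 3), sep = ":")
  }
  storage.mode(out) <- "integer"
  out
}
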