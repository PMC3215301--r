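test_that("the TSV dialect parses and round-trips exactly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_toy_tsv(path, c("ID\tSTATUS\trs1\trs2\trs3",
                        "i1\t1\t0\t1\t2",
                        "i2\t0\t2\tNA\t0",
                        "i3\t1\t1\t\t1"))
  ds <- read_genotypes(path)
  expect_s3_class(ds, "genotype_dataset")
  expect_equal(n_individuals(ds), 3L)
  expect_equal(n_snps(ds), 3L)
  expect_equal(ds$snp_ids, c("rs1", "rs2", "rs3"))
  expect_equal(as.character(ds$phenotype), c("case", "control", "case"))
  expect_equal(unname(ds$genotypes[, "rs2"]), c(1L, NA, NA))

  out <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(ds, out)
  ds2 <- read_genotypes(out)
  expect_identical(unname(ds2$genotypes), unname(ds$genotypes))
  expect_identical(ds2$phenotype, ds$phenotype)
  expect_identical(ds2$snp_ids, ds$snp_ids)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(ds, csv, dialect = "csv")
  expect_identical(unname(read_genotypes(csv, "csv")$genotypes),
                   unname(ds$genotypes))
})

test_that("malformed input raises typed errors naming the offending cell", {
  bad_geno <- withr::local_tempfile()
  write_toy_tsv(bad_geno, c("ID\tSTATUS\trs1\trs2",
                            "i1\t1\t0\t1", "i2\t0\t3\t2"))
  err <- expect_error(read_genotypes(bad_geno), class = "episnet_validation_error")
  expect_match(conditionMessage(err), "row 2")
  expect_match(conditionMessage(err), "rs1")
  expect_match(conditionMessage(err), "'3'")

  one_class <- withr::local_tempfile()
  write_toy_tsv(one_class, c("ID\tSTATUS\trs1", "i1\t1\t0", "i2\t1\t1"))
  expect_error(read_genotypes(one_class), "single class",
               class = "episnet_validation_error")

  dup <- withr::local_tempfile()
  write_toy_tsv(dup, c("ID\tSTATUS\trs1\trs1", "i1\t1\t0\t1", "i2\t0\t1\t2"))
  expect_error(read_genotypes(dup), "duplicate",
               class = "episnet_validation_error")

  bad_header <- withr::local_tempfile()
  write_toy_tsv(bad_header, c("NAME\tPHENO\trs1", "i1\t1\t0", "i2\t0\t1"))
  expect_error(read_genotypes(bad_header), "header",
               class = "episnet_validation_error")

  bad_status <- withr::local_tempfile()
  write_toy_tsv(bad_status, c("ID\tSTATUS\trs1", "i1\t2\t0", "i2\t0\t1"))
  expect_error(read_genotypes(bad_status), "STATUS",
               class = "episnet_validation_error")
})

test_that("the PLINK .raw additive dialect is accepted", {
  path <- withr::local_tempfile(fileext = ".raw")
  write_toy_tsv(path, c("FID IID PAT MAT SEX PHENOTYPE rs10_A rs11_C",
                        "f1 p1 0 0 1 2 0 2",
                        "f2 p2 0 0 2 1 1 NA",
                        "f3 p3 0 0 1 2 2 0"))
  ds <- read_plink_raw(path)
  expect_equal(ds$snp_ids, c("rs10_A", "rs11_C"))
  expect_equal(as.character(ds$phenotype), c("case", "control", "case"))
  expect_equal(unname(ds$genotypes[, 1]), c(0L, 1L, 2L))
  expect_true(is.na(ds$genotypes[2, 2]))

  bad <- withr::local_tempfile(fileext = ".raw")
  write_toy_tsv(bad, c("FID IID PAT MAT SEX PHENOTYPE rs1",
                       "f1 p1 0 0 1 0", "f2 p2 0 0 1 2"))
  expect_error(read_plink_raw(bad), class = "episnet_validation_error")
})

test_that("imputation uses the pooled population mode with low-code ties", {
  g <- cbind(a = c(0L, 0L, 1L, NA),
             b = c(2L, 2L, 2L, 2L),
             c = c(0L, 1L, 1L, NA))
  ds <- genotype_dataset(g, c("case", "case", "control", "control"))
  imp <- impute_missing(ds)
  expect_equal(unname(imp$genotypes[4, "a"]), 0L)  # mode of {0,0,1}
  expect_equal(unname(imp$genotypes[, "b"]), rep(2L, 4))  # untouched
  expect_equal(unname(imp$genotypes[4, "c"]), 1L)  # mode of {0,1,1}
  expect_false(anyNA(imp$genotypes))

  # tie between genotype 0 and 1 resolves to the lower code, matching a
  # one-line mode oracle
  tie <- genotype_dataset(cbind(x = c(0L, 0L, 1L, 1L, NA)),
                          c("case", "case", "control", "control", "case"))
  expect_equal(unname(impute_missing(tie)$genotypes[5, 1]), 0L)
  expect_equal(unname(impute_missing(tie)$genotypes[5, 1]),
               oracle_mode(tie$genotypes[, 1]))

  # pooled across classes: the case-only mode would be 1, the pooled mode 0
  pooled <- genotype_dataset(cbind(x = c(1L, 1L, 0L, 0L, 0L, NA)),
                             c("case", "case", "control", "control",
                               "control", "case"))
  expect_equal(unname(impute_missing(pooled)$genotypes[6, 1]), 0L)
})

test_that("imputation is idempotent and rejects all-missing SNPs", {
  ds <- random_tiny_ds(8, 4, seed = 11)
  ds$genotypes[cbind(c(1, 3, 5), c(1, 2, 4))] <- NA_integer_
  once <- impute_missing(ds)
  expect_identical(impute_missing(once), once)

  allna <- genotype_dataset(cbind(ok = c(0L, 1L), bad = c(NA, NA)),
                            c("case", "control"))
  expect_error(impute_missing(allna), "bad", class = "episnet_validation_error")
})

test_that("class counts are exact contingency tables summing to n", {
  ds <- genotype_dataset(cbind(s = c(0L, 0L, 2L, 2L)),
                         c("case", "case", "control", "control"))
  cc <- class_counts(ds, 1)
  expect_identical(dim(cc), c(3L, 2L))
  expect_equal(cc["0", "case"], 2L)
  expect_equal(cc["2", "control"], 2L)
  expect_equal(sum(cc), 4L)
  expect_equal(sum(cc == 0L), 4L)

  # pair counts on the XOR fixture: one individual per joint genotype
  px <- class_counts(xor9_ds(), c("A", "B"))
  expect_identical(dim(px), c(9L, 2L))
  expect_true(all(rowSums(px) == 1L))
  expect_equal(unname(colSums(px)), c(4L, 5L))

  expect_error(class_counts(ds, 5), "out of range",
               class = "episnet_validation_error")
  miss <- genotype_dataset(cbind(s = c(0L, NA, 2L)),
                           c("case", "control", "control"))
  expect_error(class_counts(miss, 1), "impute",
               class = "episnet_validation_error")
})

test_that("count tables sum to n for every SNP and pair of a random dataset", {
  ds <- random_tiny_ds(9, 4, seed = 3)
  for (j in seq_len(n_snps(ds)))
    expect_equal(sum(class_counts(ds, j)), 9L)
  idx <- pair_indices(n_snps(ds))
  for (k in seq_len(nrow(idx)))
    expect_equal(sum(class_counts(ds, c(idx$i[k], idx$j[k]))), 9L)
})

test_that("dataset construction enforces its invariants", {
  expect_error(genotype_dataset(cbind(a = c(0L, 3L)), c("case", "control")),
               "not in", class = "episnet_validation_error")
  expect_error(genotype_dataset(cbind(a = c(0L, 1L)), c("case", "case")),
               "single class", class = "episnet_validation_error")
  expect_error(genotype_dataset(cbind(a = 0L), "case"),
               class = "episnet_validation_error")
  expect_error(genotype_dataset(matrix(0L, 2, 2), c("case", "control"),
                                c("x", "x")),
               "duplicate", class = "episnet_validation_error")
})
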