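test_that("expression tables parse with order preserved and bad input rejected", {
  vals <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
                 dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  p <- write_expr_tsv(vals, withr::local_tempfile(fileext = ".tsv"))
  m <- read_expression_table(p, "FPKM")
  expect_identical(dim(unclass(m)), c(3L, 2L))
  expect_identical(rownames(m), c("g1", "g2", "g3"))
  expect_identical(colnames(m), c("s1", "s2"))
  expect_equal(unclass(m)["g2", "s2"], 5)

  # duplicated gene id
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1", "g1\t1", "g1\t2"), p2)
  expect_error(read_expression_table(p2, "FPKM"), "duplicated gene id")

  # negative entry names the offending gene and sample
  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tsA\tsB", "g1\t1\t2", "g2\t-1.0\t3"), p3)
  expect_error(read_expression_table(p3, "FPKM"), "g2.*sA")

  # non-numeric cell
  p4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tsA", "g1\tx"), p4)
  expect_error(read_expression_table(p4, "FPKM"), "non-numeric")
})

test_that("FPKM to TPM conversion normalises every sample to one million", {
  m <- expr_matrix(matrix(c(1, 1, 2), 3, 1,
                          dimnames = list(c("a", "b", "c"), "s1")), "FPKM")
  tpm <- fpkm_to_tpm(m)
  expect_equal(unname(unclass(tpm)[, 1]), c(250000, 250000, 500000))
  expect_identical(expr_units(tpm), "TPM")

  # all-zero sample is degenerate
  m0 <- expr_matrix(matrix(c(1, 2, 0, 0), 2, 2,
                           dimnames = list(c("a", "b"), c("s1", "s2"))), "FPKM")
  expect_error(fpkm_to_tpm(m0), "s2")

  # property: column sums equal 1e6 for random non-negative input
  set.seed(42)
  vals <- matrix(rexp(500), 50, 10,
                 dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:10)))
  tpm2 <- fpkm_to_tpm(expr_matrix(vals, "FPKM"))
  expect_equal(unname(colSums(tpm2)), rep(1e6, 10), tolerance = 1e-9)
})

test_that("log2(TPM+1) maps anchor points exactly and round-trips", {
  vals <- matrix(c(0, 1, 7, 3), 2, 2,
                 dimnames = list(c("g1", "g2"), c("s1", "s2")))
  lg <- log2p1_transform(expr_matrix(vals, "TPM"))
  expect_equal(unname(as.matrix(lg)), matrix(c(0, 1, 3, 2), 2, 2))
  expect_error(log2p1_transform(lg), "units")

  set.seed(7)
  vals2 <- matrix(rexp(200, 1 / 50), 20, 10,
                  dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10)))
  lg2 <- log2p1_transform(expr_matrix(vals2, "TPM"))
  expect_equal(2^as.matrix(lg2) - 1, vals2, tolerance = 1e-10)
})

test_that("zero-fraction filter removes exactly the genes above the strict threshold", {
  # 5 genes with tumour zero fractions 0, 0.1, 0.21, 0.5, 1.0 (n = 100), all
  # nonzero in normal: exactly the > 0.20 ones are removed
  n <- 100
  zf <- c(0, 0.1, 0.21, 0.5, 1.0)
  tum <- t(sapply(zf, function(f) c(rep(0, round(f * n)), rep(2, n - round(f * n)))))
  nor <- matrix(1, 5, n)
  rownames(tum) <- rownames(nor) <- paste0("g", 1:5)
  co <- toy_cohort(tum, nor)
  res <- filter_by_zero_fraction(co, 0.20)
  expect_identical(res$removed_gene_ids, c("g3", "g4", "g5"))
  expect_identical(rownames(res$cohort$tumour), c("g1", "g2"))

  # boundary case: exactly 20% zeros in both tissues is retained (strict >)
  tum2 <- matrix(c(rep(0, 2), rep(1, 8)), 1, 10)
  rownames(tum2) <- "gx"
  co2 <- toy_cohort(tum2, tum2)
  expect_identical(filter_by_zero_fraction(co2, 0.20)$removed_gene_ids, character(0))
  # but 3 zeros in 10 tumour samples (30%) is removed
  tum3 <- matrix(c(rep(0, 3), rep(1, 7)), 1, 10)
  rownames(tum3) <- "gy"
  expect_identical(filter_by_zero_fraction(toy_cohort(tum3, tum3 + 1), 0.20)$removed_gene_ids, "gy")

  # a zero fraction above threshold in the normal tissue alone also removes
  co3 <- toy_cohort(tum2 + 1, tum3)
  expect_identical(filter_by_zero_fraction(co3, 0.20)$removed_gene_ids, "gx")

  # threshold 0 removes every gene containing any zero; threshold at the max
  # observed fraction removes nothing
  set.seed(3)
  tz <- matrix(rbinom(20 * 12, 1, 0.7) * rexp(240), 20, 12)
  rownames(tz) <- sprintf("g%02d", 1:20)
  co4 <- toy_cohort(tz, tz)
  any_zero <- rowSums(tz == 0) > 0
  expect_identical(filter_by_zero_fraction(co4, 0)$removed_gene_ids,
                   rownames(tz)[any_zero])
  fmax <- max(rowMeans(tz == 0))
  expect_identical(filter_by_zero_fraction(co4, fmax)$removed_gene_ids, character(0))
})

test_that("paired cohorts keep only complete patients, aligned by patient", {
  vals <- matrix(seq_len(10), 2, 5,
                 dimnames = list(c("g1", "g2"),
                                 c("t1", "n1", "t2", "n2", "t3")))
  m <- expr_matrix(vals, "LOG2TPM1")
  sheet <- data.frame(
    sample_id = c("t1", "n1", "t2", "n2", "t3"),
    patient_id = c("A", "A", "B", "B", "C"),
    tissue = c("Tumour", "normal", "tumor", "NORMAL", "tumour"))
  co <- build_paired_cohort(m, sheet)
  expect_identical(co$patient_ids, c("A", "B"))
  expect_identical(co$dropped_patients, "C")
  expect_identical(colnames(co$tumour), c("t1", "t2"))
  expect_identical(colnames(co$normal), c("n1", "n2"))
  expect_identical(rownames(co$tumour), rownames(co$normal))
  expect_identical(expr_units(co$tumour), expr_units(co$normal))

  # sample missing from the sheet is a metadata error
  expect_error(build_paired_cohort(m, sheet[-5, ]), "absent from sample sheet")
  # no complete pair at all
  expect_error(build_paired_cohort(m, within(sheet, patient_id <- LETTERS[1:5])),
               "no patient")
})
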