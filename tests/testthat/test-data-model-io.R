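test_that("genotype TSV reader computes MAF and preserves sample order", {
  path <- writeTempTsv(c(
    "snp_id\tchrom\tpos\ts1\ts2",
    "snpA\tchr1\t100\t0\t2"))
  g <- readGenotypes(path, "tsv")
  expect_equal(unname(rowData(g)$maf), 0.5)
  expect_equal(colnames(g), c("s1", "s2"))

  path3 <- writeTempTsv(c(
    "snp_id\tchrom\tpos\ts1\ts2\ts3",
    "snpA\tchr1\t100\t0\t0\t1"))
  g3 <- readGenotypes(path3, "tsv")
  expect_equal(unname(rowData(g3)$maf), 1 / 6)
})

test_that("genotype TSV reader rejects malformed input", {
  bad <- writeTempTsv(c(
    "snp_id\tchrom\tpos\ts1\ts2",
    "snpA\tchr1\t100\t0"))
  expect_error(readGenotypes(bad, "tsv"), "line 2")
  outOfRange <- writeTempTsv(c(
    "snp_id\tchrom\tpos\ts1\ts2",
    "snpA\tchr1\t100\t0\t2.5"))
  expect_error(readGenotypes(outOfRange, "tsv"), "\\[0, 2\\]")
})

test_that("VCF GT calls convert to ALT-allele dosages", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    paste("chr1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/1", "1|1", sep = "\t"),
    paste("chr1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
          "0/0", "0/1", sep = "\t")), path)
  g <- readGenotypes(path, "vcf")
  expect_equal(unname(assay(g, "dosage")["rs1", ]), c(1, 2))
  expect_equal(unname(assay(g, "dosage")["rs2", ]), c(0, 1))
  expect_equal(unname(rowData(g)$pos), c(100L, 200L))

  missing <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", sep = "\t"),
    paste("chr1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "./.", sep = "\t")), missing)
  expect_error(readGenotypes(missing, "vcf"), "missing GT")
})

test_that("MAF agrees with a brute-force allele count", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(5:40, 1); p <- sample(3:15, 1)
    d <- matrix(sample(0:2, n * p, replace = TRUE), p, n,
                dimnames = list(paste0("s", 1:p), paste0("i", 1:n)))
    g <- GenotypeSet(d, rep("chr1", p), seq_len(p))
    brute <- apply(d, 1, function(v) {
      f <- sum(v) / (2 * length(v)); min(f, 1 - f)
    })
    expect_equal(unname(rowData(g)$maf), unname(brute), tolerance = 1e-12)
  }
})

test_that("omics matrix TSV round trip is faithful to 12 significant digits", {
  set.seed(2)
  m <- matrix(exp(rnorm(12, 0, 4)), 3, 4,
              dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
  x <- OmicsSet(m, "expression_log2")
  path <- tempfile(fileext = ".tsv")
  writeOmicsMatrix(x, path)
  back <- readOmicsMatrix(path, "expression_log2")
  expect_equal(assay(back), m, tolerance = 1e-12)
})

test_that("matrix reader rejects duplicates, bad cells and out-of-range betas", {
  dup <- writeTempTsv(c("probe_id\ts1", "p1\t0.5", "p1\t0.6"))
  expect_error(readOmicsMatrix(dup, "methylation_beta"), "duplicate")
  bad <- writeTempTsv(c("probe_id\ts1\ts2", "p1\t0.5\tfoo"))
  expect_error(readOmicsMatrix(bad, "methylation_beta"), "p1.*s2")
  over <- writeTempTsv(c("probe_id\ts1", "p1\t1.0000000001"))
  expect_error(readOmicsMatrix(over, "methylation_beta"), "\\[0, 1\\]")
})

test_that("an empty matrix is a valid degenerate OmicsSet", {
  empty <- writeTempTsv("probe_id\ts1\ts2")
  x <- readOmicsMatrix(empty, "methylation_beta")
  expect_s4_class(x, "OmicsSet")
  expect_equal(nrow(x), 0L)
})

test_that("CGI BED intervals are sorted, merged, and 1-based internally", {
  path <- writeTempTsv(c("chr1\t1500\t2500", "chr1\t1000\t2000"))
  gr <- readCgiBed(path)
  expect_equal(length(gr), 1L)
  expect_equal(GenomicRanges::start(gr), 1001L)   # BED 1000 -> 1-based 1001
  expect_equal(GenomicRanges::end(gr), 2500L)

  single <- writeTempTsv("chr2\t10\t20")
  expect_equal(length(readCgiBed(single)), 1L)

  degenerate <- writeTempTsv("chr1\t100\t100")
  expect_error(readCgiBed(degenerate), "end <= start")
})

test_that("analysis config survives a YAML round trip losslessly", {
  cfg <- analysisConfig(fdrQ = 0.1, transMaxPairs = Inf, seed = 42,
                        softPower = NA_real_, networkSign = "signed")
  path <- tempfile(fileext = ".yaml")
  writeAnalysisConfig(cfg, path)
  back <- readAnalysisConfig(path)
  for (s in slotNames(cfg))
    expect_identical(slot(back, s), slot(cfg, s), label = s)
})

test_that("covariate validation enforces the documented invariants", {
  v <- omicsTrio:::validateCovariates
  expect_error(v(
    data.frame(sample_id = c("a", "a"), age = c(30, 40), sex = c(0, 1))),
    "duplicate")
  expect_error(v(
    data.frame(sample_id = c("a", "b"), age = c(-1, 40), sex = c(0, 1))),
    "age")
  expect_error(v(
    data.frame(sample_id = c("a", "b"), age = c(30, 40), sex = c(2, 1))),
    "sex")
})
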