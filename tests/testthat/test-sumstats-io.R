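test_that("a header-only file yields an empty table", {
  f <- tempfile(fileext = ".txt")
  writeLines("SNP CHR BP A1 A2 FRQ BETA SE P", f)
  ss <- readSumstats(f, traitLabel = "empty")
  expect_s4_class(ss, "SumStats")
  expect_equal(nVariants(ss), 0L)
})

test_that("a small fixture is read field by field and position-sorted", {
  df <- makeSumstatsDf(
    snp = c("rs2", "rs1", "rs3"), chr = c("2", "1", "1"),
    bp = c(500L, 1000L, 200L), ea = c("A", "C", "G"),
    oa = c("G", "T", "A"), beta = c(-0.2, 0.1, 0.05),
    p = c(0.01, 0.5, 0.9), eaf = c(0.3, 0.4, 0.5),
    se = c(0.05, 0.04, 0.02))
  ss <- readSumstats(writeSumstatsFixture(df), traitLabel = "fix")
  expect_equal(nVariants(ss), 3L)
  v <- variants(ss)
  mc <- S4Vectors::mcols(v)
  # sorted: chr1:200 (rs3), chr1:1000 (rs1), chr2:500 (rs2)
  expect_equal(mc$snp, c("rs3", "rs1", "rs2"))
  expect_equal(GenomicRanges::start(v), c(200L, 1000L, 500L))
  expect_equal(mc$beta, c(0.05, 0.1, -0.2))
  expect_equal(mc$p, c(0.9, 0.5, 0.01))
  expect_equal(mc$ea, c("G", "C", "A"))
  expect_equal(mc$oa, c("A", "T", "G"))
  expect_equal(mc$eaf, c(0.5, 0.4, 0.3))
})

test_that("invalid rows are dropped with a warning, valid ones kept", {
  df <- makeSumstatsDf(
    snp = c("rs1", "rs2", "rs3"), chr = "1", bp = c(100L, 200L, 300L),
    ea = "A", oa = "G", beta = 0.1, p = c(0.02, 1.5, 0.3))
  expect_warning(ss <- readSumstats(writeSumstatsFixture(df)),
                 "dropped")
  expect_equal(nVariants(ss), 2L)
  expect_equal(ss@nDropped, 1L)
  expect_false("rs2" %in% S4Vectors::mcols(variants(ss))$snp)
})

test_that("p-values of exactly zero are clamped, not dropped", {
  df <- makeSumstatsDf(snp = c("rs1", "rs2"), chr = "1",
                       bp = c(100L, 200L), ea = "A", oa = "G",
                       beta = 0.1, p = c(0, 0.5))
  expect_warning(ss <- readSumstats(writeSumstatsFixture(df)),
                 "clamped")
  expect_equal(nVariants(ss), 2L)
  p <- S4Vectors::mcols(variants(ss))$p
  expect_gt(min(p), 0)
})

test_that("missing mandatory columns and duplicate ids are hard errors", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("SNP CHR BP A1 A2", "rs1 1 100 A G"), f)
  expect_error(readSumstats(f), "mandatory")

  df <- makeSumstatsDf(snp = c("rs1", "rs1"), chr = "1",
                       bp = c(100L, 200L), ea = "A", oa = "G",
                       beta = 0.1, p = 0.5)
  expect_error(readSumstats(writeSumstatsFixture(df)), "duplicate")
})

test_that("column maps and gzip input are supported", {
  f <- tempfile(fileext = ".txt.gz")
  con <- gzfile(f, "w")
  writeLines(c("rsid chrom pos ea nea freq b stderr pval",
               "rs1 chr1 100 A G 0.2 0.3 0.1 0.004"), con)
  close(con)
  ss <- readSumstats(f, columnMap = c(
    SNP = "rsid", CHR = "chrom", BP = "pos", A1 = "ea", A2 = "nea",
    FRQ = "freq", BETA = "b", SE = "stderr", P = "pval"))
  expect_equal(nVariants(ss), 1L)
  mc <- S4Vectors::mcols(variants(ss))
  expect_equal(mc$p, 0.004)
  # "chr1" normalized to "1"
  expect_equal(as.character(GenomicRanges::seqnames(variants(ss))), "1")
})

test_that("write/read round-trips a table", {
  sim <- simulatePair(smallGenome(5), seed = 3)
  f <- tempfile(fileext = ".txt")
  writeSumstats(sim$primary, f)
  back <- readSumstats(f, traitLabel = traitLabel(sim$primary))
  expect_equal(nVariants(back), nVariants(sim$primary))
  expect_equal(S4Vectors::mcols(variants(back))$p,
               S4Vectors::mcols(variants(sim$primary))$p,
               tolerance = 1e-12)
})

test_that("intersectAll keeps only SNPs present in every table", {
  mk <- function(ids) makeSumStatsObj(makeSumstatsDf(
    snp = ids, chr = "1", bp = seq_along(ids) * 100L,
    ea = "A", oa = "G", beta = 0.1, p = 0.5))
  a <- mk(paste0("rs", 1:10))
  expect_equal(nrow(intersectAll(a, a)), 10L)

  b <- mk(paste0("rs", 6:15))
  ab <- intersectAll(a, b)
  expect_equal(ab$snp, paste0("rs", 6:10))

  c3 <- mk(paste0("rs", 101:110))
  expect_error(intersectAll(a, b, c3), "no SNPs shared")
  expect_error(intersectAll(a), "at least two")
})
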