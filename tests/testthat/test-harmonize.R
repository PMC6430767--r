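# One non-palindromic SNP in four allele orientations; beta2 < 0 so the
# sign arithmetic is visible.
orientationFixture <- function(ea2, oa2) {
  p <- makeSumStatsObj(makeSumstatsDf("rs1", "1", 100L, "A", "G",
                                      beta = 0.1, p = 0.02), "p")
  s <- makeSumStatsObj(makeSumstatsDf("rs1", "1", 100L, ea2, oa2,
                                      beta = -0.3, p = 0.04), "s")
  harmonize(p, s)
}

test_that("all four allele orientations resolve to the right sign", {
  # primary A/G, secondary beta -0.3 (sign -1 on its own effect allele)
  cases <- list(
    list(ea = "A", oa = "G", s2 = -1L),  # identical
    list(ea = "G", oa = "A", s2 = +1L),  # swapped
    list(ea = "T", oa = "C", s2 = -1L),  # strand complement
    list(ea = "C", oa = "T", s2 = +1L)   # complement + swapped
  )
  for (cs in cases) {
    hp <- orientationFixture(cs$ea, cs$oa)
    mc <- S4Vectors::mcols(variants(hp))
    expect_equal(mc$s1, 1L)
    expect_equal(mc$s2, cs$s2,
                 info = paste("secondary", cs$ea, "/", cs$oa))
  }
  # irreconcilable pair is dropped, which empties the overlap -> error
  expect_error(orientationFixture("A", "C"), "survived")
})

test_that("same alleles with positive betas give (+1, +1)", {
  p <- makeSumStatsObj(makeSumstatsDf("rs1", "1", 100L, "A", "G",
                                      beta = 0.1, p = 0.5), "p")
  s <- makeSumStatsObj(makeSumstatsDf("rs1", "1", 100L, "A", "G",
                                      beta = 0.2, p = 0.5), "s")
  mc <- S4Vectors::mcols(variants(harmonize(p, s)))
  expect_equal(c(mc$s1, mc$s2), c(1L, 1L))
})

test_that("palindromic SNPs are dropped by default, rescued by frequency", {
  df1 <- makeSumstatsDf(c("rs1", "rs2"), "1", c(100L, 200L),
                        ea = c("A", "A"), oa = c("T", "G"),
                        beta = c(0.1, 0.1), p = 0.5,
                        eaf = c(0.2, 0.4))
  df2 <- df1
  df2$eaf <- c(0.25, 0.4)
  p <- makeSumStatsObj(df1, "p")
  s <- makeSumStatsObj(df2, "s")

  hp <- harmonize(p, s)
  expect_equal(nVariants(hp), 1L)
  expect_equal(hp@nDroppedPalindromic, 1L)
  expect_equal(S4Vectors::mcols(variants(hp))$snp, "rs2")

  hp2 <- harmonize(p, s, freqRescue = TRUE)
  expect_equal(nVariants(hp2), 2L)
  mc <- S4Vectors::mcols(variants(hp2))
  expect_equal(mc$s2[mc$snp == "rs1"], 1L)  # eaf 0.2 vs 0.25: same strand

  # ambiguous frequency (near 0.5) still drops
  df3 <- df2; df3$eaf <- c(0.52, 0.4)
  hp3 <- harmonize(p, makeSumStatsObj(df3, "s"), freqRescue = TRUE)
  expect_equal(nVariants(hp3), 1L)
})

test_that("harmonization is symmetric in the sign product", {
  sim <- simulatePair(smallGenome(10), seed = 5)
  ab <- S4Vectors::mcols(variants(harmonize(sim$primary, sim$secondary)))
  ba <- S4Vectors::mcols(variants(harmonize(sim$secondary, sim$primary)))
  expect_equal(ab$snp, ba$snp)
  expect_equal(ab$s1 * ab$s2, ba$s1 * ba$s2)
})

test_that("negating every secondary beta flips sign2 and nothing else", {
  sim <- simulatePair(smallGenome(10), seed = 6)
  neg <- sim$secondary
  S4Vectors::mcols(neg@variants)$beta <-
    -S4Vectors::mcols(neg@variants)$beta
  a <- S4Vectors::mcols(variants(harmonize(sim$primary, sim$secondary)))
  b <- S4Vectors::mcols(variants(harmonize(sim$primary, neg)))
  expect_equal(b$s2, -a$s2)
  expect_equal(b$s1, a$s1)
  expect_equal(b$p1, a$p1)
  expect_equal(b$p2, a$p2)
})

test_that("overlap size never exceeds either input", {
  sim <- simulatePair(smallGenome(10), seed = 7)
  hp <- harmonize(sim$primary, sim$secondary)
  expect_lte(nVariants(hp),
             min(nVariants(sim$primary), nVariants(sim$secondary)))
})

test_that("zero overlap is a hard error", {
  a <- makeSumStatsObj(makeSumstatsDf("rs1", "1", 100L, "A", "G",
                                      beta = 0.1, p = 0.5), "a")
  b <- makeSumStatsObj(makeSumstatsDf("rs2", "1", 100L, "A", "G",
                                      beta = 0.1, p = 0.5), "b")
  expect_error(harmonize(a, b), "no overlapping")
})
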