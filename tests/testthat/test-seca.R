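# 100 SNPs engineered so the (0.01, 0.01) cell has margins (10, 10)
# and 5 SNPs in both tails.
marginFixture <- function() {
  p1 <- c(rep(0.005, 10), rep(0.5, 90))
  p2 <- c(rep(0.005, 5), rep(0.5, 5), rep(0.005, 5), rep(0.5, 85))
  makePair(p1, 1, p2, 1)
}

test_that("degenerate input: all p = 1 puts everything in the last cell", {
  hp <- makePair(p1 = rep(1, 6), s1 = 1, p2 = rep(1, 6), s2 = 1)
  g <- pleiotropyGrid(hp)
  expect_equal(g$nBoth[g$t1 == 1 & g$t2 == 1], 6L)
  expect_true(all(g$nBoth[g$t1 < 1 | g$t2 < 1] == 0L))
  expect_true(all(g$enrichmentP[g$t1 < 1 | g$t2 < 1] == 1))
})

test_that("cell enrichment p equals the hypergeometric tail sum", {
  g <- pleiotropyGrid(marginFixture())
  cell <- g[g$t1 == 0.01 & g$t2 == 0.01, ]
  expect_equal(cell$nBoth, 5L)
  expect_equal(cell$nOnly1, 5L)
  expect_equal(cell$nOnly2, 5L)
  expect_equal(cell$nNeither, 85L)
  expect_equal(cell$enrichmentP, enumHyperTail(5, 10, 10, 100),
               tolerance = 1e-12)
  # every cell, not just the engineered one
  for (r in sample.int(nrow(g), 20)) {
    K1 <- g$nBoth[r] + g$nOnly1[r]
    K2 <- g$nBoth[r] + g$nOnly2[r]
    expect_equal(g$enrichmentP[r], enumHyperTail(g$nBoth[r], K1, K2, 100),
                 tolerance = 1e-12)
  }
})

test_that("concordance p-values match full sign enumeration", {
  # 10 SNPs in the strict cell, 8 concordant
  s2 <- c(rep(1L, 8), rep(-1L, 2), rep(1L, 10))
  hp <- makePair(p1 = c(rep(0.005, 10), rep(0.5, 10)), s1 = 1L,
                 p2 = c(rep(0.005, 10), rep(0.5, 10)), s2 = s2)
  g <- concordanceGrid(hp)
  cell <- g[g$t1 == 0.01 & g$t2 == 0.01, ]
  expect_equal(cell$nBoth, 10L)
  expect_equal(cell$nConcordant, 8L)
  expect_equal(cell$concordancePExcess, 56 / 1024, tolerance = 1e-12)
  expect_equal(cell$concordancePExcess, enumBinomTail(10, 8),
               tolerance = 1e-12)
  # spot-check other informative cells against the enumeration oracle
  inf <- which(g$informative & g$nBoth <= 12)
  for (r in head(inf, 10)) {
    expect_equal(g$concordancePExcess[r],
                 enumBinomTail(g$nBoth[r], g$nConcordant[r]),
                 tolerance = 1e-12)
    expect_equal(g$concordancePDeficit[r],
                 enumBinomTail(g$nBoth[r], g$nDiscordant[r]),
                 tolerance = 1e-12)
  }
})

test_that("single concordant SNP gives excess p = 0.5; empty cells p = 1", {
  hp <- makePair(p1 = c(0.005, 0.5), s1 = c(1L, 1L),
                 p2 = c(0.005, 0.5), s2 = c(1L, -1L))
  g <- concordanceGrid(hp)
  cell <- g[g$t1 == 0.01 & g$t2 == 0.01, ]
  expect_equal(cell$nBoth, 1L)
  expect_equal(cell$concordancePExcess, 0.5)

  hp2 <- makePair(p1 = c(0.5, 0.5), s1 = 1L, p2 = c(0.5, 0.5), s2 = 1L)
  g2 <- concordanceGrid(hp2)
  empty <- g2[g2$t1 == 0.01 & g2$t2 == 0.01, ]
  expect_equal(empty$nBoth, 0L)
  expect_false(empty$informative)
  expect_equal(empty$concordancePExcess, 1)
  expect_equal(empty$concordancePDeficit, 1)
})

test_that("a permutation-invariant statistic gives empirical p = 1", {
  hp <- makePair(p1 = runif(20), s1 = 1L, p2 = rep(1, 20), s2 = 1L)
  s <- secaPermutation(hp, "pleiotropy", nPerm = 99, seed = 4)
  expect_equal(empiricalP(s), 1)
})

test_that("an unbeaten observed statistic gives the add-one minimum", {
  # overwhelming shared signal: no permutation can reach the observed
  # grid statistic
  sim <- simulatePair(smallGenome(120),
                      effectSpec(pi1 = 0.3, pi2 = 0.3, piShared = 0.3,
                                 pSignAgree = 1, effectSd = 0.06),
                      seed = 21)
  cl <- ldClump(harmonize(sim$primary, sim$secondary), sim$ld)
  s <- secaPermutation(cl, "pleiotropy", nPerm = 999, seed = 8)
  expect_equal(empiricalP(s), 1 / 1000)
  expect_gte(empiricalP(s), 1 / (1 + 999))
})

test_that("permutation summaries are deterministic given a seed", {
  hp <- makePair(p1 = c(0.001, 0.2, 0.4, 0.6, 0.9), s1 = 1L,
                 p2 = c(0.005, 0.3, 0.1, 0.8, 0.7),
                 s2 = c(1L, 1L, -1L, 1L, -1L))
  a <- secaPermutation(hp, "concordance", nPerm = 99, seed = 42)
  b <- secaPermutation(hp, "concordance", nPerm = 99, seed = 42)
  expect_equal(empiricalP(a), empiricalP(b))
  expect_equal(a@statistic, b@statistic)
  expect_equal(a@ciLow, b@ciLow)
  expect_equal(a@ciHigh, b@ciHigh)
  expect_equal(direction(a), direction(b))
  # the global RNG stream is untouched
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(secaPermutation(hp, "pleiotropy",
                                         nPerm = 19, seed = 1))
  expect_equal(rnorm(1), before)
})

test_that("flipping all secondary signs mirrors concordance, not pleiotropy", {
  sim <- makeFixture("concordant_pair", smallGenome(60), seed = 13)
  cl <- ldClump(harmonize(sim$primary, sim$secondary), sim$ld)
  flipped <- cl
  S4Vectors::mcols(flipped@index)$s2 <- -S4Vectors::mcols(cl@index)$s2

  p1 <- secaPermutation(cl, "pleiotropy", nPerm = 99, seed = 5)
  p2 <- secaPermutation(flipped, "pleiotropy", nPerm = 99, seed = 5)
  expect_equal(empiricalP(p1), empiricalP(p2))
  expect_equal(p1@statistic, p2@statistic)

  c1 <- secaPermutation(cl, "concordance", nPerm = 99, seed = 5)
  c2 <- secaPermutation(flipped, "concordance", nPerm = 99, seed = 5)
  expect_equal(direction(c1), "+")
  expect_equal(direction(c2), "-")
  expect_equal(empiricalP(c1), empiricalP(c2))
})

test_that("empirical p respects the Clopper-Pearson interval and floor", {
  hp <- makePair(p1 = runif(30), s1 = sample(c(-1L, 1L), 30, TRUE),
                 p2 = runif(30), s2 = sample(c(-1L, 1L), 30, TRUE))
  for (mode in c("pleiotropy", "concordance")) {
    s <- secaPermutation(hp, mode, nPerm = 99, seed = 11)
    expect_gte(empiricalP(s), 1 / 100)
    expect_lte(s@ciLow, empiricalP(s))
    expect_gte(s@ciHigh, empiricalP(s))
  }
})

test_that("self-comparison is maximally significant with direction +", {
  sim <- simulatePair(smallGenome(80), effectSpec(pi1 = 0.3, pi2 = 0.3,
                                                  piShared = 0.3,
                                                  pSignAgree = 1),
                      seed = 31)
  res <- runSeca(sim$primary, sim$primary, sim$ld, nPerm = 99, seed = 2)
  expect_equal(empiricalP(res@pleiotropy), 1 / 100)
  expect_equal(empiricalP(res@concordance), 1 / 100)
  expect_equal(direction(res@concordance), "+")
  expect_equal(res@nIndex, 80L)
})

test_that("secaRow flattens a result into the published table schema", {
  sim <- makeFixture("concordant_pair", smallGenome(40), seed = 3)
  res <- runSeca(sim$primary, sim$secondary, sim$ld, nPerm = 99, seed = 1)
  row <- secaRow(res)
  expect_named(row, c("trait1", "trait2", "pPleiotropy",
                      "ciPleiotropyLow", "ciPleiotropyHigh",
                      "pConcordance", "ciConcordanceLow",
                      "ciConcordanceHigh", "direction"))
  expect_equal(row$direction, "+")
})
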