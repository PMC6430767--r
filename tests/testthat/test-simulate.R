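test_that("forced zero sharing gives an empty shared set", {
  sim <- simulatePair(smallGenome(20),
                      effectSpec(pi1 = 0.3, pi2 = 0.3, piShared = 0),
                      seed = 2)
  expect_equal(sum(sim$truth$shared), 0L)
  expect_equal(sum(sim$truth$causal1), round(0.3 * 20))
  expect_equal(sum(sim$truth$causal2), round(0.3 * 20))
  # disjoint by construction
  expect_false(any(sim$truth$causal1 & sim$truth$causal2))
})

test_that("independent assignment overlaps at the chance rate", {
  sh <- vapply(1:20, function(i) {
    sim <- simulatePair(smallGenome(50),
                        effectSpec(pi1 = 0.4, pi2 = 0.4, piShared = NA),
                        seed = 100 + i)
    sum(sim$truth$shared)
  }, numeric(1))
  # E = 50 * 0.4 * 0.4 = 8; binomial-ish SE over 20 reps ~ 0.5
  expect_gt(mean(sh), 8 - 3 * 0.6)
  expect_lt(mean(sh), 8 + 3 * 0.6)
})

test_that("the same seed reproduces the simulation exactly", {
  a <- simulatePair(smallGenome(10), seed = 12)
  b <- simulatePair(smallGenome(10), seed = 12)
  expect_equal(S4Vectors::mcols(variants(a$primary)),
               S4Vectors::mcols(variants(b$primary)))
  expect_equal(S4Vectors::mcols(variants(a$secondary)),
               S4Vectors::mcols(variants(b$secondary)))
  expect_equal(a$ld@pairs, b$ld@pairs)
  expect_equal(a$truth, b$truth, ignore_attr = TRUE)
  c1 <- simulatePair(smallGenome(10), seed = 13)
  expect_false(isTRUE(all.equal(
    S4Vectors::mcols(variants(a$primary))$p,
    S4Vectors::mcols(variants(c1$primary))$p)))
})

test_that("Z-score moments match the generating model", {
  eff <- effectSpec(pi1 = 0.3, pi2 = 0, piShared = 0, effectSd = 0.02,
                    n1 = 10000)
  sim <- simulatePair(genomeSpec(), eff, seed = 8)
  mc <- S4Vectors::mcols(variants(sim$primary))
  z <- mc$beta / mc$se
  genome <- attr(sim$truth, "genome")
  blocks <- blockOfSnp(mc$snp, genome)
  nullSnp <- !sim$truth$causal1[blocks]
  nNull <- sum(nullSnp)
  # null SNPs: mean 0, variance 1 (3-SE tolerances; within-block
  # correlation inflates the SE of the mean by ~ sqrt(1 + (k-1) rho))
  infl <- sqrt(1 + (genome$snpsPerBlock - 1) * sqrt(genome$withinBlockR2))
  expect_lt(abs(mean(z[nullSnp])), 3 * infl / sqrt(nNull))
  expect_lt(abs(var(z[nullSnp]) - 1), 3 * sqrt(2 / nNull) * infl)
  # causal tags: E[chi^2] = 1 + n * effectSd^2
  tags <- mc$snp %in% sim$truth$tagSnp[sim$truth$causal1]
  lambda <- eff$n1 * eff$effectSd^2
  expChi2 <- 1 + lambda
  seChi2 <- sqrt((2 + 4 * lambda) / sum(tags))
  expect_lt(abs(mean(z[tags]^2) - expChi2), 3 * seChi2)
})

test_that("null-block p-values are uniform (pooled KS)", {
  ps <- unlist(lapply(1:3, function(i) {
    sim <- simulatePair(smallGenome(100),
                        effectSpec(pi1 = 0.3, pi2 = 0, piShared = 0),
                        seed = 300 + i)
    mc <- S4Vectors::mcols(variants(sim$primary))
    blocks <- blockOfSnp(mc$snp, attr(sim$truth, "genome"))
    # one SNP per null block keeps the sample independent
    tag <- mc$snp %in% sim$truth$tagSnp
    mc$p[tag & !sim$truth$causal1[blocks]]
  }))
  expect_gt(length(ps), 150)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("clumping the simulated data recovers one index per block", {
  sim <- makeFixture("null_pair", smallGenome(50, 2), seed = 9)
  cl <- ldClump(harmonize(sim$primary, sim$secondary), sim$ld)
  expect_equal(length(indexVariants(cl)), 100L)
  genome <- attr(sim$truth, "genome")
  idxBlocks <- blockOfSnp(S4Vectors::mcols(indexVariants(cl))$snp, genome)
  expect_equal(sort(idxBlocks), 1:100)
})

test_that("the SECA direction label recovers the sign regime", {
  for (cs in list(list(f = "concordant_pair", d = "+"),
                  list(f = "discordant_pair", d = "-"))) {
    sim <- makeFixture(cs$f, smallGenome(80), seed = 17)
    cl <- ldClump(harmonize(sim$primary, sim$secondary), sim$ld)
    s <- secaPermutation(cl, "concordance", nPerm = 99, seed = 3)
    if (empiricalP(s) <= 0.05) expect_equal(direction(s), cs$d)
  }
})

test_that("simulated bundles round-trip through their text formats", {
  sim <- makeFixture("concordant_pair", smallGenome(10), seed = 4)
  dir <- tempfile()
  paths <- writeSimulatedPair(sim, dir)
  expect_true(all(file.exists(paths)))
  p <- readSumstats(paths[["primary"]], traitLabel = "trait1")
  expect_equal(S4Vectors::mcols(variants(p))$p,
               S4Vectors::mcols(variants(sim$primary))$p,
               tolerance = 1e-10)
  ld <- readLdTable(paths[["ld"]])
  expect_equal(nrow(ld@pairs), nrow(sim$ld@pairs))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$shared, sim$truth$shared)
})

test_that("simulated alleles are never palindromic", {
  sim <- simulatePair(smallGenome(20), seed = 19)
  mc <- S4Vectors::mcols(variants(sim$primary))
  expect_false(any(crossPleio:::isPalindromic(mc$ea, mc$oa)))
})
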