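#' Default SECA p-value threshold grid
#'
#' The twelve nested significance cutoffs applied to both traits,
#' spanning nominal significance (0.01, 0.05, 0.1) through the full SNP
#' set (1.0). Crossing the two sets yields the 144-cell grid on which
#' pleiotropy and concordance are tested.
#'
#' @return Ascending numeric vector ending in 1.
#' @export
secaThresholds <- function() {
  c(0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0)
}

# Cumulative 2-D cell counts: C[i, j] = #(p1 <= t1[i] & p2 <= t2[j]).
# Works on precomputed threshold bins so permutations only re-tabulate.
cellCounts <- function(bin1, bin2, m1, m2, subset = NULL) {
  if (!is.null(subset)) {
    bin1 <- bin1[subset]
    bin2 <- bin2[subset]
  }
  if (length(bin1) == 0L) return(matrix(0L, m1, m2))
  C <- matrix(tabulate((bin2 - 1L) * m1 + bin1, nbins = m1 * m2), m1, m2)
  if (m1 > 1L) C <- matrix(apply(C, 2L, cumsum), m1, m2)
  if (m2 > 1L) C <- matrix(t(apply(C, 1L, cumsum)), m1, m2)
  C
}

# One-sided hypergeometric enrichment p for every grid cell:
# P(X >= nBoth) with margins (K1, K2) out of n.
cellEnrichmentP <- function(nBoth, K1, K2, n) {
  m1 <- length(K1); m2 <- length(K2)
  phyper(nBoth - 1,
         m = matrix(K1, m1, m2),
         n = matrix(n - K1, m1, m2),
         k = matrix(K2, m1, m2, byrow = TRUE),
         lower.tail = FALSE)
}

#' Grid-based pleiotropy test
#'
#' For every cell (t1, t2) of the threshold grid, cross-classifies the
#' SNPs by (p_primary <= t1) and (p_secondary <= t2) and computes a
#' one-sided exact hypergeometric (Fisher-type) p-value for
#' over-representation of the both-significant cell — evidence that the
#' same SNPs affect both traits, regardless of effect direction.
#'
#' @param x A [ClumpResult-class] or [HarmonizedPair-class] object
#'   (normally the clumped index SNPs).
#' @param thresholds1,thresholds2 Ascending p-value cutoffs ending at 1
#'   for the primary and secondary trait (default [secaThresholds()]).
#' @return Long-format `data.frame`, one row per cell: `t1`, `t2`,
#'   `nBoth`, `nOnly1`, `nOnly2`, `nNeither`, `enrichmentP`.
#' @export
pleiotropyGrid <- function(x, thresholds1 = secaThresholds(),
                           thresholds2 = secaThresholds()) {
  d <- secaInputs(x)
  checkThresholds(thresholds1); checkThresholds(thresholds2)
  m1 <- length(thresholds1); m2 <- length(thresholds2)
  bin1 <- thresholdBin(d$p1, thresholds1)
  bin2 <- thresholdBin(d$p2, thresholds2)
  n <- length(d$p1)
  C <- cellCounts(bin1, bin2, m1, m2)
  K1 <- C[, m2]; K2 <- C[m1, ]
  ep <- cellEnrichmentP(C, K1, K2, n)
  data.frame(
    t1 = rep(thresholds1, times = m2),
    t2 = rep(thresholds2, each = m1),
    nBoth = as.integer(C),
    nOnly1 = as.integer(matrix(K1, m1, m2) - C),
    nOnly2 = as.integer(matrix(K2, m1, m2, byrow = TRUE) - C),
    nNeither = as.integer(n - matrix(K1, m1, m2) -
                            matrix(K2, m1, m2, byrow = TRUE) + C),
    enrichmentP = as.numeric(ep)
  )
}

#' Grid-based sign-concordance test
#'
#' For the SNPs falling in each cell (p_primary <= t1 AND
#' p_secondary <= t2), counts agreements between the harmonized effect
#' signs and computes one-sided exact binomial p-values against 0.5 for
#' an excess of concordant signs and for an excess of discordant signs.
#' Cells containing no SNP are non-informative and get p = 1 on both
#' sides.
#'
#' @inheritParams pleiotropyGrid
#' @return Long-format `data.frame`, one row per cell: `t1`, `t2`,
#'   `nBoth`, `nConcordant`, `nDiscordant`, `concordancePExcess`,
#'   `concordancePDeficit`, `informative`.
#' @export
concordanceGrid <- function(x, thresholds1 = secaThresholds(),
                            thresholds2 = secaThresholds()) {
  d <- secaInputs(x)
  checkThresholds(thresholds1); checkThresholds(thresholds2)
  m1 <- length(thresholds1); m2 <- length(thresholds2)
  bin1 <- thresholdBin(d$p1, thresholds1)
  bin2 <- thresholdBin(d$p2, thresholds2)
  C <- cellCounts(bin1, bin2, m1, m2)
  Cc <- cellCounts(bin1, bin2, m1, m2, subset = d$s1 == d$s2)
  exc <- matrix(1, m1, m2)
  def <- matrix(1, m1, m2)
  inf <- C > 0
  exc[inf] <- pbinom(Cc[inf] - 1, C[inf], 0.5, lower.tail = FALSE)
  def[inf] <- pbinom(Cc[inf], C[inf], 0.5)
  data.frame(
    t1 = rep(thresholds1, times = m2),
    t2 = rep(thresholds2, each = m1),
    nBoth = as.integer(C),
    nConcordant = as.integer(Cc),
    nDiscordant = as.integer(C - Cc),
    concordancePExcess = as.numeric(exc),
    concordancePDeficit = as.numeric(def),
    informative = as.logical(inf)
  )
}

# Common input extraction: p-values and signs from clumped or harmonized
# variants.
secaInputs <- function(x) {
  gr <- if (is(x, "ClumpResult")) x@index
        else if (is(x, "HarmonizedPair")) x@variants
        else stop("x must be a ClumpResult or HarmonizedPair")
  if (length(gr) == 0L) stop("no variants")
  mc <- S4Vectors::mcols(gr)
  list(p1 = mc$p1, s1 = mc$s1, p2 = mc$p2, s2 = mc$s2)
}

checkThresholds <- function(t) {
  stopifnot(length(t) >= 1L, all(t > 0), all(t <= 1),
            all(diff(t) > 0), t[length(t)] == 1)
}

# Grid statistics on bins; returns the counts of cells meeting the
# cell-level criterion (and the minimum cell p) for each test direction.
gridStats <- function(bin1, bin2, s1, s2, m1, m2, n, cellAlpha) {
  C <- cellCounts(bin1, bin2, m1, m2)
  K1 <- C[, m2]; K2 <- C[m1, ]
  ep <- cellEnrichmentP(C, K1, K2, n)
  Cc <- cellCounts(bin1, bin2, m1, m2, subset = s1 == s2)
  inf <- C > 0
  exc <- matrix(1, m1, m2); def <- matrix(1, m1, m2)
  exc[inf] <- pbinom(Cc[inf] - 1, C[inf], 0.5, lower.tail = FALSE)
  def[inf] <- pbinom(Cc[inf], C[inf], 0.5)
  list(
    pleioCount = sum(ep <= cellAlpha),
    pleioMinP = min(ep),
    excCount = sum(exc <= cellAlpha),
    excMinP = min(exc),
    defCount = sum(def <= cellAlpha),
    defMinP = min(def),
    netConcordant = sum(Cc[inf] - (C[inf] - Cc[inf])),
    fullCellNet = Cc[m1, m2] - (C[m1, m2] - Cc[m1, m2]),
    anyInformative = any(inf)
  )
}

# Direction label from the informative cells: sign of the summed
# concordant-minus-discordant excess; ties resolved from the full
# (1, 1) cell; "none" when no cell is informative.
directionLabel <- function(st) {
  if (!st$anyInformative) return("none")
  net <- st$netConcordant
  if (net == 0) net <- st$fullCellNet
  if (net > 0) "+" else if (net < 0) "-" else "none"
}

#' Permutation summary of a SECA grid test
#'
#' Computes the observed grid statistic — by default the minimum
#' cell-level one-sided p-value over the grid — and calibrates it
#' against a permutation null in which the secondary
#' trait's (p-value, sign) pairs are randomly re-paired across SNPs.
#' Re-pairing preserves each trait's marginal distributions exactly
#' while destroying any cross-trait linkage. The empirical p-value uses
#' the add-one rule `(1 + #\{permuted >= observed\}) / (1 + nPerm)` and
#' never returns 0; an exact 95% Clopper-Pearson interval on that
#' proportion is attached.
#'
#' For `mode = "concordance"` the statistic is evaluated separately for
#' the excess-concordance and excess-discordance directions; the
#' reported empirical p is the smaller of the two (not doubled) and the
#' direction label is `"+"` for excess, `"-"` for deficit. For
#' `mode = "pleiotropy"` the direction label summarizes the sign
#' agreement of the informative cells.
#'
#' @param x A [ClumpResult-class] or [HarmonizedPair-class] object.
#' @param mode `"pleiotropy"` or `"concordance"`.
#' @param nPerm Number of permutations (default 9999, giving empirical-p
#'   resolution 1e-4).
#' @param seed Integer seed; all randomness is local to the call.
#' @param thresholds1,thresholds2 Grid cutoffs, as in [pleiotropyGrid()].
#' @param cellAlpha Cell-level significance criterion used by the
#'   `"count"` statistic (default 0.05).
#' @param statistic `"minp"` (default: minimum cell-level p over the
#'   grid; smaller is more extreme) or `"count"` (number of cells at
#'   `p <= cellAlpha`; the statistic historically reported for this
#'   analysis). The count statistic is integer-valued with an atom at
#'   0, which makes its permutation p conservative with a mass at 1
#'   under the null; the min-p statistic is near-continuous and
#'   null-calibrated, hence the default.
#' @return A [SecaSummary-class] object.
#' @export
secaPermutation <- function(x, mode = c("pleiotropy", "concordance"),
                            nPerm = 9999L, seed = 1L,
                            thresholds1 = secaThresholds(),
                            thresholds2 = secaThresholds(),
                            cellAlpha = 0.05,
                            statistic = c("minp", "count")) {
  mode <- match.arg(mode)
  statistic <- match.arg(statistic)
  stopifnot(nPerm >= 1L)
  if (nPerm < 99L)
    warning("fewer than 99 permutations gives coarse empirical p resolution")
  d <- secaInputs(x)
  checkThresholds(thresholds1); checkThresholds(thresholds2)
  m1 <- length(thresholds1); m2 <- length(thresholds2)
  n <- length(d$p1)
  bin1 <- thresholdBin(d$p1, thresholds1)
  bin2 <- thresholdBin(d$p2, thresholds2)

  obs <- gridStats(bin1, bin2, d$s1, d$s2, m1, m2, n, cellAlpha)

  pick <- function(st) switch(statistic,
    count = switch(mode,
      pleiotropy = list(pl = st$pleioCount),
      concordance = list(exc = st$excCount, def = st$defCount)),
    minp = switch(mode,
      pleiotropy = list(pl = st$pleioMinP),
      concordance = list(exc = st$excMinP, def = st$defMinP)))
  # "count": larger is more extreme; "minp": smaller is more extreme
  moreExtreme <- if (statistic == "count") `>=` else `<=`

  obsStat <- pick(obs)
  exceed <- lapply(obsStat, function(z) 0L)
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(nPerm)) {
      perm <- sample.int(n)
      st <- gridStats(bin1, bin2[perm], d$s1, d$s2[perm], m1, m2, n,
                      cellAlpha)
      ps <- pick(st)
      for (k in names(ps))
        if (moreExtreme(ps[[k]], obsStat[[k]]))
          exceed[[k]] <- exceed[[k]] + 1L
    }
  })

  empP <- vapply(exceed, function(b) (1 + b) / (1 + nPerm), numeric(1))
  if (mode == "pleiotropy") {
    pSel <- empP[["pl"]]
    statSel <- obsStat[["pl"]]
    xSucc <- 1L + exceed[["pl"]]
    dir <- directionLabel(obs)
  } else {
    if (empP[["exc"]] < empP[["def"]] ||
        (empP[["exc"]] == empP[["def"]] &&
         (if (obs$anyInformative)
            (if (obs$netConcordant != 0) obs$netConcordant
             else obs$fullCellNet) >= 0 else TRUE))) {
      pSel <- empP[["exc"]]; statSel <- obsStat[["exc"]]
      xSucc <- 1L + exceed[["exc"]]
      dir <- "+"
    } else {
      pSel <- empP[["def"]]; statSel <- obsStat[["def"]]
      xSucc <- 1L + exceed[["def"]]
      dir <- "-"
    }
    if (!obs$anyInformative) dir <- "none"
  }
  ci <- clopperPearson(xSucc, 1L + nPerm)
  new("SecaSummary", mode = mode, statistic = as.numeric(statSel),
      empiricalP = pSel, ciLow = unname(ci["low"]),
      ciHigh = unname(ci["high"]), direction = dir,
      nPerm = as.integer(nPerm))
}

#' Run a full SNP effect concordance analysis for one trait pair
#'
#' Chains the pipeline for one (primary, secondary) pair: allele
#' harmonization, greedy LD clumping ranked on the secondary trait,
#' pleiotropy and concordance grids on the index SNPs, and permutation
#' summaries for both tests.
#'
#' @param primary,secondary [SumStats-class] objects.
#' @param ld An [LdReference-class] object.
#' @param windowBp,r2Threshold Clumping parameters, see [ldClump()].
#' @param nPerm,seed,thresholds1,thresholds2,cellAlpha,statistic
#'   Permutation parameters, see [secaPermutation()].
#' @param dropPalindromic Passed to [harmonize()].
#' @return A [SecaResult-class] object.
#' @examples
#' sim <- makeFixture("concordant_pair",
#'                    genomeSpec(nChromosomes = 1, blocksPerChromosome = 40),
#'                    seed = 11)
#' res <- runSeca(sim$primary, sim$secondary, sim$ld, nPerm = 99, seed = 3)
#' res
#' @export
runSeca <- function(primary, secondary, ld,
                    windowBp = 5e5, r2Threshold = 0.2,
                    nPerm = 9999L, seed = 1L,
                    thresholds1 = secaThresholds(),
                    thresholds2 = secaThresholds(),
                    cellAlpha = 0.05,
                    statistic = c("minp", "count"),
                    dropPalindromic = TRUE) {
  statistic <- match.arg(statistic)
  hp <- harmonize(primary, secondary, dropPalindromic = dropPalindromic)
  cl <- ldClump(hp, ld, windowBp = windowBp, r2Threshold = r2Threshold,
                rankBy = "secondary")
  pg <- pleiotropyGrid(cl, thresholds1, thresholds2)
  cg <- concordanceGrid(cl, thresholds1, thresholds2)
  pleio <- secaPermutation(cl, "pleiotropy", nPerm = nPerm, seed = seed,
                           thresholds1 = thresholds1,
                           thresholds2 = thresholds2,
                           cellAlpha = cellAlpha, statistic = statistic)
  conc <- secaPermutation(cl, "concordance", nPerm = nPerm,
                          seed = seed + 1L,
                          thresholds1 = thresholds1,
                          thresholds2 = thresholds2,
                          cellAlpha = cellAlpha, statistic = statistic)
  new("SecaResult",
      traitPrimary = primary@traitLabel,
      traitSecondary = secondary@traitLabel,
      nIndex = length(cl@index),
      pleiotropy = pleio, concordance = conc,
      pleiotropyGrid = pg, concordanceGrid = cg)
}

#' One-row summary of a SECA result
#'
#' Flattens a [SecaResult-class] to the schema of the published
#' cross-trait tables: one row per trait pair with both empirical
#' p-values, their confidence intervals, and the direction label.
#'
#' @param x A [SecaResult-class] object.
#' @return One-row `data.frame` with columns `trait1, trait2,
#'   pPleiotropy, ciPleiotropyLow, ciPleiotropyHigh, pConcordance,
#'   ciConcordanceLow, ciConcordanceHigh, direction`.
#' @export
secaRow <- function(x) {
  stopifnot(is(x, "SecaResult"))
  data.frame(
    trait1 = x@traitPrimary,
    trait2 = x@traitSecondary,
    pPleiotropy = x@pleiotropy@empiricalP,
    ciPleiotropyLow = x@pleiotropy@ciLow,
    ciPleiotropyHigh = x@pleiotropy@ciHigh,
    pConcordance = x@concordance@empiricalP,
    ciConcordanceLow = x@concordance@ciLow,
    ciConcordanceHigh = x@concordance@ciHigh,
    direction = x@concordance@direction,
    stringsAsFactors = FALSE
  )
}
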