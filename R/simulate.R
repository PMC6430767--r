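#' Specify an LD-block genome for simulation
#'
#' The simulated genome is a sequence of independent LD blocks:
#' `snpsPerBlock` equally spaced SNPs per block with compound-symmetry
#' LD inside the block (every within-block pair shares the same r²) and
#' linkage equilibrium between blocks, guaranteed by placing consecutive
#' blocks further apart than any clumping window of interest. This makes
#' "one independent index SNP per block" an exact ground truth rather
#' than an approximation.
#'
#' @param nChromosomes Number of chromosomes (default 2).
#' @param blocksPerChromosome LD blocks per chromosome (default 250).
#' @param snpsPerBlock SNPs per block (default 8).
#' @param withinBlockR2 r² between any two SNPs of the same block, in
#'   \eqn{[0, 1)} (default 0.64, i.e. dosage correlation r = 0.8 — a
#'   tight, realistically clumpable block).
#' @param bpSpacing Base pairs between adjacent SNPs in a block
#'   (default 10,000).
#' @param blockGapBp Gap between the last SNP of one block and the first
#'   of the next (default 600,000, larger than the default 500 kb
#'   clumping window so blocks can never be co-clumped).
#' @return A `GenomeSpec` list.
#' @export
genomeSpec <- function(nChromosomes = 2L, blocksPerChromosome = 250L,
                       snpsPerBlock = 8L, withinBlockR2 = 0.64,
                       bpSpacing = 10000L, blockGapBp = 600000L) {
  stopifnot(nChromosomes >= 1, blocksPerChromosome >= 1, snpsPerBlock >= 1,
            withinBlockR2 >= 0, withinBlockR2 < 1,
            bpSpacing >= 1, blockGapBp >= 1)
  structure(list(nChromosomes = as.integer(nChromosomes),
                 blocksPerChromosome = as.integer(blocksPerChromosome),
                 snpsPerBlock = as.integer(snpsPerBlock),
                 withinBlockR2 = withinBlockR2,
                 bpSpacing = as.integer(bpSpacing),
                 blockGapBp = as.integer(blockGapBp)),
            class = "GenomeSpec")
}

#' Specify the two-trait causal architecture
#'
#' Controls how causal LD blocks are shared between the two simulated
#' traits. A fraction `pi1` of blocks is causal for trait 1, `pi2` for
#' trait 2, with `piShared` causal for both (`piShared <= min(pi1, pi2)`;
#' trait-specific causal blocks are disjoint between traits). Each
#' causal block carries one causal tag variant of standardized effect
#' magnitude `effectSd` with a random sign; for shared blocks the two
#' traits' signs agree with probability `pSignAgree` (1 = fully
#' concordant architecture, 0 = fully discordant, 0.5 = pleiotropy
#' without concordance). Block counts are deterministic
#' (`round(pi * nBlocks)`), so power is stable across seeds.
#'
#' `piShared` fixes the overlap exactly: note that `piShared = 0` makes
#' the two causal sets disjoint — a negative-overlap (exclusion)
#' architecture, not trait independence, since independently drawn sets
#' would overlap by chance in `pi1 * pi2` of blocks. For genuinely
#' independent traits set `piShared = NA`: the two causal sets are then
#' drawn independently and the realized chance intersection is recorded
#' as the shared set.
#'
#' @param pi1,pi2 Causal-block fractions per trait (default 0.3).
#' @param piShared Fraction causal in both (default 0.15), or `NA` for
#'   independent causal assignment (chance overlap).
#' @param pSignAgree Probability a shared block's signs agree
#'   (default 0.5).
#' @param effectSd Standardized per-causal-tag effect size (default
#'   0.02; at n = 10,000 this puts the causal tag's expected Z at
#'   \eqn{\sqrt{n} \cdot 0.02 = 2}, a realistically sub-genome-wide-
#'   significant polygenic signal).
#' @param n1,n2 GWAS sample sizes (default 10,000 each).
#' @return A `TwoTraitEffectSpec` list.
#' @export
effectSpec <- function(pi1 = 0.3, pi2 = 0.3, piShared = 0.15,
                       pSignAgree = 0.5, effectSd = 0.02,
                       n1 = 10000L, n2 = 10000L) {
  stopifnot(pi1 >= 0, pi1 <= 1, pi2 >= 0, pi2 <= 1,
            is.na(piShared) ||
              (piShared >= 0 && piShared <= min(pi1, pi2)),
            pSignAgree >= 0, pSignAgree <= 1,
            effectSd >= 0, n1 >= 2, n2 >= 2)
  structure(list(pi1 = pi1, pi2 = pi2, piShared = piShared,
                 pSignAgree = pSignAgree, effectSd = effectSd,
                 n1 = as.integer(n1), n2 = as.integer(n2)),
            class = "TwoTraitEffectSpec")
}

# non-palindromic ordered allele pairs (effect, other)
.allelePairs <- matrix(c("A","C", "A","G", "C","A", "C","T",
                         "G","A", "G","T", "T","C", "T","G"),
                       ncol = 2, byrow = TRUE)

#' Simulate paired GWAS summary statistics over an LD-block genome
#'
#' Generates two studies' summary statistics with a known shared-causal
#' structure, the exact pairwise r² table of the simulated LD, and a
#' ground-truth record, so every pipeline stage can be tested without
#' external data.
#'
#' Per block and trait, the SNP Z-scores are drawn from a multivariate
#' normal with compound-symmetry correlation (off-diagonal
#' \eqn{r = \sqrt{r^2_{\mathrm{block}}}}) and mean
#' \eqn{\sqrt{n}\,\beta\, r_i}, where \eqn{r_i} is the dosage
#' correlation of SNP i with the block's causal tag (1 at the tag,
#' \eqn{r} elsewhere) and \eqn{\beta = 0} for non-causal blocks. Null
#' blocks therefore have Z ~ N(0, 1) marginally, and the causal tag has
#' \eqn{E[\chi^2] = 1 + n\,\beta^2}. Two-sided p-values, per-SNP effect
#' sizes \eqn{\beta = Z/\sqrt{n}} with \eqn{SE = 1/\sqrt{n}}, shared
#' non-palindromic alleles and effect-allele frequencies complete the
#' tables.
#'
#' @param genome A [genomeSpec()] list.
#' @param effects An [effectSpec()] list.
#' @param seed Integer seed; all randomness is local to the call
#'   (the caller's RNG state is untouched).
#' @param traitLabels Length-2 character vector of trait names.
#' @return A list with elements `primary` and `secondary`
#'   ([SumStats-class]), `ld` ([LdReference-class]), and `truth` — a
#'   `data.frame` with one row per block (`block`, `chr`, `tagSnp`,
#'   `causal1`, `causal2`, `shared`, `sign1`, `sign2`) plus attributes
#'   `genome` and `effects`.
#' @examples
#' sim <- simulatePair(genomeSpec(nChromosomes = 1, blocksPerChromosome = 20),
#'                     effectSpec(piShared = 0.3, pSignAgree = 1),
#'                     seed = 42)
#' sum(sim$truth$shared)
#' @export
simulatePair <- function(genome = genomeSpec(), effects = effectSpec(),
                         seed = 1L,
                         traitLabels = c("trait1", "trait2")) {
  stopifnot(inherits(genome, "GenomeSpec"),
            inherits(effects, "TwoTraitEffectSpec"),
            length(traitLabels) == 2L)
  B <- genome$nChromosomes * genome$blocksPerChromosome
  k <- genome$snpsPerBlock
  rho <- sqrt(genome$withinBlockR2)

  withr::with_seed(as.integer(seed), {
    # causal architecture: deterministic counts, random placement
    causal1 <- logical(B); causal2 <- logical(B)
    if (is.na(effects$piShared)) {
      # independent assignment: overlap left to chance
      causal1[sample.int(B, round(effects$pi1 * B))] <- TRUE
      causal2[sample.int(B, round(effects$pi2 * B))] <- TRUE
    } else {
      nShared <- round(effects$piShared * B)
      nOnly1 <- round((effects$pi1 - effects$piShared) * B)
      nOnly2 <- round((effects$pi2 - effects$piShared) * B)
      pick <- sample.int(B, nShared + nOnly1 + nOnly2)
      causal1[pick[seq_len(nShared + nOnly1)]] <- TRUE
      causal2[pick[c(seq_len(nShared),
                     nShared + nOnly1 + seq_len(nOnly2))]] <- TRUE
    }
    shared <- causal1 & causal2

    sign1 <- integer(B); sign2 <- integer(B)
    sign1[causal1] <- sample(c(-1L, 1L), sum(causal1), replace = TRUE)
    agree <- ifelse(runif(B) < effects$pSignAgree, 1L, -1L)
    sign2[shared] <- sign1[shared] * agree[shared]
    sign2[causal2 & !shared] <- sample(c(-1L, 1L), sum(causal2 & !shared),
                                       replace = TRUE)
    tagIdx <- sample.int(k, B, replace = TRUE)

    # coordinates
    blockChr <- rep(seq_len(genome$nChromosomes),
                    each = genome$blocksPerChromosome)
    blockWithin <- rep(seq_len(genome$blocksPerChromosome),
                       times = genome$nChromosomes)
    blockSpan <- (k - 1L) * genome$bpSpacing
    blockStart <- 1L + (blockWithin - 1L) * (blockSpan + genome$blockGapBp)
    snpBlock <- rep(seq_len(B), each = k)
    snpChr <- as.character(blockChr[snpBlock])
    snpPos <- blockStart[snpBlock] +
      (rep(seq_len(k), times = B) - 1L) * genome$bpSpacing
    snpId <- sprintf("rs%07d", seq_len(B * k))
    isTag <- rep(seq_len(k), times = B) == tagIdx[snpBlock]

    # r-profile to the tag: 1 at the tag, rho elsewhere
    rProfile <- ifelse(isTag, 1, rho)

    drawTrait <- function(causal, sgn, nSamp) {
      beta <- ifelse(causal, sgn * effects$effectSd, 0)
      mu <- sqrt(nSamp) * beta[snpBlock] * rProfile
      u <- rnorm(B)                      # shared block component
      e <- rnorm(B * k)                  # idiosyncratic component
      z <- mu + sqrt(rho) * u[snpBlock] + sqrt(1 - rho) * e
      p <- 2 * pnorm(-abs(z))
      p[p == 0] <- .Machine$double.xmin
      list(z = z, p = p)
    }
    t1 <- drawTrait(causal1, sign1, effects$n1)
    t2 <- drawTrait(causal2, sign2, effects$n2)

    eaf <- runif(B * k, 0.05, 0.95)
    ap <- .allelePairs[sample.int(nrow(.allelePairs), B * k,
                                  replace = TRUE), , drop = FALSE]

    mkTable <- function(tr, nSamp, label) {
      makeSumStats(data.frame(
        snp = snpId, chr = snpChr, bp = snpPos,
        ea = ap[, 1], oa = ap[, 2], eaf = eaf,
        beta = tr$z / sqrt(nSamp), se = 1 / sqrt(nSamp), p = tr$p,
        stringsAsFactors = FALSE
      ), traitLabel = label, effectScale = "beta")
    }
    primary <- mkTable(t1, effects$n1, traitLabels[1])
    secondary <- mkTable(t2, effects$n2, traitLabels[2])

    # exact LD used: all within-block unordered pairs at withinBlockR2
    ld <- if (genome$withinBlockR2 > 0 && k > 1) {
      pairIdx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
      off <- rep((seq_len(B) - 1L) * k, each = nrow(pairIdx))
      LdReference(data.frame(
        snpA = snpId[off + pairIdx[, 1]],
        snpB = snpId[off + pairIdx[, 2]],
        r2 = genome$withinBlockR2
      ))
    } else LdReference()

    truth <- data.frame(
      block = seq_len(B),
      chr = as.character(blockChr),
      tagSnp = snpId[(seq_len(B) - 1L) * k + tagIdx],
      causal1 = causal1, causal2 = causal2, shared = shared,
      sign1 = sign1, sign2 = sign2,
      stringsAsFactors = FALSE
    )
  })
  attr(truth, "genome") <- genome
  attr(truth, "effects") <- effects
  list(primary = primary, secondary = secondary, ld = ld, truth = truth)
}

#' Named simulation fixtures for the test suite
#'
#' Seeded, documented parameter bundles exercising the regimes the
#' pipeline must distinguish:
#' \describe{
#'   \item{`null_pair`}{independent traits: the causal-block sets are
#'     drawn independently (`piShared = NA`) and relative signs are
#'     random — the calibration regime under which the cross-trait
#'     tests must be null-calibrated.}
#'   \item{`concordant_pair`}{all causal blocks shared
#'     (`pi1 = pi2 = piShared = 0.3`) with fully agreeing signs
#'     (`pSignAgree = 1`).}
#'   \item{`discordant_pair`}{as above with `pSignAgree = 0`.}
#'   \item{`pleiotropy_no_concordance`}{shared blocks with random
#'     relative signs (`pSignAgree = 0.5`).}
#'   \item{`cfdr_enriched`}{a sparser shared architecture
#'     (`pi1 = pi2 = piShared = 0.1`, `pSignAgree = 1`) with a
#'     well-powered conditioning study (`n2 = 40,000` vs `n1 = 10,000`,
#'     `effectSd = 0.025`), so conditioning rescues SNPs that are
#'     underpowered unconditionally.}
#' }
#'
#' @param name One of the fixture names above.
#' @param genome A [genomeSpec()] list (default desk-scale genome).
#' @param seed Integer seed passed to [simulatePair()].
#' @return As [simulatePair()].
#' @export
makeFixture <- function(name = c("null_pair", "concordant_pair",
                                 "discordant_pair",
                                 "pleiotropy_no_concordance",
                                 "cfdr_enriched"),
                        genome = genomeSpec(), seed = 1L) {
  name <- match.arg(name)
  eff <- switch(name,
    null_pair = effectSpec(pi1 = 0.3, pi2 = 0.3, piShared = NA,
                           pSignAgree = 0.5),
    concordant_pair = effectSpec(pi1 = 0.3, pi2 = 0.3, piShared = 0.3,
                                 pSignAgree = 1),
    discordant_pair = effectSpec(pi1 = 0.3, pi2 = 0.3, piShared = 0.3,
                                 pSignAgree = 0),
    pleiotropy_no_concordance = effectSpec(pi1 = 0.3, pi2 = 0.3,
                                           piShared = 0.3,
                                           pSignAgree = 0.5),
    cfdr_enriched = effectSpec(pi1 = 0.1, pi2 = 0.1, piShared = 0.1,
                               pSignAgree = 1, effectSd = 0.025,
                               n1 = 10000L, n2 = 40000L)
  )
  simulatePair(genome, eff, seed = seed)
}

#' Write a simulated pair to disk
#'
#' Emits the two summary-statistics tables in the format
#' [readSumstats()] reads, the PLINK-style r² table [readLdTable()]
#' reads, and the ground truth as JSON.
#'
#' @param sim Result of [simulatePair()] or [makeFixture()].
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix (default `"sim"`).
#' @return Named character vector of the four paths, invisibly.
#' @export
writeSimulatedPair <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    primary = file.path(dir, paste0(prefix, "_trait1.sumstats.txt")),
    secondary = file.path(dir, paste0(prefix, "_trait2.sumstats.txt")),
    ld = file.path(dir, paste0(prefix, "_ld.tsv")),
    truth = file.path(dir, paste0(prefix, "_truth.json"))
  )
  writeSumstats(sim$primary, paths["primary"])
  writeSumstats(sim$secondary, paths["secondary"])
  writeLdTable(sim$ld, paths["ld"])
  jsonlite::write_json(sim$truth, paths["truth"], digits = NA)
  invisible(paths)
}
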