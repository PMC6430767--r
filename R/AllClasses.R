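#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges granges seqnames start
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

#' Container for one trait's GWAS summary statistics
#'
#' A `SumStats` object holds validated, position-sorted per-SNP association
#' results for a single trait: variant identity and coordinates (as a
#' [GenomicRanges::GRanges]), effect/other alleles, effect-allele frequency,
#' signed effect size with its standard error, and the association p-value.
#'
#' @slot traitLabel Single string naming the trait.
#' @slot effectScale One of `"beta"`, `"z"`, `"log-odds"`; the scale on
#'   which the signed effect is reported.
#' @slot variants `GRanges` with one range per SNP (width 1, 1-based
#'   positions) and metadata columns `snp`, `ea`, `oa`, `eaf`, `beta`,
#'   `se`, `p`.
#' @slot nDropped Number of input rows dropped during validation.
#'
#' @seealso [readSumstats()], [simulatePair()]
#' @export
setClass("SumStats",
  slots = c(
    traitLabel = "character",
    effectScale = "character",
    variants = "GRanges",
    nDropped = "integer"
  )
)

setValidity("SumStats", function(object) {
  msg <- character()
  v <- object@variants
  mc <- S4Vectors::mcols(v)
  need <- c("snp", "ea", "oa", "eaf", "beta", "se", "p")
  if (!all(need %in% colnames(mc)))
    return(paste("variants must carry metadata columns:",
                 paste(need, collapse = ", ")))
  if (length(object@traitLabel) != 1L || !nzchar(object@traitLabel))
    msg <- c(msg, "traitLabel must be a non-empty string")
  if (!object@effectScale %in% c("beta", "z", "log-odds"))
    msg <- c(msg, "effectScale must be one of beta, z, log-odds")
  if (length(v)) {
    if (anyDuplicated(mc$snp))
      msg <- c(msg, "duplicate snp ids")
    if (any(!nzchar(mc$snp)))
      msg <- c(msg, "empty snp id")
    if (any(mc$p <= 0 | mc$p > 1, na.rm = TRUE) || anyNA(mc$p))
      msg <- c(msg, "p-values must lie in (0, 1]")
    if (any(!mc$ea %in% c("A", "C", "G", "T")) ||
        any(!mc$oa %in% c("A", "C", "G", "T")))
      msg <- c(msg, "alleles must be one of A, C, G, T")
    if (any(mc$ea == mc$oa))
      msg <- c(msg, "effect and other allele must differ")
    if (any(GenomicRanges::start(v) < 1))
      msg <- c(msg, "positions must be >= 1 (1-based)")
    if (any(mc$se <= 0, na.rm = TRUE))
      msg <- c(msg, "standard errors must be positive where present")
    key <- paste(as.character(GenomicRanges::seqnames(v)),
                 GenomicRanges::start(v))
    if (anyDuplicated(key))
      msg <- c(msg, "(chromosome, position) pairs must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Allele-harmonized variants shared by two traits
#'
#' Holds the SNPs present in two studies after allele harmonization:
#' for each SNP, the p-value and effect-direction sign in each trait, with
#' the secondary trait's sign expressed relative to the primary trait's
#' effect allele.
#'
#' @slot traitPrimary,traitSecondary Trait labels.
#' @slot variants `GRanges` with metadata columns `snp`, `p1`, `s1`,
#'   `p2`, `s2` (signs are `+1L`/`-1L`).
#' @slot nDroppedPalindromic Palindromic (A/T, C/G) SNPs removed.
#' @slot nDroppedIrreconcilable SNPs whose allele pairs could not be
#'   reconciled even after strand complement.
#'
#' @seealso [harmonize()]
#' @export
setClass("HarmonizedPair",
  slots = c(
    traitPrimary = "character",
    traitSecondary = "character",
    variants = "GRanges",
    nDroppedPalindromic = "integer",
    nDroppedIrreconcilable = "integer"
  )
)

setValidity("HarmonizedPair", function(object) {
  mc <- S4Vectors::mcols(object@variants)
  need <- c("snp", "p1", "s1", "p2", "s2")
  if (!all(need %in% colnames(mc)))
    return(paste("variants must carry:", paste(need, collapse = ", ")))
  if (length(object@variants)) {
    if (!all(mc$s1 %in% c(-1L, 1L)) || !all(mc$s2 %in% c(-1L, 1L)))
      return("signs must be -1 or +1")
    if (any(mc$p1 <= 0 | mc$p1 > 1) || any(mc$p2 <= 0 | mc$p2 > 1))
      return("p-values must lie in (0, 1]")
  }
  TRUE
})

#' Pairwise LD reference
#'
#' Sparse symmetric store of pairwise r-squared values between SNPs; any
#' pair not listed is taken to be in linkage equilibrium (r² = 0). Pairs
#' are canonicalized so (a, b) and (b, a) are the same entry.
#'
#' @slot pairs `data.frame` with columns `snpA`, `snpB`, `r2` and
#'   `snpA < snpB` lexicographically.
#'
#' @seealso [readLdTable()], [ldClump()]
#' @export
setClass("LdReference", slots = c(pairs = "data.frame"))

setValidity("LdReference", function(object) {
  p <- object@pairs
  if (!all(c("snpA", "snpB", "r2") %in% names(p)))
    return("pairs needs columns snpA, snpB, r2")
  if (nrow(p)) {
    if (any(p$r2 < 0 | p$r2 > 1)) return("r2 must lie in [0, 1]")
    if (any(p$snpA == p$snpB)) return("self-pairs not allowed")
    if (anyDuplicated(paste(p$snpA, p$snpB)))
      return("duplicate pair after canonicalization (conflicting r2?)")
  }
  TRUE
})

#' Independent index SNPs after greedy LD clumping
#'
#' @slot conditioningLabel Trait whose p-values ranked the clumping.
#' @slot index `GRanges` of retained index SNPs (metadata as in the
#'   clumped [HarmonizedPair]).
#' @slot removedCount SNPs absorbed into clumps.
#' @slot windowBp,r2Threshold The exclusion rule actually applied.
#'
#' @seealso [ldClump()]
#' @export
setClass("ClumpResult",
  slots = c(
    conditioningLabel = "character",
    index = "GRanges",
    removedCount = "integer",
    windowBp = "numeric",
    r2Threshold = "numeric"
  )
)

#' Permutation summary of one SECA test
#'
#' @slot mode `"pleiotropy"` or `"concordance"`.
#' @slot statistic Observed grid statistic (minimum cell-level one-sided
#'   p by default; optionally the count of cells below the cell alpha).
#' @slot empiricalP Add-one permutation p-value.
#' @slot ciLow,ciHigh Exact 95% Clopper-Pearson interval on `empiricalP`.
#' @slot direction `"+"`, `"-"`, or `"none"`.
#' @slot nPerm Number of permutations used.
#' @export
setClass("SecaSummary",
  slots = c(
    mode = "character",
    statistic = "numeric",
    empiricalP = "numeric",
    ciLow = "numeric",
    ciHigh = "numeric",
    direction = "character",
    nPerm = "integer"
  )
)

setValidity("SecaSummary", function(object) {
  if (object@empiricalP <= 0 || object@empiricalP > 1)
    return("empiricalP must lie in (0, 1]")
  if (object@ciLow > object@empiricalP || object@ciHigh < object@empiricalP)
    return("empiricalP must lie inside its confidence interval")
  if (!object@direction %in% c("+", "-", "none"))
    return("direction must be one of +, -, none")
  TRUE
})

#' Full SECA result for one trait pair
#'
#' @slot traitPrimary,traitSecondary Trait labels.
#' @slot nIndex Number of clumped index SNPs the grids were built on.
#' @slot pleiotropy,concordance [SecaSummary-class] objects.
#' @slot pleiotropyGrid,concordanceGrid Long-format per-cell tables.
#' @seealso [runSeca()]
#' @export
setClass("SecaResult",
  slots = c(
    traitPrimary = "character",
    traitSecondary = "character",
    nIndex = "integer",
    pleiotropy = "SecaSummary",
    concordance = "SecaSummary",
    pleiotropyGrid = "data.frame",
    concordanceGrid = "data.frame"
  )
)

#' Conditional FDR result for one trait pair
#'
#' @slot traitPrimary,traitSecondary Trait labels.
#' @slot table Per-SNP `data.frame`: `snp`, `chr`, `bp`, `pPrimary`,
#'   `qUnconditional`, `qConditionalMin`, `bestLevel`, `significant`.
#' @slot levels Conditioning q-value thresholds used.
#' @slot alpha Declaration threshold for `significant`.
#' @seealso [runCfdr()], [conditionalFdr()]
#' @export
setClass("CfdrResult",
  slots = c(
    traitPrimary = "character",
    traitSecondary = "character",
    table = "data.frame",
    levels = "numeric",
    alpha = "numeric"
  )
)
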