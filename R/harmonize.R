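#' Allele-harmonize two summary-statistics tables
#'
#' Restricts two studies to their shared SNPs and expresses the secondary
#' study's effect direction relative to the primary study's effect allele,
#' so that "agreement in SNP effect directions" is well defined across
#' studies. Four allele orientations are recognized per SNP: identical
#' alleles (sign kept), swapped effect/other alleles (sign flipped), and
#' the same two cases after strand complement (A<->T, C<->G). SNPs whose
#' allele pairs match none of the four orientations are dropped and
#' counted.
#'
#' Palindromic SNPs (A/T or C/G) are strand-ambiguous: their alleles match
#' both with and without complementing, so the sign cannot be resolved
#' from alleles alone. They are dropped by default. With
#' `freqRescue = TRUE`, a palindromic SNP is kept when both studies report
#' an effect-allele frequency clearly away from 0.5
#' (`|eaf - 0.5| > freqThreshold` in both) — the orientation is then the
#' one making the frequencies consistent.
#'
#' @param primary,secondary [SumStats-class] objects; matching is by SNP
#'   id, coordinates are taken from `primary`.
#' @param dropPalindromic Drop strand-ambiguous A/T and C/G SNPs
#'   (default `TRUE`).
#' @param freqRescue Attempt frequency-based orientation of palindromic
#'   SNPs instead of dropping them (default `FALSE`).
#' @param freqThreshold Minimum `|eaf - 0.5|` in both studies for a
#'   frequency rescue (default 0.08).
#' @return A [HarmonizedPair-class] object. Zero overlapping SNPs is an
#'   error.
#' @examples
#' sim <- simulatePair(genomeSpec(nChromosomes = 1, blocksPerChromosome = 5),
#'                     seed = 1)
#' hp <- harmonize(sim$primary, sim$secondary)
#' nVariants(hp)
#' @export
harmonize <- function(primary, secondary, dropPalindromic = TRUE,
                      freqRescue = FALSE, freqThreshold = 0.08) {
  stopifnot(is(primary, "SumStats"), is(secondary, "SumStats"))
  v1 <- primary@variants
  m1 <- S4Vectors::mcols(v1)
  m2 <- S4Vectors::mcols(secondary@variants)

  idx2 <- match(m1$snp, m2$snp)
  keep <- !is.na(idx2)
  if (!any(keep))
    stop("no overlapping SNPs between '", primary@traitLabel,
         "' and '", secondary@traitLabel, "'")
  v1 <- v1[keep]
  m1 <- m1[keep, , drop = FALSE]
  m2 <- m2[idx2[keep], , drop = FALSE]

  ea1 <- m1$ea; oa1 <- m1$oa
  ea2 <- m2$ea; oa2 <- m2$oa
  cea2 <- complementAllele(ea2)
  coa2 <- complementAllele(oa2)

  same <- ea2 == ea1 & oa2 == oa1
  swapped <- ea2 == oa1 & oa2 == ea1
  compSame <- cea2 == ea1 & coa2 == oa1
  compSwapped <- cea2 == oa1 & coa2 == ea1
  palin <- isPalindromic(ea1, oa1) | isPalindromic(ea2, oa2)

  flip <- rep(NA_integer_, length(ea1))   # NA = irreconcilable
  flip[compSwapped] <- -1L
  flip[compSame] <- 1L
  flip[swapped] <- -1L
  flip[same] <- 1L                        # direct match takes precedence

  nPalinDropped <- 0L
  if (any(palin)) {
    if (dropPalindromic && !freqRescue) {
      nPalinDropped <- sum(palin & !is.na(flip))
      flip[palin] <- NA_integer_
    } else if (freqRescue) {
      # Orient by allele-frequency consistency; drop ambiguous ones.
      f1 <- m1$eaf
      # frequency of the allele letter-matched to the primary effect allele
      f2 <- ifelse(ea2 == ea1 | cea2 == ea1, m2$eaf, 1 - m2$eaf)
      informative <- !is.na(f1) & !is.na(f2) &
        abs(f1 - 0.5) > freqThreshold & abs(f2 - 0.5) > freqThreshold
      agree <- (f1 - 0.5) * (f2 - 0.5) > 0
      flip[palin & informative & agree] <- 1L
      flip[palin & informative & !agree] <- -1L
      nPalinDropped <- sum(palin & !informative & !is.na(flip))
      flip[palin & !informative] <- NA_integer_
    }
  }
  nIrreconcilable <- sum(is.na(flip)) - nPalinDropped

  ok <- !is.na(flip)
  sign1 <- ifelse(m1$beta[ok] < 0, -1L, 1L)
  sign2 <- ifelse(m2$beta[ok] < 0, -1L, 1L) * flip[ok]

  gr <- GenomicRanges::granges(v1[ok])
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    snp = m1$snp[ok],
    p1 = m1$p[ok], s1 = as.integer(sign1),
    p2 = m2$p[ok], s2 = as.integer(sign2)
  )
  if (length(gr) == 0L)
    stop("no SNPs survived allele harmonization")
  new("HarmonizedPair",
      traitPrimary = primary@traitLabel,
      traitSecondary = secondary@traitLabel,
      variants = gr,
      nDroppedPalindromic = as.integer(nPalinDropped),
      nDroppedIrreconcilable = as.integer(nIrreconcilable))
}

#' Export a harmonized pair as a data.frame or TSV
#'
#' @param x A [HarmonizedPair-class] object.
#' @param path Optional output path; when given, a TSV with columns
#'   `snp, chr, bp, p1, sign1, p2, sign2` is written.
#' @return The `data.frame` (invisibly when `path` is given).
#' @export
harmonizedFrame <- function(x, path = NULL) {
  stopifnot(is(x, "HarmonizedPair"))
  mc <- S4Vectors::mcols(x@variants)
  df <- data.frame(
    snp = mc$snp,
    chr = as.character(GenomicRanges::seqnames(x@variants)),
    bp = GenomicRanges::start(x@variants),
    p1 = mc$p1, sign1 = mc$s1, p2 = mc$p2, sign2 = mc$s2,
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    data.table::fwrite(df, path, sep = "\t", quote = FALSE)
    return(invisible(df))
  }
  df
}
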