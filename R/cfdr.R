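#' Benjamini-Hochberg step-up q-values
#'
#' Step-up q-values for a vector of p-values: with sorted p-values
#' \eqn{p_{(1)} \le \dots \le p_{(n)}}, \eqn{q_{(i)} = \min_{j \ge i}
#' p_{(j)} n / j}, capped at 1 and mapped back to input order.
#'
#' @param p Numeric vector of p-values in \eqn{(0, 1]}.
#' @return Numeric vector of q-values, same length and order.
#' @examples
#' bhQvalues(c(0.001, 0.5))   # 0.002, 0.5
#' @export
bhQvalues <- function(p) {
  if (length(p) == 0L) stop("empty p-value vector")
  stopifnot(is.numeric(p), all(p > 0), all(p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Default conditioning q-value thresholds
#'
#' The 14 nested FDR levels at which conditioning subsets are formed:
#' q ≤ 1e-5, 1e-4, 1e-3, 0.01, 0.1, 0.2, ..., 0.9, 1.
#'
#' @return Ascending numeric vector of length 14 ending at 1.
#' @export
cfdrLevels <- function() {
  c(1e-5, 1e-4, 1e-3, 0.01, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1)
}

#' Conditional FDR across nested conditioning subsets
#'
#' For each conditioning level c, forms the subset of SNPs whose
#' conditioning-trait q-value is at most c, re-applies the
#' Benjamini-Hochberg procedure to the primary-trait p-values restricted
#' to that subset, and records per SNP the minimum within-subset q-value
#' over all subsets containing it. A SNP is declared significant when
#' that minimum is at or below `alpha`, i.e. when it passes FDR control
#' conditioned on any subset. Because the last level is 1, every SNP
#' belongs to the full set and `qConditionalMin` can never exceed the
#' unconditional q-value.
#'
#' Taking the minimum over nested subsets is a per-SNP best case and is
#' reported as such (no correction for the number of subsets examined).
#'
#' @param primaryP Primary-trait p-values on the clumped SNP set.
#' @param conditioningQ Conditioning-trait q-values, aligned to
#'   `primaryP` (typically `bhQvalues` of the secondary-trait p-values).
#' @param levels Conditioning thresholds; must be ascending and end at 1
#'   (default [cfdrLevels()]).
#' @param alpha FDR declaration threshold (default 0.05).
#' @param snp Optional SNP ids carried into the output.
#' @return `data.frame` with one row per SNP: `snp`, `pPrimary`,
#'   `qUnconditional`, `qConditionalMin`, `bestLevel`, `significant`.
#' @export
conditionalFdr <- function(primaryP, conditioningQ, levels = cfdrLevels(),
                           alpha = 0.05, snp = NULL) {
  n <- length(primaryP)
  stopifnot(n >= 1L, length(conditioningQ) == n,
            all(primaryP > 0), all(primaryP <= 1),
            all(conditioningQ > 0), all(conditioningQ <= 1),
            all(diff(levels) > 0), levels[length(levels)] == 1,
            alpha > 0, alpha <= 1)
  if (is.null(snp)) snp <- paste0("snp", seq_len(n))

  qMin <- rep(Inf, n)
  bestLevel <- rep(NA_real_, n)
  qUncond <- rep(NA_real_, n)
  for (lv in levels) {
    inS <- which(conditioningQ <= lv)
    if (length(inS) == 0L) {
      message(sprintf("conditioning level %g has an empty subset; skipped",
                      lv))
      next
    }
    qSub <- bhQvalues(primaryP[inS])
    if (lv == 1) qUncond <- qSub[match(seq_len(n), inS)]
    better <- qSub < qMin[inS]
    qMin[inS][better] <- qSub[better]
    bestLevel[inS][better] <- lv
  }
  data.frame(
    snp = snp,
    pPrimary = primaryP,
    qUnconditional = qUncond,
    qConditionalMin = qMin,
    bestLevel = bestLevel,
    significant = qMin <= alpha,
    stringsAsFactors = FALSE
  )
}

#' Run the conditional FDR analysis for a clumped trait pair
#'
#' Convenience wrapper: takes the clumped index SNPs of a harmonized
#' pair, computes conditioning q-values from the secondary trait's
#' p-values, and applies [conditionalFdr()] to the primary trait.
#'
#' @param clump A [ClumpResult-class] object (index SNPs carrying both
#'   traits' p-values).
#' @param levels,alpha See [conditionalFdr()].
#' @param traitPrimary,traitSecondary Labels for the result (defaults
#'   taken from the clump's conditioning label where available).
#' @return A [CfdrResult-class] object whose table also carries `chr`
#'   and `bp`.
#' @export
runCfdr <- function(clump, levels = cfdrLevels(), alpha = 0.05,
                    traitPrimary = "primary",
                    traitSecondary = clump@conditioningLabel) {
  stopifnot(is(clump, "ClumpResult"))
  gr <- clump@index
  mc <- S4Vectors::mcols(gr)
  condQ <- bhQvalues(mc$p2)
  tab <- conditionalFdr(mc$p1, condQ, levels = levels, alpha = alpha,
                        snp = mc$snp)
  tab$chr <- as.character(GenomicRanges::seqnames(gr))
  tab$bp <- GenomicRanges::start(gr)
  tab$qConditioning <- condQ
  tab <- tab[, c("snp", "chr", "bp", "pPrimary", "qUnconditional",
                 "qConditionalMin", "bestLevel", "qConditioning",
                 "significant")]
  new("CfdrResult", traitPrimary = traitPrimary,
      traitSecondary = traitSecondary, table = tab,
      levels = as.numeric(levels), alpha = alpha)
}

#' Approximate variance explained by a single SNP
#'
#' Converts a signed effect and its standard error to the percentage of
#' trait variance explained, via the squared-correlation identity for a
#' single regressor: \eqn{100 \, z^2 / (z^2 + n - 2)} with
#' \eqn{z = \mathrm{effect}/\mathrm{se}}. This is an approximation
#' (exact for simple linear regression on a quantitative trait) and is
#' reported for descriptive table columns only.
#'
#' @param effect Signed effect size.
#' @param se Standard error (> 0).
#' @param n Study sample size (> 1).
#' @return Percentage in \eqn{[0, 100]}.
#' @examples
#' varianceExplained(0.5, 0.1, 10000)   # z = 5 -> ~0.249%
#' @export
varianceExplained <- function(effect, se, n) {
  stopifnot(all(se > 0), all(n > 1))
  z <- effect / se
  100 * z^2 / (z^2 + n - 2)
}
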