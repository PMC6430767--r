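#' Build an LD reference from pairwise r-squared values
#'
#' @param pairs `data.frame` with columns `snpA`, `snpB`, `r2` (any
#'   extra columns are ignored). Pairs are canonicalized; a pair listed
#'   in both orders must carry the same r-squared.
#' @return An [LdReference-class] object.
#' @export
LdReference <- function(pairs = data.frame(snpA = character(),
                                           snpB = character(),
                                           r2 = numeric())) {
  stopifnot(all(c("snpA", "snpB", "r2") %in% names(pairs)))
  a <- as.character(pairs$snpA)
  b <- as.character(pairs$snpB)
  r2 <- as.numeric(pairs$r2)
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  df <- data.frame(snpA = a, snpB = b, r2 = r2, stringsAsFactors = FALSE)
  key <- paste(df$snpA, df$snpB)
  if (anyDuplicated(key)) {
    agg <- tapply(df$r2, key, function(v) diff(range(v)))
    if (any(agg > 1e-9))
      stop("conflicting r2 for pair(s) listed in both orders")
    df <- df[!duplicated(key), , drop = FALSE]
  }
  rownames(df) <- NULL
  new("LdReference", pairs = df)
}

#' Read a PLINK-style pairwise LD table
#'
#' Expects whitespace- or tab-delimited text with header columns
#' `SNP_A`, `SNP_B`, `R2` (extra columns, e.g. `CHR_A`/`BP_A` from
#' `plink --r2`, are ignored). Absent pairs are treated as r² = 0.
#'
#' @param path Path to the table (gzip accepted).
#' @return An [LdReference-class] object.
#' @export
readLdTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- freadText(path, header = TRUE, showProgress = FALSE)
  need <- c("SNP_A", "SNP_B", "R2")
  if (!all(need %in% names(dt)))
    stop("LD table needs columns SNP_A, SNP_B, R2")
  LdReference(data.frame(snpA = as.character(dt$SNP_A),
                         snpB = as.character(dt$SNP_B),
                         r2 = as.numeric(dt$R2)))
}

#' Write an LD reference as a PLINK-style table
#'
#' @param ld An [LdReference-class] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeLdTable <- function(ld, path) {
  stopifnot(is(ld, "LdReference"))
  out <- data.frame(SNP_A = ld@pairs$snpA, SNP_B = ld@pairs$snpB,
                    R2 = ld@pairs$r2)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Greedy LD clumping of a harmonized SNP set
#'
#' Reduces the harmonized SNP set to approximately independent index
#' SNPs: SNPs are ranked by one trait's p-value (ascending), and the
#' best unremoved SNP repeatedly becomes an index, removing every
#' unremoved SNP on the same chromosome within the window that is in LD
#' with it (r² above the threshold). A SNP is excluded only when it is
#' BOTH inside the window AND above the r² threshold. Every input SNP
#' ends up either an index or removed by exactly one index.
#'
#' Ranking defaults to the secondary trait, producing one independent
#' set of SNPs conditioned on the secondary trait's significance — the
#' conditioning used throughout the cross-trait analysis. Ties in the
#' ranking p-value are broken by (chromosome, position, SNP id)
#' ascending, so the result does not depend on input row order. SNPs
#' absent from the LD reference are treated as r² = 0 with everything
#' and become their own clumps.
#'
#' @param pair A [HarmonizedPair-class] object.
#' @param ld An [LdReference-class] object.
#' @param windowBp Half-width of the exclusion window in base pairs
#'   around each index SNP, inclusive (default 500,000, i.e. a 500 kb
#'   window on each side).
#' @param r2Threshold SNPs with r² strictly above this value are removed
#'   (default 0.2).
#' @param rankBy `"secondary"` (default) or `"primary"`: which trait's
#'   p-values rank the SNPs.
#' @return A [ClumpResult-class] object.
#' @examples
#' sim <- simulatePair(genomeSpec(nChromosomes = 1, blocksPerChromosome = 10),
#'                     seed = 7)
#' hp <- harmonize(sim$primary, sim$secondary)
#' ldClump(hp, sim$ld)
#' @export
ldClump <- function(pair, ld, windowBp = 5e5, r2Threshold = 0.2,
                    rankBy = c("secondary", "primary")) {
  stopifnot(is(pair, "HarmonizedPair"), is(ld, "LdReference"),
            windowBp > 0, r2Threshold >= 0, r2Threshold <= 1)
  rankBy <- match.arg(rankBy)
  v <- pair@variants
  n <- length(v)
  if (n == 0L) stop("no variants to clump")
  mc <- S4Vectors::mcols(v)
  chr <- as.character(GenomicRanges::seqnames(v))
  pos <- GenomicRanges::start(v)
  rankP <- if (rankBy == "secondary") mc$p2 else mc$p1

  # adjacency restricted to pairs exceeding the r2 threshold
  adj <- vector("list", n)
  pairsTbl <- ld@pairs
  if (nrow(pairsTbl)) {
    pairsTbl <- pairsTbl[pairsTbl$r2 > r2Threshold, , drop = FALSE]
    ia <- match(pairsTbl$snpA, mc$snp)
    ib <- match(pairsTbl$snpB, mc$snp)
    ok <- !is.na(ia) & !is.na(ib)
    ia <- ia[ok]; ib <- ib[ok]
    if (length(ia)) {
      edges <- split(c(ib, ia), c(ia, ib))
      adj[as.integer(names(edges))] <- edges
    }
  }

  ord <- order(rankP, chromRank(chr), pos, mc$snp)
  removed <- logical(n)
  isIndex <- logical(n)
  for (i in ord) {
    if (removed[i]) next
    isIndex[i] <- TRUE
    nb <- adj[[i]]
    if (!is.null(nb) && length(nb)) {
      hit <- nb[!removed[nb] & !isIndex[nb] & chr[nb] == chr[i] &
                  abs(pos[nb] - pos[i]) <= windowBp]
      removed[hit] <- TRUE
    }
  }
  idx <- v[isIndex]
  ord2 <- order(chromRank(as.character(GenomicRanges::seqnames(idx))),
                GenomicRanges::start(idx))
  new("ClumpResult",
      conditioningLabel = if (rankBy == "secondary") pair@traitSecondary
                          else pair@traitPrimary,
      index = idx[ord2],
      removedCount = as.integer(sum(removed)),
      windowBp = windowBp,
      r2Threshold = r2Threshold)
}

#' Export clumped index SNPs as a data.frame or TSV
#'
#' @param x A [ClumpResult-class] object.
#' @param path Optional TSV output path.
#' @return `data.frame` with columns `snp, chr, bp, p1, sign1, p2, sign2`.
#' @export
clumpFrame <- function(x, path = NULL) {
  stopifnot(is(x, "ClumpResult"))
  mc <- S4Vectors::mcols(x@index)
  df <- data.frame(
    snp = mc$snp,
    chr = as.character(GenomicRanges::seqnames(x@index)),
    bp = GenomicRanges::start(x@index),
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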