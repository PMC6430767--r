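# Independent oracles and fixture builders used across the suite.
# Oracles deliberately use the most literal definition available
# (enumeration, O(n^2) scans) and share no code with the implementation.

# --- fixture builders -------------------------------------------------

makeSumstatsDf <- function(snp, chr, bp, ea, oa, beta, p,
                           eaf = NA_real_, se = NA_real_) {
  data.frame(snp = snp, chr = chr, bp = bp, ea = ea, oa = oa,
             eaf = eaf, beta = beta, se = se, p = p,
             stringsAsFactors = FALSE)
}

makeSumStatsObj <- function(df, label = "t") {
  crossPleio:::makeSumStats(df, traitLabel = label)
}

writeSumstatsFixture <- function(df, path = tempfile(fileext = ".txt")) {
  hdr <- "SNP CHR BP A1 A2 FRQ BETA SE P"
  rows <- apply(df, 1, function(r)
    paste(r[["snp"]], r[["chr"]], r[["bp"]], r[["ea"]], r[["oa"]],
          r[["eaf"]], r[["beta"]], r[["se"]], r[["p"]]))
  writeLines(c(hdr, rows), path)
  path
}

# Directly assemble a HarmonizedPair from vectors (grids and clumping
# operate on this level).
makePair <- function(p1, s1, p2, s2, chr = NULL, pos = NULL, snp = NULL) {
  n <- length(p1)
  if (is.null(chr)) chr <- rep("1", n)
  if (is.null(pos)) pos <- seq_len(n) * 1000000L
  if (is.null(snp)) snp <- paste0("s", seq_len(n))
  gr <- GenomicRanges::GRanges(chr, IRanges::IRanges(pos, width = 1L))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    snp = snp, p1 = p1, s1 = as.integer(s1),
    p2 = p2, s2 = as.integer(s2))
  new("HarmonizedPair", traitPrimary = "a", traitSecondary = "b",
      variants = gr, nDroppedPalindromic = 0L,
      nDroppedIrreconcilable = 0L)
}

smallGenome <- function(blocks = 40L, chroms = 1L) {
  genomeSpec(nChromosomes = chroms, blocksPerChromosome = blocks)
}

# --- oracles ----------------------------------------------------------

# Benjamini-Hochberg by literal step-up definition, O(n^2).
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in i:n) best <- min(best, ps[j] * n / j)
    q[i] <- min(1, best)
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# Hypergeometric upper tail by direct summation of the pmf over the
# support, using choose() only.
enumHyperTail <- function(nBoth, K1, K2, n) {
  lo <- max(0, K1 + K2 - n)
  hi <- min(K1, K2)
  if (nBoth > hi) return(0)
  js <- max(nBoth, lo):hi
  sum(choose(K1, js) * choose(n - K1, K2 - js)) / choose(n, K2)
}

# P(#concordant >= k among n fair signs) by enumerating all 2^n
# outcomes as the bits of 0..2^n-1.
enumBinomTail <- function(n, k) {
  stopifnot(n <= 20)
  bits <- vapply(0:(2^n - 1), function(x)
    sum(as.integer(intToBits(x))[seq_len(n)]), numeric(1))
  mean(bits >= k)
}

# Greedy clumping by the literal definition: repeatedly pick the best
# unassigned SNP, drop everything in window and in LD with it. O(n^2),
# r2 looked up in a dense matrix.
bruteClump <- function(snp, chr, pos, rankP, r2mat, windowBp, r2th) {
  n <- length(snp)
  state <- rep("free", n)
  chrRank <- crossPleio:::chromRank(chr)
  while (any(state == "free")) {
    free <- which(state == "free")
    o <- free[order(rankP[free], chrRank[free], pos[free], snp[free])]
    i <- o[1]
    state[i] <- "index"
    for (j in which(state == "free")) {
      if (chr[j] == chr[i] && abs(pos[j] - pos[i]) <= windowBp &&
          r2mat[i, j] > r2th)
        state[j] <- "removed"
    }
  }
  snp[state == "index"]
}

randomClumpInstance <- function(n, seed) {
  set.seed(seed)
  nChr <- sample(1:2, 1)
  chr <- as.character(sample(seq_len(nChr), n, replace = TRUE))
  pos <- integer(n)
  repeat {
    pos <- sample.int(2000000L, n, replace = TRUE)
    if (!anyDuplicated(paste(chr, pos))) break
  }
  snp <- paste0("v", sample.int(10 * n, n))
  rankP <- runif(n)
  r2mat <- matrix(0, n, n)
  pairs <- NULL
  nPairs <- rbinom(1, n * 2, 0.5)
  if (nPairs > 0) {
    for (k in seq_len(nPairs)) {
      ij <- sample.int(n, 2)
      r2 <- runif(1)
      r2mat[ij[1], ij[2]] <- r2
      r2mat[ij[2], ij[1]] <- r2
      pairs <- rbind(pairs, data.frame(snpA = snp[ij[1]],
                                       snpB = snp[ij[2]], r2 = r2))
    }
    # keep last write in case the same pair was drawn twice
    pairs <- pairs[!duplicated(t(apply(pairs[, 1:2], 1, sort)),
                               fromLast = TRUE), , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      i <- match(pairs$snpA[r], snp); j <- match(pairs$snpB[r], snp)
      r2mat[i, j] <- pairs$r2[r]; r2mat[j, i] <- pairs$r2[r]
    }
  }
  windowBp <- sample(c(100000, 500000, 1000000), 1)
  r2th <- sample(c(0.1, 0.2, 0.5), 1)
  list(snp = snp, chr = chr, pos = pos, rankP = rankP, r2mat = r2mat,
       pairs = pairs, windowBp = windowBp, r2th = r2th)
}

# Run the package clumping on a random instance.
packageClump <- function(inst) {
  hp <- makePair(p1 = rep(0.5, length(inst$snp)), s1 = 1,
                 p2 = inst$rankP, s2 = 1,
                 chr = inst$chr, pos = inst$pos, snp = inst$snp)
  ld <- if (is.null(inst$pairs)) LdReference() else LdReference(inst$pairs)
  cl <- ldClump(hp, ld, windowBp = inst$windowBp,
                r2Threshold = inst$r2th)
  S4Vectors::mcols(indexVariants(cl))$snp
}

# Map a simulated SNP id back to its block.
blockOfSnp <- function(snp, genome) {
  (as.integer(sub("rs", "", snp)) - 1L) %/% genome$snpsPerBlock + 1L
}
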