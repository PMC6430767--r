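## Internal helpers shared across modules.

#' @importFrom stats p.adjust pbinom phyper pnorm qbeta runif rnorm setNames
#' @importFrom utils modifyList packageVersion
#' @importFrom withr with_seed
NULL

# "chr1", "Chr1", "1" all compare equal; chromosome labels are strings.
normalizeChrom <- function(x) {
  x <- toupper(trimws(as.character(x)))
  sub("^CHR", "", x)
}

# Natural order for chromosome labels: numeric labels first in numeric
# order, then X, Y, MT, then anything else alphabetically.
chromLevels <- function(x) {
  u <- unique(as.character(x))
  num <- suppressWarnings(as.numeric(u))
  special <- c("X", "Y", "MT", "M")
  isNum <- !is.na(num)
  isSpecial <- !isNum & u %in% special
  c(u[isNum][order(num[isNum])],
    u[isSpecial][order(match(u[isSpecial], special))],
    sort(u[!isNum & !isSpecial]))
}

chromRank <- function(x) {
  match(as.character(x), chromLevels(x))
}

complementAllele <- function(x) {
  chartr("ACGT", "TGCA", toupper(x))
}

isPalindromic <- function(ea, oa) {
  toupper(oa) == complementAllele(ea)
}

# fread via a decompressing connection for .gz paths (no optional
# dependency needed), plain fread otherwise.
freadText <- function(path, ...) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    data.table::fread(text = readLines(con), ...)
  } else {
    data.table::fread(path, ...)
  }
}

# Exact (Clopper-Pearson) two-sided binomial confidence interval.
clopperPearson <- function(x, n, conf = 0.95) {
  stopifnot(length(x) == 1L, length(n) == 1L, x >= 0, x <= n)
  a <- (1 - conf) / 2
  low <- if (x == 0) 0 else qbeta(a, x, n - x + 1)
  high <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
  c(low = low, high = high)
}

# p-values of exactly 0 are clamped so that ratio-based quantities (TDR,
# BH) stay defined; p must live in (0, 1].
clampPValues <- function(p, context = "p-value") {
  nzero <- sum(p == 0, na.rm = TRUE)
  if (nzero > 0) {
    warning(sprintf("%d %s(s) of exactly 0 clamped to %.3g",
                    nzero, context, .Machine$double.xmin), call. = FALSE)
    p[!is.na(p) & p == 0] <- .Machine$double.xmin
  }
  p
}

# Smallest index j with thresholds[j] >= p, for each p. Thresholds are
# strictly ascending and end at 1, so every p in (0,1] gets a bin.
thresholdBin <- function(p, thresholds) {
  findInterval(p, thresholds, left.open = TRUE) + 1L
}
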