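#' @importFrom data.table fread fwrite setDF
NULL

# Build a SumStats from a plain data.frame with columns
# snp, chr, bp, ea, oa, eaf, beta, se, p. Sorts by (chromosome, position).
makeSumStats <- function(df, traitLabel, effectScale = "beta",
                         nDropped = 0L) {
  chr <- normalizeChrom(df$chr)
  ord <- order(chromRank(chr), df$bp, df$snp)
  df <- df[ord, , drop = FALSE]
  chr <- chr[ord]
  gr <- GenomicRanges::GRanges(
    seqnames = chr,
    ranges = IRanges::IRanges(start = as.integer(df$bp), width = 1L)
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    snp = as.character(df$snp),
    ea = toupper(as.character(df$ea)),
    oa = toupper(as.character(df$oa)),
    eaf = as.numeric(df$eaf),
    beta = as.numeric(df$beta),
    se = as.numeric(df$se),
    p = as.numeric(df$p)
  )
  new("SumStats", traitLabel = traitLabel, effectScale = effectScale,
      variants = gr, nDropped = as.integer(nDropped))
}

#' Read a GWAS summary-statistics table
#'
#' Reads a whitespace- or tab-delimited text file (optionally
#' gzip-compressed) of per-SNP association results in METAL/PLINK-style
#' layout, validates each row, and returns a [SumStats-class] object
#' sorted by genomic position.
#'
#' Rows failing validation — unparseable numerics, p-values outside
#' \eqn{(0, 1]}, invalid or identical alleles, non-positive standard
#' errors, positions below 1 — are dropped with a warning that counts
#' them. p-values of exactly 0 are clamped to the smallest positive
#' double (they must stay positive for ratio-based statistics downstream).
#' A duplicated SNP id or duplicated (chromosome, position) pair is a
#' hard error, as is a missing mandatory column.
#'
#' @param path Path to the file. Default expected column names are
#'   `SNP, CHR, BP, A1, A2, FRQ, BETA, SE, P` (A1 = effect allele);
#'   `FRQ` and `SE` are optional.
#' @param columnMap Named character vector mapping the canonical names
#'   above to the file's actual header names, e.g.
#'   `c(SNP = "rsid", P = "pval")`. Unmapped names keep their defaults.
#' @param traitLabel Trait name stored in the object; defaults to the
#'   file name without extension.
#' @param effectScale Scale of the signed effect column: `"beta"`,
#'   `"z"`, or `"log-odds"`.
#' @return A [SumStats-class] object.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("SNP CHR BP A1 A2 FRQ BETA SE P",
#'              "rs1 1 1000 A G 0.4 0.12 0.05 0.016",
#'              "rs2 1 2000 C T 0.2 -0.05 0.04 0.21"), f)
#' ss <- readSumstats(f, traitLabel = "demo")
#' nVariants(ss)
#' @export
readSumstats <- function(path, columnMap = NULL, traitLabel = NULL,
                         effectScale = c("beta", "z", "log-odds")) {
  effectScale <- match.arg(effectScale)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(traitLabel))
    traitLabel <- sub("\\.(txt|tsv|gz|sumstats)+$", "",
                      basename(path), ignore.case = TRUE)

  cols <- c(SNP = "SNP", CHR = "CHR", BP = "BP", A1 = "A1", A2 = "A2",
            FRQ = "FRQ", BETA = "BETA", SE = "SE", P = "P")
  if (!is.null(columnMap)) {
    unknown <- setdiff(names(columnMap), names(cols))
    if (length(unknown))
      stop("columnMap names must be among: ",
           paste(names(cols), collapse = ", "))
    cols[names(columnMap)] <- columnMap
  }

  dt <- freadText(path, header = TRUE, colClasses = list(
    character = unname(cols[c("SNP", "CHR", "A1", "A2")])),
    showProgress = FALSE)
  mandatory <- cols[c("SNP", "CHR", "BP", "A1", "A2", "BETA", "P")]
  missing <- setdiff(unname(mandatory), names(dt))
  if (length(missing))
    stop("mandatory column(s) missing from ", path, ": ",
         paste(missing, collapse = ", "))

  getNum <- function(nm, default = NA_real_) {
    if (cols[[nm]] %in% names(dt))
      suppressWarnings(as.numeric(dt[[cols[[nm]]]]))
    else rep(default, nrow(dt))
  }
  df <- data.frame(
    snp = as.character(dt[[cols[["SNP"]]]]),
    chr = as.character(dt[[cols[["CHR"]]]]),
    bp = getNum("BP"),
    ea = toupper(as.character(dt[[cols[["A1"]]]])),
    oa = toupper(as.character(dt[[cols[["A2"]]]])),
    eaf = getNum("FRQ"),
    beta = getNum("BETA"),
    se = getNum("SE"),
    p = getNum("P"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$snp))
    stop("duplicate SNP id(s) in ", path, ", e.g. ",
         df$snp[anyDuplicated(df$snp)])

  df$p <- clampPValues(df$p)
  ok <- !is.na(df$bp) & df$bp >= 1 &
    !is.na(df$beta) & !is.na(df$p) & df$p > 0 & df$p <= 1 &
    df$ea %in% c("A", "C", "G", "T") & df$oa %in% c("A", "C", "G", "T") &
    df$ea != df$oa &
    (is.na(df$se) | df$se > 0) &
    (is.na(df$eaf) | (df$eaf >= 0 & df$eaf <= 1))
  nDropped <- sum(!ok)
  if (nDropped > 0)
    warning(sprintf("%d row(s) failed validation and were dropped from %s",
                    nDropped, basename(path)), call. = FALSE)
  makeSumStats(df[ok, , drop = FALSE], traitLabel, effectScale, nDropped)
}

#' Write a summary-statistics table to disk
#'
#' Writes a [SumStats-class] object in the same tab-delimited layout
#' [readSumstats()] reads (`SNP CHR BP A1 A2 FRQ BETA SE P`).
#'
#' @param x A [SumStats-class] object.
#' @param path Output path (`.gz` suffix gives gzip compression).
#' @return `path`, invisibly.
#' @export
writeSumstats <- function(x, path) {
  stopifnot(is(x, "SumStats"))
  v <- x@variants
  mc <- S4Vectors::mcols(v)
  out <- data.frame(
    SNP = mc$snp,
    CHR = as.character(GenomicRanges::seqnames(v)),
    BP = GenomicRanges::start(v),
    A1 = mc$ea, A2 = mc$oa, FRQ = mc$eaf,
    BETA = mc$beta, SE = mc$se, P = mc$p
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Intersect the variant sets of several studies
#'
#' Returns the SNPs present (by id) in every supplied table, in
#' deterministic (chromosome, position) order — the cross-study analysis
#' set on which clumping and all downstream tests operate.
#'
#' @param ... Two or more [SumStats-class] objects, or a single list of
#'   them.
#' @return `data.frame` with columns `snp`, `chr`, `bp` (coordinates from
#'   the first table).
#' @export
intersectAll <- function(...) {
  tables <- list(...)
  if (length(tables) == 1L && is.list(tables[[1]]) &&
      !is(tables[[1]], "SumStats"))
    tables <- tables[[1]]
  if (length(tables) < 2L)
    stop("need at least two SumStats tables")
  lapply(tables, function(t) stopifnot(is(t, "SumStats")))
  ids <- Reduce(intersect,
                lapply(tables, function(t) S4Vectors::mcols(t@variants)$snp))
  if (length(ids) == 0L)
    stop("no SNPs shared by all ", length(tables), " tables")
  v <- tables[[1]]@variants
  keep <- S4Vectors::mcols(v)$snp %in% ids
  v <- v[keep]
  data.frame(
    snp = S4Vectors::mcols(v)$snp,
    chr = as.character(GenomicRanges::seqnames(v)),
    bp = GenomicRanges::start(v),
    stringsAsFactors = FALSE
  )
}
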