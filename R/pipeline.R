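#' Bonferroni-corrected significance threshold
#'
#' The family-wise threshold for the cross-trait analysis:
#' 0.05 divided by the number of tests, counted as
#' (primary traits) × (brain-volume traits) × (methods). Three primary
#' traits, eight volumes and two methods give 0.05/48 = 1.042e-3.
#'
#' @param nTraits Number of primary traits (>= 1).
#' @param nVolumes Number of secondary traits (>= 1).
#' @param nMethods Number of testing methods counted (>= 1).
#' @return The corrected threshold, 0.05 / (nTraits * nVolumes * nMethods).
#' @examples
#' bonferroniThreshold(3, 8, 2)   # 0.05/48
#' @export
bonferroniThreshold <- function(nTraits, nVolumes, nMethods) {
  stopifnot(nTraits >= 1, nVolumes >= 1, nMethods >= 1)
  0.05 / (nTraits * nVolumes * nMethods)
}

#' Three-band significance annotation
#'
#' Annotates empirical p-values with the footnote convention of the
#' cross-trait tables: `"significant"` at or below the Bonferroni
#' threshold, `"nominal"` below 0.05, `"trending"` below 0.1, `"ns"`
#' otherwise. Bands are mutually exclusive and exhaustive on (0, 1].
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param threshold Bonferroni threshold (see [bonferroniThreshold()]).
#' @return Character vector of band labels.
#' @export
annotateSignificance <- function(p, threshold) {
  stopifnot(all(p > 0), all(p <= 1), threshold > 0)
  ifelse(p <= threshold, "significant",
         ifelse(p < 0.05, "nominal",
                ifelse(p < 0.1, "trending", "ns")))
}

#' Read a YAML run configuration
#'
#' Reads a single YAML document mirroring the arguments of [runAll()]:
#' `primary` (path + label), `secondary` (list of path + label), `ld`
#' (path), and optional `clump`, `seca`, `cfdr`, `bonferroni` blocks
#' overriding defaults.
#'
#' @param path Path to the YAML file.
#' @return A named list usable as [runAll()]'s `config`.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  yaml::read_yaml(path)
}

defaultRunConfig <- function() {
  list(
    clump = list(windowBp = 5e5, r2Threshold = 0.2),
    seca = list(nPerm = 9999L, thresholds = secaThresholds(),
                cellAlpha = 0.05, statistic = "minp"),
    cfdr = list(levels = cfdrLevels(), alpha = 0.05,
                strata = tdrStrata()),
    bonferroni = list(nMethods = 2L)
  )
}

loadTrait <- function(x, effectScale = "beta") {
  if (is(x, "SumStats")) return(x)
  if (is.list(x) && !is.null(x$path))
    return(readSumstats(x$path, columnMap = x$columnMap,
                        traitLabel = x$label,
                        effectScale = if (is.null(x$effectScale))
                          effectScale else x$effectScale))
  if (is.character(x)) return(readSumstats(x))
  stop("cannot interpret trait input")
}

#' Run the full cross-trait analysis for all trait pairs
#'
#' Orchestrates, for every (primary, secondary) pair: allele
#' harmonization, LD clumping conditioned on the secondary trait, the
#' SECA pleiotropy and concordance permutation tests, the conditional
#' FDR table, and stratified TDR curves. Writes per-primary-trait SECA
#' tables, per-pair conditional FDR tables, a combined table of
#' conditional discoveries, TDR plot data, and a machine-readable JSON
#' run log with the seed and full configuration, so every emitted
#' number is recomputable. A failure in one pair is caught, recorded in
#' the log, and does not stop the remaining pairs.
#'
#' @param config Named list (or path to a YAML file, see
#'   [readRunConfig()]) with elements `primary` (a [SumStats-class],
#'   path, or `list(path=, label=)`), `secondary` (list of the same),
#'   `ld` (an [LdReference-class] or path), and optional `clump`,
#'   `seca`, `cfdr`, `bonferroni` override blocks.
#' @param outputDir Directory for output files (created if absent).
#' @param seed Master integer seed; each pair's permutations derive a
#'   distinct sub-seed from it deterministically.
#' @return Invisibly, a list with `secaRows` (annotated per-pair
#'   summary `data.frame`), `seca` / `cfdr` / `tdr` (per-pair results),
#'   `discoveries` (conditionally significant SNPs),
#'   `bonferroniThreshold`, and `files`.
#' @export
runAll <- function(config, outputDir, seed = 1L) {
  if (is.character(config) && length(config) == 1L)
    config <- readRunConfig(config)
  cfg <- modifyList(defaultRunConfig(), config)
  if (is.null(cfg$primary) || is.null(cfg$secondary))
    stop("config must name a primary trait and at least one secondary trait")
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)

  primary <- loadTrait(cfg$primary)
  secondaries <- if (is(cfg$secondary, "SumStats")) list(cfg$secondary)
                 else if (is.list(cfg$secondary) &&
                          !is.null(cfg$secondary$path)) list(cfg$secondary)
                 else as.list(cfg$secondary)
  secondaries <- lapply(secondaries, loadTrait)
  ld <- if (is(cfg$ld, "LdReference")) cfg$ld else readLdTable(cfg$ld)

  nSec <- length(secondaries)
  nMethods <- cfg$bonferroni$nMethods
  nTests <- if (!is.null(cfg$bonferroni$nTests)) cfg$bonferroni$nTests
            else 1 * nSec * nMethods
  bonf <- 0.05 / nTests

  secaRes <- list(); cfdrRes <- list(); tdrRes <- list()
  errors <- list()
  rows <- NULL
  for (i in seq_len(nSec)) {
    sec <- secondaries[[i]]
    lab <- traitLabel(sec)
    pairSeed <- as.integer(seed) + 1000L * i
    res <- tryCatch({
      hp <- harmonize(primary, sec)
      cl <- ldClump(hp, ld, windowBp = cfg$clump$windowBp,
                    r2Threshold = cfg$clump$r2Threshold)
      pg <- pleiotropyGrid(cl, cfg$seca$thresholds, cfg$seca$thresholds)
      cg <- concordanceGrid(cl, cfg$seca$thresholds, cfg$seca$thresholds)
      pleio <- secaPermutation(cl, "pleiotropy", nPerm = cfg$seca$nPerm,
                               seed = pairSeed,
                               thresholds1 = cfg$seca$thresholds,
                               thresholds2 = cfg$seca$thresholds,
                               cellAlpha = cfg$seca$cellAlpha,
                               statistic = cfg$seca$statistic)
      conc <- secaPermutation(cl, "concordance", nPerm = cfg$seca$nPerm,
                              seed = pairSeed + 1L,
                              thresholds1 = cfg$seca$thresholds,
                              thresholds2 = cfg$seca$thresholds,
                              cellAlpha = cfg$seca$cellAlpha,
                              statistic = cfg$seca$statistic)
      seca <- new("SecaResult", traitPrimary = traitLabel(primary),
                  traitSecondary = lab, nIndex = length(cl@index),
                  pleiotropy = pleio, concordance = conc,
                  pleiotropyGrid = pg, concordanceGrid = cg)
      cf <- runCfdr(cl, levels = cfg$cfdr$levels, alpha = cfg$cfdr$alpha,
                    traitPrimary = traitLabel(primary),
                    traitSecondary = lab)
      mc <- S4Vectors::mcols(cl@index)
      td <- stratifiedTdr(mc$p1, mc$p2, strata = cfg$cfdr$strata,
                          evalGrid = tdrEvalGrid())
      list(seca = seca, cfdr = cf, tdr = td)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("pair '", lab, "' failed: ", conditionMessage(res),
              call. = FALSE)
      errors[[lab]] <- conditionMessage(res)
      next
    }
    secaRes[[lab]] <- res$seca
    cfdrRes[[lab]] <- res$cfdr
    tdrRes[[lab]] <- res$tdr
    rows <- rbind(rows, secaRow(res$seca))
  }
  if (is.null(rows)) stop("all trait pairs failed")

  rows$annotationPleiotropy <- annotateSignificance(rows$pPleiotropy, bonf)
  rows$annotationConcordance <- annotateSignificance(rows$pConcordance, bonf)

  # outputs
  files <- character()
  secaPath <- file.path(outputDir,
                        paste0("seca_", traitLabel(primary), ".tsv"))
  data.table::fwrite(rows, secaPath, sep = "\t", quote = FALSE)
  files <- c(files, seca = secaPath)

  discoveries <- NULL
  for (lab in names(cfdrRes)) {
    tab <- cfdrTable(cfdrRes[[lab]])
    p <- file.path(outputDir, paste0("cfdr_", lab, ".tsv"))
    data.table::fwrite(tab, p, sep = "\t", quote = FALSE)
    files <- c(files, setNames(p, paste0("cfdr_", lab)))
    sig <- tab[tab$significant, , drop = FALSE]
    if (nrow(sig)) {
      sig <- cbind(structure = lab, sig)
      discoveries <- rbind(discoveries, sig)
    }
    td <- tdrRes[[lab]]
    p2 <- file.path(outputDir, paste0("tdr_", lab, ".tsv"))
    data.table::fwrite(td, p2, sep = "\t", quote = FALSE)
    files <- c(files, setNames(p2, paste0("tdr_", lab)))
  }
  discPath <- file.path(outputDir, "cfdr_discoveries.tsv")
  if (is.null(discoveries))
    discoveries <- data.frame(structure = character(), snp = character())
  data.table::fwrite(discoveries, discPath, sep = "\t", quote = FALSE)
  files <- c(files, discoveries = discPath)

  logPath <- file.path(outputDir, "run_log.json")
  log <- list(
    package = "crossPleio",
    version = as.character(utils::packageVersion("crossPleio")),
    seed = as.integer(seed),
    bonferroniThreshold = bonf,
    nTests = nTests,
    clump = cfg$clump,
    seca = cfg$seca[c("nPerm", "thresholds", "cellAlpha", "statistic")],
    cfdr = cfg$cfdr,
    pairs = names(secaRes),
    errors = errors
  )
  jsonlite::write_json(log, logPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, log = logPath)

  invisible(list(secaRows = rows, seca = secaRes, cfdr = cfdrRes,
                 tdr = tdrRes, discoveries = discoveries,
                 bonferroniThreshold = bonf, files = files))
}
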