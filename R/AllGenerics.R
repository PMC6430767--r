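#' Accessors for crossPleio classes
#'
#' Small accessor generics: `traitLabel()` returns the trait name of a
#' [SumStats-class]; `variants()` the underlying `GRanges` of a
#' [SumStats-class] or [HarmonizedPair-class]; `nVariants()` the SNP count;
#' `indexVariants()` the retained index SNPs of a [ClumpResult-class];
#' `empiricalP()` and `direction()` the headline numbers of a
#' [SecaSummary-class]; `cfdrTable()` the per-SNP table of a
#' [CfdrResult-class].
#'
#' @param x An object of the documented class.
#' @return See the per-accessor description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("traitLabel", function(x) standardGeneric("traitLabel"))

#' @rdname accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))

#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname accessors
#' @export
setGeneric("indexVariants", function(x) standardGeneric("indexVariants"))

#' @rdname accessors
#' @export
setGeneric("empiricalP", function(x) standardGeneric("empiricalP"))

#' @rdname accessors
#' @export
setGeneric("direction", function(x) standardGeneric("direction"))

#' @rdname accessors
#' @export
setGeneric("cfdrTable", function(x) standardGeneric("cfdrTable"))

#' @rdname accessors
#' @export
setMethod("traitLabel", "SumStats", function(x) x@traitLabel)

#' @rdname accessors
#' @export
setMethod("variants", "SumStats", function(x) x@variants)

#' @rdname accessors
#' @export
setMethod("variants", "HarmonizedPair", function(x) x@variants)

#' @rdname accessors
#' @export
setMethod("nVariants", "SumStats", function(x) length(x@variants))

#' @rdname accessors
#' @export
setMethod("nVariants", "HarmonizedPair", function(x) length(x@variants))

#' @rdname accessors
#' @export
setMethod("indexVariants", "ClumpResult", function(x) x@index)

#' @rdname accessors
#' @export
setMethod("empiricalP", "SecaSummary", function(x) x@empiricalP)

#' @rdname accessors
#' @export
setMethod("direction", "SecaSummary", function(x) x@direction)

#' @rdname accessors
#' @export
setMethod("cfdrTable", "CfdrResult", function(x) x@table)

setMethod("show", "SumStats", function(object) {
  cat("SumStats for trait '", object@traitLabel, "' (",
      object@effectScale, " scale)\n", sep = "")
  cat("  ", length(object@variants), " variants on ",
      length(unique(as.character(GenomicRanges::seqnames(object@variants)))),
      " chromosome(s); ", object@nDropped, " row(s) dropped on read\n",
      sep = "")
})

setMethod("show", "HarmonizedPair", function(object) {
  cat("HarmonizedPair: '", object@traitPrimary, "' x '",
      object@traitSecondary, "'\n", sep = "")
  cat("  ", length(object@variants), " shared SNPs; dropped ",
      object@nDroppedPalindromic, " palindromic, ",
      object@nDroppedIrreconcilable, " irreconcilable\n", sep = "")
})

setMethod("show", "LdReference", function(object) {
  cat("LdReference with", nrow(object@pairs), "non-zero r2 pairs\n")
})

setMethod("show", "ClumpResult", function(object) {
  cat("ClumpResult ranked on '", object@conditioningLabel, "': ",
      length(object@index), " index SNPs (", object@removedCount,
      " removed; window +/-", format(object@windowBp, big.mark = ","),
      " bp, r2 > ", object@r2Threshold, ")\n", sep = "")
})

setMethod("show", "SecaSummary", function(object) {
  cat(sprintf("SECA %s: statistic = %g, empirical p = %.4g (95%% CI %.4g-%.4g), direction %s [%d permutations]\n",
              object@mode, object@statistic, object@empiricalP,
              object@ciLow, object@ciHigh, object@direction, object@nPerm))
})

setMethod("show", "SecaResult", function(object) {
  cat("SecaResult: '", object@traitPrimary, "' x '",
      object@traitSecondary, "' on ", object@nIndex,
      " index SNPs\n  ", sep = "")
  show(object@pleiotropy)
  cat("  ")
  show(object@concordance)
})

setMethod("show", "CfdrResult", function(object) {
  cat("CfdrResult: '", object@traitPrimary, "' | '",
      object@traitSecondary, "'\n  ", nrow(object@table), " SNPs, ",
      sum(object@table$significant), " significant at q <= ",
      object@alpha, " (", length(object@levels),
      " conditioning levels)\n", sep = "")
})
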