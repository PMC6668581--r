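#' @include AllClasses.R
NULL

#' Accessors for BTScan objects
#'
#' Small accessor family used instead of direct slot access: offsets and
#' score cells of scoring matrices, per-offset information content,
#' per-offset residue frequencies, and the number of training entries.
#'
#' @param x a \linkS4class{SignalPWM}, \linkS4class{BitScoreMatrix} or
#'   \linkS4class{WindowStack}.
#' @return \code{offsets}: integer vector of cleavage-anchored offsets;
#'   \code{cells}/\code{freqMatrix}: numeric matrix with one row per offset
#'   and one column per residue; \code{infoContent}: numeric vector of bits
#'   per offset; \code{trainingCount}: integer.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("offsets", function(x) standardGeneric("offsets"))
#' @rdname accessors
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))
#' @rdname accessors
#' @export
setGeneric("infoContent", function(x) standardGeneric("infoContent"))
#' @rdname accessors
#' @export
setGeneric("freqMatrix", function(x) standardGeneric("freqMatrix"))
#' @rdname accessors
#' @export
setGeneric("trainingCount", function(x) standardGeneric("trainingCount"))

#' @rdname accessors
setMethod("offsets", "SignalPWM", function(x) x@offsets)
#' @rdname accessors
setMethod("offsets", "BitScoreMatrix", function(x) x@offsets)
#' @rdname accessors
setMethod("offsets", "WindowStack", function(x) x@offsets)
#' @rdname accessors
setMethod("cells", "SignalPWM", function(x) x@cells)
#' @rdname accessors
setMethod("cells", "BitScoreMatrix", function(x) x@cells)
#' @rdname accessors
setMethod("infoContent", "BitScoreMatrix", function(x)
  stats::setNames(x@info, x@offsets))
#' @rdname accessors
setMethod("freqMatrix", "BitScoreMatrix", function(x) x@freq)
#' @rdname accessors
setMethod("trainingCount", "SignalPWM", function(x) x@nTrain)
#' @rdname accessors
setMethod("trainingCount", "BitScoreMatrix", function(x) x@nTrain)
#' @rdname accessors
setMethod("trainingCount", "WindowStack", function(x) nrow(x@rows))

#' Reference-set accessors
#'
#' @param x a \linkS4class{ReferenceSet}.
#' @return \code{refSequences}: the \code{AAStringSet} of reference
#'   proteins; \code{refInfo}: the per-protein annotation
#'   \code{DataFrame} (id, label, knownCleavage, excluded, reason).
#' @name reference-accessors
NULL

#' @rdname reference-accessors
#' @export
setGeneric("refSequences", function(x) standardGeneric("refSequences"))
#' @rdname reference-accessors
#' @export
setGeneric("refInfo", function(x) standardGeneric("refInfo"))
#' @rdname reference-accessors
setMethod("refSequences", "ReferenceSet", function(x) x@sequences)
#' @rdname reference-accessors
setMethod("refInfo", "ReferenceSet", function(x) x@info)

setMethod("show", "CleavageSite", function(object) {
  cat(sprintf("CleavageSite: %s, position %d (mature +1 = %d), %s, score %.3g\n",
              object@recordId, object@position, object@position + 1L,
              object@predictor, object@score))
})

setMethod("show", "ReferenceSet", function(object) {
  tab <- table(factor(object@info$label, levels = COMPARTMENTS))
  cat(sprintf("ReferenceSet with %d proteins (%d excluded)\n",
              nrow(object@info), sum(object@info$excluded)))
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat(sprintf("  known cleavage sites: %d\n",
              sum(!is.na(object@info$knownCleavage))))
})

setMethod("show", "SignalPWM", function(object) {
  cat(sprintf("SignalPWM over offsets %d..%d, trained on %d entries (pseudocount %.3g)\n",
              min(object@offsets), max(object@offsets), object@nTrain,
              object@pseudocount))
})

setMethod("show", "BitScoreMatrix", function(object) {
  cat(sprintf("BitScoreMatrix [%s] over offsets %d..%d, n = %d%s\n",
              if (nzchar(object@speciesTag)) object@speciesTag else "untagged",
              min(object@offsets), max(object@offsets), object@nTrain,
              if (object@correctionApplied) ", small-sample corrected" else ""))
  cat(sprintf("  total information: %.2f bits; max column: %.2f bits at offset %+d\n",
              sum(object@info), max(object@info),
              object@offsets[which.max(object@info)]))
})

setMethod("show", "WindowScanResult", function(object) {
  cat(sprintf("WindowScanResult: %s, cumulative %.3f, best window shift %+d (%s)\n",
              object@recordId, object@cumulativeScore,
              object@bestWindowOffset,
              if (object@agrees) "agrees" else "disagrees"))
})

setMethod("show", "PredictionResult", function(object) {
  cat(sprintf("PredictionResult: %s -> %s (score %.3g, threshold %.3g)\n",
              object@recordId, object@call, object@score, object@threshold))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts [%s @ %.3g]: tp=%d fp=%d fn=%d tn=%d\n",
              object@positiveClass, object@threshold,
              object@tp, object@fp, object@fn, object@tn))
})

setMethod("show", "BenchmarkCurve", function(object) {
  cat(sprintf("BenchmarkCurve for %s (positive class %s): %d thresholds in [%.3g, %.3g]\n",
              object@predictor, object@positiveClass, nrow(object@points),
              min(object@points$threshold), max(object@points$threshold)))
})

setMethod("show", "FixtureSpec", function(object) {
  cat(sprintf("FixtureSpec: %d per class, profile %s (P[F at +1] = %.2f), seed %d\n",
              object@nPerClass, object@speciesProfile, object@phePlus1Prob,
              object@seed))
})
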