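#' @include AllClasses.R
NULL

#' Confusion counts at a decision threshold
#'
#' Counts true/false positives/negatives for a one-vs-rest evaluation:
#' entries labelled \code{positiveClass} in \code{truth} are positives;
#' an entry is predicted positive when its score reaches the threshold
#' (inclusive, score >= threshold). Scores of \code{-Inf} (no detection)
#' never pass a finite threshold.
#'
#' @param scores named numeric vector of predictor scores.
#' @param truth named character vector of true labels; must cover exactly
#'   the same ids as \code{scores}.
#' @param positiveClass the label counted as positive.
#' @param threshold decision threshold.
#' @return a \linkS4class{ConfusionCounts}.
#' @export
confusionCounts <- function(scores, truth, positiveClass, threshold) {
  extra <- setdiff(names(scores), names(truth))
  missing <- setdiff(names(truth), names(scores))
  if (length(extra) || length(missing))
    stop("score/truth id mismatch; only in scores: {",
         paste(extra, collapse = ", "), "}; only in truth: {",
         paste(missing, collapse = ", "), "}")
  truth <- truth[names(scores)]
  isPos <- truth == positiveClass
  pass <- scores >= threshold
  new("ConfusionCounts",
      tp = sum(isPos & pass), fp = sum(!isPos & pass),
      fn = sum(isPos & !pass), tn = sum(!isPos & !pass),
      positiveClass = positiveClass, threshold = as.numeric(threshold))
}

#' Sensitivity (recall of the positive class)
#'
#' \code{tp / (tp + fn)}: the proportion of recognized true positives.
#' When no positives exist (\code{tp + fn = 0}) the metric is undefined
#' and \code{NA} is returned as an explicit marker — never silently 0.
#'
#' @param counts a \linkS4class{ConfusionCounts}.
#' @return a number in [0, 1], or \code{NA} when undefined.
#' @examples
#' sensitivity(new("ConfusionCounts", tp = 3L, fp = 0L, fn = 1L, tn = 0L,
#'                 positiveClass = "plastid", threshold = 1))
#' @export
sensitivity <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  denom <- counts@tp + counts@fn
  if (denom == 0L) return(NA_real_)
  counts@tp / denom
}

#' Precision (positive predictive value)
#'
#' \code{tp / (tp + fp)}: the proportion of true positives among all
#' entries passing the threshold. When nothing passes
#' (\code{tp + fp = 0}) the metric is undefined and \code{NA} is returned
#' as an explicit marker — never silently 0 or 1.
#'
#' @param counts a \linkS4class{ConfusionCounts}.
#' @return a number in [0, 1], or \code{NA} when undefined.
#' @export
precision <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  denom <- counts@tp + counts@fp
  if (denom == 0L) return(NA_real_)
  counts@tp / denom
}

#' Sweep a threshold grid into a sensitivity/precision curve
#'
#' Evaluates confusion counts, sensitivity and precision at every
#' threshold of the grid (by default the sorted unique finite scores).
#' Undefined precision points are kept in the curve as \code{NA}, never
#' dropped.
#'
#' @param scores named numeric scores.
#' @param truth named character labels over the same ids.
#' @param positiveClass the positive label.
#' @param grid optional numeric threshold grid; defaults to the sorted
#'   unique finite scores.
#' @param predictor name recorded in the curve.
#' @return a \linkS4class{BenchmarkCurve}.
#' @export
sweepThresholds <- function(scores, truth, positiveClass, grid = NULL,
                            predictor = "scores") {
  if (is.null(grid)) {
    grid <- sort(unique(scores[is.finite(scores)]))
    if (length(grid) < 2L)
      warning("fewer than 2 distinct finite scores; single-point curve")
  }
  grid <- sort(unique(as.numeric(grid)))
  if (length(grid) == 0L)
    stop("empty threshold grid")
  pts <- lapply(grid, function(thr) {
    cc <- confusionCounts(scores, truth, positiveClass, thr)
    data.frame(threshold = thr, sensitivity = sensitivity(cc),
               precision = precision(cc), tp = cc@tp, fp = cc@fp,
               fn = cc@fn, tn = cc@tn)
  })
  new("BenchmarkCurve", points = do.call(rbind, pts),
      predictor = predictor, positiveClass = positiveClass)
}

#' Select an operating threshold from a benchmark curve
#'
#' Implements the dual-threshold scheme used to report predictor
#' performance: \code{sensitivity_level} picks the largest threshold whose
#' sensitivity still reaches \code{level} (sensitivity is weakly
#' decreasing in the threshold, so this maximizes precision subject to
#' the sensitivity floor — the "s" threshold, typically at level 0.75);
#' \code{precision_level} picks the smallest threshold whose precision
#' reaches \code{level} (maximizing sensitivity subject to the precision
#' floor — the "p" threshold, typically 0.85). When the level is
#' unattainable anywhere on the curve the closest point is returned with
#' \code{attained = FALSE}.
#'
#' @param curve a \linkS4class{BenchmarkCurve}.
#' @param mode \code{"sensitivity_level"} or \code{"precision_level"}.
#' @param level the required metric floor, in (0, 1].
#' @return a list with elements \code{threshold}, \code{sensitivity},
#'   \code{precision} and \code{attained}.
#' @export
selectThreshold <- function(curve,
                            mode = c("sensitivity_level",
                                     "precision_level"),
                            level) {
  stopifnot(is(curve, "BenchmarkCurve"), level > 0, level <= 1)
  mode <- match.arg(mode)
  p <- curve@points
  if (nrow(p) == 0L) stop("empty benchmark curve")
  metric <- if (mode == "sensitivity_level") p$sensitivity else p$precision
  ok <- which(!is.na(metric) & metric >= level - 1e-12)
  if (length(ok)) {
    i <- if (mode == "sensitivity_level") max(ok) else min(ok)
    attained <- TRUE
  } else {
    defined <- which(!is.na(metric))
    if (length(defined) == 0L) defined <- seq_len(nrow(p))
    i <- defined[which.min(abs(metric[defined] - level))]
    attained <- FALSE
  }
  list(threshold = p$threshold[i], sensitivity = p$sensitivity[i],
       precision = p$precision[i], attained = attained)
}

#' Compare predictors at fixed sensitivity and precision levels
#'
#' Builds, for each predictor score table, the threshold sweep and the two
#' selected operating points: one aimed at higher sensitivity (the "s"
#' threshold at \code{levels["sensitivity"]}) and one aimed at high
#' precision (the "p" threshold at \code{levels["precision"]}).
#'
#' @param scoreTables named list of named numeric score vectors, one per
#'   predictor.
#' @param truth named character labels covering every scored id.
#' @param positiveClass the positive label (evaluation is one-vs-rest;
#'   plastid and mitochondrion benchmarks are run separately).
#' @param levels numeric with entries \code{sensitivity} (default 0.75)
#'   and \code{precision} (default 0.85).
#' @return a data.frame with one row per predictor and columns
#'   \code{predictor}, \code{threshold_s}, \code{sensitivity_s},
#'   \code{precision_s}, \code{attained_s}, \code{threshold_p},
#'   \code{sensitivity_p}, \code{precision_p}, \code{attained_p}.
#' @export
comparePredictors <- function(scoreTables, truth, positiveClass,
                              levels = c(sensitivity = 0.75,
                                         precision = 0.85)) {
  stopifnot(is.list(scoreTables), length(scoreTables) >= 1L)
  rows <- lapply(names(scoreTables), function(nm) {
    curve <- sweepThresholds(scoreTables[[nm]], truth, positiveClass,
                             predictor = nm)
    s <- selectThreshold(curve, "sensitivity_level",
                         levels[["sensitivity"]])
    p <- selectThreshold(curve, "precision_level", levels[["precision"]])
    data.frame(predictor = nm,
               threshold_s = s$threshold, sensitivity_s = s$sensitivity,
               precision_s = s$precision, attained_s = s$attained,
               threshold_p = p$threshold, sensitivity_p = p$sensitivity,
               precision_p = p$precision, attained_p = p$attained)
  })
  do.call(rbind, rows)
}

#' Write a predictor-comparison report to TSV
#'
#' @param report the data.frame returned by
#'   \code{\link{comparePredictors}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeBenchmarkReport <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
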