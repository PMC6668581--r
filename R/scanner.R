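#' @include AllClasses.R
NULL

#' Sliding-window transit-peptide scan at a cleavage site
#'
#' Scores a protein against a species-specific
#' \linkS4class{BitScoreMatrix} anchored at a predicted cleavage site.
#' The cumulative score sums matrix cells over the full offset span at the
#' cleavage anchor (cell(o, residue at site + o); X contributes 0). In
#' addition, a length-\code{windowLen} window of the early mature region
#' (matrix offsets +1..+windowLen) is slid across shifts d in
#' \code{shifts}: windowScores(d) scores residues starting at
#' \code{site + 1 + d} against those cells, localizing the conserved
#' transit-peptide Phe motif around the predicted cleavage site. The best
#' shift (ties to smallest |d|, then smallest d) must fall within
#' \code{tolerance} of the anchor for the scan to "agree".
#'
#' @param record a single-record \code{AAStringSet}.
#' @param site a \linkS4class{CleavageSite}.
#' @param matrix a \linkS4class{BitScoreMatrix}.
#' @param windowLen sliding-window length (default 5).
#' @param shifts candidate window shifts (default \code{-5:5}).
#' @param tolerance maximal |best shift| still counted as agreement
#'   (default 2).
#' @return a \linkS4class{WindowScanResult}.
#' @export
scanWindows <- function(record, site, matrix, windowLen = 5L,
                        shifts = -5:5, tolerance = 2L) {
  stopifnot(is(record, "AAStringSet"), length(record) == 1L,
            is(site, "CleavageSite"), is(matrix, "BitScoreMatrix"),
            windowLen >= 1L)
  s <- as.character(record[[1]])
  n <- nchar(s)
  off <- matrix@offsets
  if (site@position + off[1] < 1L || site@position + off[length(off)] > n)
    stop("cleavage site at ", site@position, " too close to a terminus ",
         "for the matrix span ", off[1], "..", off[length(off)],
         " (sequence length ", n, ")")
  chars <- strsplit(s, "")[[1]]
  cellAt <- function(o, pos) {
    a <- match(chars[pos], AA20)
    if (is.na(a)) 0 else matrix@cells[match(o, off), a]
  }
  cumulative <- sum(vapply(off, function(o)
    cellAt(o, site@position + o), numeric(1)))
  wOff <- (1:windowLen)
  if (!all(wOff %in% off))
    stop("matrix does not cover window offsets +1..+", windowLen)
  shifts <- as.integer(shifts)
  ws <- numeric(0)
  for (d in shifts) {
    pos <- site@position + 1L + d + (wOff - 1L)
    if (pos[1] < 1L || pos[length(pos)] > n) next
    ws[as.character(d)] <- sum(vapply(seq_along(wOff), function(j)
      cellAt(wOff[j], pos[j]), numeric(1)))
  }
  if (length(ws) == 0L)
    stop("cleavage site at ", site@position,
         " too close to a terminus for any window")
  dOk <- as.integer(names(ws))
  best <- max(ws)
  tied <- dOk[ws >= best - 1e-12]
  bestD <- tied[order(abs(tied), tied)][1]
  new("WindowScanResult", recordId = names(record),
      cumulativeScore = cumulative, windowScores = ws,
      bestWindowOffset = bestD,
      agrees = abs(bestD) <= tolerance)
}

#' Species threshold presets for the plastid scanner
#'
#' Named cumulative-score thresholds for the two shipped species profiles
#' (the calibrated operating points of the species-specific matrices):
#' 1.4 for the cvelia profile and 1.0 for the vbrassicaformis profile.
#'
#' @param preset \code{"cvelia"} or \code{"vbrassicaformis"}.
#' @return a numeric threshold.
#' @examples
#' thresholdPreset("cvelia")
#' @export
thresholdPreset <- function(preset = c("cvelia", "vbrassicaformis")) {
  preset <- match.arg(preset)
  c(cvelia = 1.4, vbrassicaformis = 1.0)[[preset]]
}

#' Classify one protein by the targeting-signal cascade
#'
#' Decision cascade: (1) with no consensus cleavage site, the protein is
#' called mitochondrion if an external mitochondrial score reaches
#' \code{mitoThreshold}, else other; (2) with a site, the transit-peptide
#' scan runs and the protein is called plastid iff the cumulative bit
#' score reaches \code{plastidThreshold} and the best window agrees with
#' the cleavage anchor; (3) with a site but no plastid evidence the call
#' is secretory (the signal peptide alone routes to the endomembrane
#' system). Scan failures on valid records degrade to an "other" call with
#' a warning, never an error.
#'
#' @param record a single-record \code{AAStringSet}.
#' @param site a consensus \linkS4class{CleavageSite} or \code{NULL}.
#' @param matrix a \linkS4class{BitScoreMatrix}.
#' @param plastidThreshold cumulative-score threshold (see
#'   \code{\link{thresholdPreset}}).
#' @param mitoScore optional external mitochondrial predictor score.
#' @param mitoThreshold threshold on \code{mitoScore} (default 0.5).
#' @param windowLen,tolerance passed to \code{\link{scanWindows}}.
#' @return a \linkS4class{PredictionResult}.
#' @export
classifyProtein <- function(record, site, matrix,
                            plastidThreshold = thresholdPreset("cvelia"),
                            mitoScore = NA_real_, mitoThreshold = 0.5,
                            windowLen = 5L, tolerance = 2L) {
  stopifnot(is.finite(plastidThreshold), is.finite(mitoThreshold))
  id <- names(record)
  if (is.null(site)) {
    if (!is.na(mitoScore) && mitoScore >= mitoThreshold)
      return(new("PredictionResult", recordId = id, call = "mitochondrion",
                 score = mitoScore, threshold = mitoThreshold,
                 cleavage = NULL, scan = NULL, mitoScore = mitoScore))
    return(new("PredictionResult", recordId = id, call = "other",
               score = if (is.na(mitoScore)) NA_real_ else mitoScore,
               threshold = mitoThreshold, cleavage = NULL, scan = NULL,
               mitoScore = mitoScore))
  }
  scan <- tryCatch(
    scanWindows(record, site, matrix, windowLen = windowLen,
                tolerance = tolerance),
    error = function(e) {
      warning("scan failed for '", id, "': ", conditionMessage(e),
              "; calling 'other'")
      NULL
    })
  if (is.null(scan))
    return(new("PredictionResult", recordId = id, call = "other",
               score = NA_real_, threshold = plastidThreshold,
               cleavage = site, scan = NULL, mitoScore = mitoScore))
  call <- if (scan@cumulativeScore >= plastidThreshold && scan@agrees)
    "plastid" else "secretory"
  new("PredictionResult", recordId = id, call = call,
      score = scan@cumulativeScore, threshold = plastidThreshold,
      cleavage = site, scan = scan, mitoScore = mitoScore)
}

#' Predict localization for a whole sequence set
#'
#' Runs the full internal pipeline on every record: PWM cleavage-site
#' prediction, consensus calling (trivially, over the single internal
#' predictor; external sites may be mixed in by the caller), the
#' sliding-window scan and the classification cascade.
#'
#' @param sequences an \code{AAStringSet}.
#' @param pwm a \linkS4class{SignalPWM} for cleavage-site prediction.
#' @param matrix a \linkS4class{BitScoreMatrix} for transit-peptide
#'   scoring.
#' @param plastidThreshold cumulative-score threshold.
#' @param mitoScores optional named numeric of external mitochondrial
#'   scores.
#' @param mitoThreshold threshold on the mitochondrial score.
#' @param searchRange,minScore passed to
#'   \code{\link{predictCleavagePWM}}.
#' @param windowLen,tolerance passed to \code{\link{scanWindows}}.
#' @return a data.frame with one row per record: \code{id}, \code{call},
#'   \code{score}, \code{threshold}, \code{cleavage_position},
#'   \code{best_window_offset}, \code{agrees}. The \code{score} column
#'   carries the cumulative bit score where a cleavage site was found and
#'   \code{-Inf} otherwise, so it can be fed directly to
#'   \code{\link{sweepThresholds}}.
#' @export
predictLocalization <- function(sequences, pwm, matrix,
                                plastidThreshold = thresholdPreset("cvelia"),
                                mitoScores = NULL, mitoThreshold = 0.5,
                                searchRange = 10:45, minScore = 4,
                                windowLen = 5L, tolerance = 2L) {
  stopifnot(is(sequences, "AAStringSet"))
  ids <- names(sequences)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rec <- sequences[i]
    site <- predictCleavagePWM(rec, pwm, searchRange = searchRange,
                               minScore = minScore)
    cons <- if (is.null(site)) NULL else consensusCleavage(list(site))
    ms <- if (!is.null(mitoScores) && ids[i] %in% names(mitoScores))
      mitoScores[[ids[i]]] else NA_real_
    res <- classifyProtein(rec, cons, matrix,
                           plastidThreshold = plastidThreshold,
                           mitoScore = ms, mitoThreshold = mitoThreshold,
                           windowLen = windowLen, tolerance = tolerance)
    out[[i]] <- data.frame(
      id = ids[i], call = res@call,
      score = if (is.null(res@scan)) -Inf else res@scan@cumulativeScore,
      threshold = res@threshold,
      cleavage_position = if (is.null(res@cleavage)) NA_integer_
                          else res@cleavage@position,
      best_window_offset = if (is.null(res@scan)) NA_integer_
                           else res@scan@bestWindowOffset,
      agrees = if (is.null(res@scan)) NA else res@scan@agrees)
  }
  do.call(rbind, out)
}

#' Write a prediction table to TSV
#'
#' @param predictions the data.frame returned by
#'   \code{\link{predictLocalization}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePredictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
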