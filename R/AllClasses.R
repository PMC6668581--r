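#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
NULL

## 20 standard residues; X is the only tolerated ambiguity character and is
## excluded from all counting and scoring.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA21 <- c(AA20, "X")

COMPARTMENTS <- c("plastid", "mitochondrion", "cytosol", "secretory")
CALLS <- c("plastid", "secretory", "mitochondrion", "other")

.uniformBackground <- function() {
  stats::setNames(rep(1 / 20, 20), AA20)
}

.checkBackground <- function(background) {
  if (!is.numeric(background) || length(background) != 20 ||
      is.null(names(background)) || !setequal(names(background), AA20))
    return("background must be a numeric vector named by the 20 standard residues")
  if (any(background < 0)) return("background frequencies must be non-negative")
  if (abs(sum(background) - 1) > 1e-9)
    return("background frequencies must sum to 1")
  NULL
}

.isContiguous <- function(offsets) {
  length(offsets) >= 1 && !anyNA(offsets) &&
    identical(as.integer(offsets), seq(offsets[1], offsets[length(offsets)]))
}

#' Predicted signal-peptide cleavage site
#'
#' Records a cleavage position on one protein. \code{position} is the
#' 1-based index of the \emph{last} residue of the signal peptide, so the
#' mature protein starts at \code{position + 1} (the "+1" convention used
#' throughout the package: +1 is the first mature residue, where
#' plastid-targeted proteins of rhodophyte-derived lineages typically carry
#' a conserved phenylalanine).
#'
#' @slot recordId id of the scored protein.
#' @slot position 1-based index of the last signal-peptide residue.
#' @slot predictor name of the predictor that produced the site.
#' @slot score predictor-specific score (for consensus sites: the number of
#'   supporting predictors).
#' @export
setClass("CleavageSite",
  representation(recordId = "character", position = "integer",
                 predictor = "character", score = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@recordId) != 1L || length(object@position) != 1L ||
        length(object@predictor) != 1L || length(object@score) != 1L)
      msg <- c(msg, "all slots must have length 1")
    else {
      if (is.na(object@position) || object@position < 1L)
        msg <- c(msg, "position must be a positive integer")
      if (!nzchar(object@predictor))
        msg <- c(msg, "predictor must be non-empty")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Labelled reference protein set
#'
#' Couples an \code{AAStringSet} of curated reference proteins with a
#' per-protein table of compartment labels, optional known cleavage
#' positions and exclusion flags (e.g. organellar genome-encoded proteins
#' that are retained in the table but dropped from training).
#'
#' @slot sequences \code{AAStringSet}, names are unique ids.
#' @slot info \code{DataFrame} with columns \code{id}, \code{label}
#'   (plastid / mitochondrion / cytosol / secretory), \code{knownCleavage}
#'   (integer or NA), \code{excluded} (logical), \code{reason} (character).
#' @export
setClass("ReferenceSet",
  representation(sequences = "AAStringSet", info = "DataFrame"),
  validity = function(object) {
    msg <- NULL
    info <- object@info
    need <- c("id", "label", "knownCleavage", "excluded", "reason")
    if (!all(need %in% colnames(info)))
      return(paste("info must have columns:", paste(need, collapse = ", ")))
    if (!all(info$id %in% names(object@sequences)))
      msg <- c(msg, "every info id must name a sequence")
    if (anyDuplicated(info$id))
      msg <- c(msg, "duplicate ids in info table")
    if (!all(info$label %in% COMPARTMENTS))
      msg <- c(msg, paste("labels must be one of:",
                          paste(COMPARTMENTS, collapse = ", ")))
    kc <- info$knownCleavage
    len <- width(object@sequences)[match(info$id, names(object@sequences))]
    bad <- !is.na(kc) & (kc < 1L | kc >= len)
    if (any(bad))
      msg <- c(msg, paste("knownCleavage out of range for:",
                          paste(info$id[bad], collapse = ", ")))
    if (is.null(msg)) TRUE else msg
  })

#' Position weight matrix for signal-peptide cleavage sites
#'
#' Log-odds scoring matrix anchored at the cleavage site: cell (o, a) is
#' log2 of the pseudocount-smoothed frequency of residue a at offset o
#' (offset 0 = last signal-peptide residue) over its background frequency.
#'
#' @slot offsets contiguous integer offsets relative to the cleavage site.
#' @slot cells numeric matrix, rows = offsets, columns = the 20 residues.
#' @slot background per-residue background frequency, sums to 1.
#' @slot pseudocount smoothing pseudocount used in training (> 0).
#' @slot nTrain number of training entries used.
#' @export
setClass("SignalPWM",
  representation(offsets = "integer", cells = "matrix",
                 background = "numeric", pseudocount = "numeric",
                 nTrain = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!.isContiguous(object@offsets))
      msg <- c(msg, "offsets must be a contiguous integer range")
    if (!identical(dim(object@cells),
                   c(length(object@offsets), 20L)) ||
        !identical(colnames(object@cells), AA20))
      msg <- c(msg, "cells must be a |offsets| x 20 matrix with residue columns")
    if (any(!is.finite(object@cells)))
      msg <- c(msg, "every cell must be finite")
    bg <- .checkBackground(object@background)
    if (!is.null(bg)) msg <- c(msg, bg)
    if (object@pseudocount <= 0)
      msg <- c(msg, "pseudocount must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' Stack of aligned cleavage-site windows
#'
#' One row per training protein, columns = offsets anchored at the
#' consensus cleavage site (+1 = first mature residue). The raw material
#' for a \linkS4class{BitScoreMatrix}.
#'
#' @slot offsets contiguous integer offsets.
#' @slot rows character matrix of single residues, one row per protein.
#' @slot ids record ids, one per row.
#' @export
setClass("WindowStack",
  representation(offsets = "integer", rows = "matrix", ids = "character"),
  validity = function(object) {
    msg <- NULL
    if (!.isContiguous(object@offsets))
      msg <- c(msg, "offsets must be a contiguous integer range")
    if (ncol(object@rows) != length(object@offsets))
      msg <- c(msg, "rows must span all offsets")
    if (nrow(object@rows) < 2L)
      msg <- c(msg, "a window stack needs at least 2 rows")
    if (nrow(object@rows) != length(object@ids))
      msg <- c(msg, "one id per row required")
    if (!all(object@rows %in% AA21))
      msg <- c(msg, "rows may contain only the 20 residues and X")
    if (is.null(msg)) TRUE else msg
  })

#' Bit-score-weighted cleavage-site matrix
#'
#' Per-offset, per-residue weights cell(o, a) = freq(o, a) * info(o), where
#' info(o) is the positional information content in bits (log2(20) minus
#' the Shannon entropy of the residue distribution at o, optionally reduced
#' by a small-sample correction and clamped at 0). These are the letter
#' heights of a sequence logo, and the species-specific scoring weights of
#' the sliding-window transit-peptide scanner.
#'
#' @slot offsets contiguous integer offsets anchored at the cleavage site.
#' @slot freq per-offset residue frequencies (rows sum to 1).
#' @slot info per-offset information content in bits, in [0, log2(20)].
#' @slot cells freq * info, all non-negative.
#' @slot nTrain number of training rows.
#' @slot correctionApplied whether the small-sample correction was applied.
#' @slot speciesTag free-text tag of the training set (e.g. a species name).
#' @export
setClass("BitScoreMatrix",
  representation(offsets = "integer", freq = "matrix", info = "numeric",
                 cells = "matrix", nTrain = "integer",
                 correctionApplied = "logical", speciesTag = "character"),
  validity = function(object) {
    msg <- NULL
    no <- length(object@offsets)
    if (!.isContiguous(object@offsets))
      msg <- c(msg, "offsets must be a contiguous integer range")
    for (nm in c("freq", "cells")) {
      m <- slot(object, nm)
      if (!identical(dim(m), c(no, 20L)) || !identical(colnames(m), AA20))
        msg <- c(msg, paste(nm, "must be a |offsets| x 20 residue matrix"))
    }
    if (length(object@info) != no)
      msg <- c(msg, "info must have one value per offset")
    if (is.null(msg)) {
      if (any(abs(rowSums(object@freq) - 1) > 1e-9))
        msg <- c(msg, "frequencies must sum to 1 at every offset")
      if (any(object@info < -1e-12 | object@info > log2(20) + 1e-12))
        msg <- c(msg, "info must lie in [0, log2(20)]")
      if (any(abs(rowSums(object@cells) - object@info) > 1e-9))
        msg <- c(msg, "cells must sum to info at every offset")
      if (any(object@cells < -1e-12))
        msg <- c(msg, "all cells must be non-negative")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Result of a sliding-window transit-peptide scan
#'
#' @slot recordId id of the scanned protein.
#' @slot cumulativeScore sum of matrix cells over the full offset span at
#'   the cleavage anchor.
#' @slot windowScores named numeric: score of the length-w window starting
#'   at +1 shifted by d residues, for each shift d.
#' @slot bestWindowOffset shift attaining the maximal window score (ties to
#'   smallest |d|, then smallest d).
#' @slot agrees whether the best window lies within the agreement tolerance
#'   of the cleavage anchor.
#' @export
setClass("WindowScanResult",
  representation(recordId = "character", cumulativeScore = "numeric",
                 windowScores = "numeric", bestWindowOffset = "integer",
                 agrees = "logical"),
  validity = function(object) {
    msg <- NULL
    if (!is.finite(object@cumulativeScore))
      msg <- c(msg, "cumulative score must be finite")
    ws <- object@windowScores
    if (length(ws)) {
      best <- ws[as.character(object@bestWindowOffset)]
      if (is.na(best) || best < max(ws) - 1e-12)
        msg <- c(msg, "bestWindowOffset must attain the maximal window score")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Localization call for one protein
#'
#' @slot recordId protein id.
#' @slot call one of plastid / secretory / mitochondrion / other.
#' @slot score the governing score of the call (cumulative bit score for
#'   plastid/secretory, external mitochondrial score for mitochondrion,
#'   NA for other when no evidence exists).
#' @slot threshold the threshold the governing score was compared against.
#' @slot cleavage consensus \linkS4class{CleavageSite} or NULL.
#' @slot scan \linkS4class{WindowScanResult} or NULL.
#' @slot mitoScore external mitochondrial score or NA.
#' @export
setClass("PredictionResult",
  representation(recordId = "character", call = "character",
                 score = "numeric", threshold = "numeric",
                 cleavage = "ANY", scan = "ANY", mitoScore = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!object@call %in% CALLS)
      msg <- c(msg, paste("call must be one of:", paste(CALLS, collapse = ", ")))
    if (identical(object@call, "plastid")) {
      if (is.null(object@cleavage))
        msg <- c(msg, "a plastid call requires a cleavage site")
      if (is.na(object@score) || object@score < object@threshold)
        msg <- c(msg, "a plastid call requires score >= threshold")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Confusion counts at one threshold
#'
#' @slot tp,fp,fn,tn non-negative counts; they sum to the cohort size.
#' @slot positiveClass the label counted as positive.
#' @slot threshold the (inclusive, score >= threshold) decision threshold.
#' @export
setClass("ConfusionCounts",
  representation(tp = "integer", fp = "integer", fn = "integer",
                 tn = "integer", positiveClass = "character",
                 threshold = "numeric"),
  validity = function(object) {
    counts <- c(object@tp, object@fp, object@fn, object@tn)
    if (any(is.na(counts)) || any(counts < 0L))
      "counts must be non-negative integers" else TRUE
  })

#' Sensitivity/precision curve over a threshold grid
#'
#' @slot points data.frame with columns threshold, sensitivity, precision,
#'   tp, fp, fn, tn; thresholds strictly increasing, sensitivity weakly
#'   decreasing. Undefined precision points carry NA (flagged, not
#'   dropped).
#' @slot predictor predictor name.
#' @slot positiveClass the positive label.
#' @export
setClass("BenchmarkCurve",
  representation(points = "data.frame", predictor = "character",
                 positiveClass = "character"),
  validity = function(object) {
    msg <- NULL
    p <- object@points
    need <- c("threshold", "sensitivity", "precision",
              "tp", "fp", "fn", "tn")
    if (!all(need %in% colnames(p)))
      return(paste("points must have columns:", paste(need, collapse = ", ")))
    if (nrow(p) > 1) {
      if (any(diff(p$threshold) <= 0))
        msg <- c(msg, "thresholds must be strictly increasing")
      s <- p$sensitivity[!is.na(p$sensitivity)]
      if (length(s) > 1 && any(diff(s) > 1e-12))
        msg <- c(msg, "sensitivity must be weakly decreasing")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Specification of a synthetic labelled fixture
#'
#' Parameterizes the seeded generator of synthetic proteins with the
#' presequence architecture the scanner assumes: plastid proteins carry a
#' signal peptide followed by a transit peptide whose first mature residue
#' (+1) is phenylalanine with a species-profile-specific probability
#' (strongly conserved in the cvelia_like profile, weaker in
#' vbrassicaformis_like); mitochondrial proteins carry shorter Arg-rich
#' presequences; secretory proteins a signal peptide only; cytosolic
#' proteins no presequence.
#'
#' @slot nPerClass proteins generated per compartment class.
#' @slot seed RNG seed; the generator is deterministic given the seed.
#' @slot speciesProfile "cvelia_like" or "vbrassicaformis_like".
#' @slot phePlus1Prob probability of Phe at +1 for plastid proteins.
#' @slot signalLenRange min/max signal-peptide length.
#' @slot btsExtensionRange min/max total N-terminal extension
#'   (signal + transit) of plastid proteins.
#' @slot mitoPresequenceRange min/max mitochondrial presequence length.
#' @slot matureLenRange min/max mature-domain length.
#' @slot background per-residue background frequency for unstructured
#'   segments.
#' @export
setClass("FixtureSpec",
  representation(nPerClass = "integer", seed = "integer",
                 speciesProfile = "character", phePlus1Prob = "numeric",
                 signalLenRange = "integer", btsExtensionRange = "integer",
                 mitoPresequenceRange = "integer", matureLenRange = "integer",
                 background = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@nPerClass < 1L)
      msg <- c(msg, "nPerClass must be >= 1")
    if (!object@speciesProfile %in% c("cvelia_like", "vbrassicaformis_like"))
      msg <- c(msg, "speciesProfile must be cvelia_like or vbrassicaformis_like")
    if (object@phePlus1Prob < 0 || object@phePlus1Prob > 1)
      msg <- c(msg, "phePlus1Prob must lie in [0, 1]")
    for (nm in c("signalLenRange", "btsExtensionRange",
                 "mitoPresequenceRange", "matureLenRange")) {
      r <- slot(object, nm)
      if (length(r) != 2L || r[1] > r[2] || r[1] < 1L)
        msg <- c(msg, paste(nm, "must be a non-empty positive range"))
    }
    bg <- .checkBackground(object@background)
    if (!is.null(bg)) msg <- c(msg, bg)
    if (is.null(msg)) TRUE else msg
  })
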