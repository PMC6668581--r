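#' @include AllClasses.R
NULL

PREDICTORS <- c("targetp", "signalp", "hectar", "multiloc2", "predisi",
                "predsl", "generic")

## column-name mappings for the supported dialects; "generic" is the
## documented, guaranteed interchange format; per-tool mappings are
## best-effort converters for common tabular exports of those tools
.DIALECTS <- list(
  generic   = c(id = "id", score = "score", cleavage = "cleavage",
                call = "call"),
  signalp   = c(id = "name", score = "D", cleavage = "pos", call = NA),
  targetp   = c(id = "Name", score = "mTP", cleavage = "TPlen",
                call = "Loc"),
  hectar    = c(id = "protein_id", score = "score", cleavage = NA,
                call = "predicted_targeting_category"),
  multiloc2 = c(id = "id", score = "mitochondrial", cleavage = NA,
                call = "prediction"),
  predisi   = c(id = "id", score = "score", cleavage = "position",
                call = "signal"),
  predsl    = c(id = "id", score = "score", cleavage = "cleavage",
                call = "prediction"))

#' Parse an external localization-predictor output table
#'
#' Converts tab-separated output of an external predictor into a uniform
#' prediction table. The \code{generic} dialect (TSV with header columns
#' \code{id}, \code{score}, \code{cleavage}, \code{call}) is fully
#' specified; per-tool dialects (signalp, targetp, hectar, multiloc2,
#' predisi, predsl) are best-effort column mappings for common export
#' formats of those tools. Parsing is all-or-nothing: rows whose score
#' fails numeric parsing are reported with their line numbers and the
#' whole file is rejected, so bad rows can never be silently dropped.
#'
#' @param path path to the TSV file.
#' @param dialect one of the documented dialect names.
#' @return a data.frame with columns \code{record_id}, \code{predictor},
#'   \code{score}, \code{cleavage_position}, \code{raw_call}.
#' @export
parsePredictorTable <- function(path, dialect = "generic") {
  if (!dialect %in% names(.DIALECTS))
    stop("unknown dialect '", dialect, "'; supported: ",
         paste(names(.DIALECTS), collapse = ", "))
  if (!file.exists(path)) stop("predictor table not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           quote = "", comment.char = "#",
                           colClasses = "character")
  if (nrow(tab) == 0L) stop("empty predictor table: ", path)
  map <- .DIALECTS[[dialect]]
  for (col in c("id", "score")) {
    if (!map[[col]] %in% colnames(tab))
      stop("dialect '", dialect, "' expects column '", map[[col]],
           "' in ", path)
  }
  score <- suppressWarnings(as.numeric(tab[[map[["score"]]]]))
  bad <- which(is.na(score) | !is.finite(score))
  if (length(bad))
    stop("non-numeric or non-finite score in row(s) ",
         paste(bad, collapse = ", "), " of ", path,
         " (line(s) ", paste(bad + 1L, collapse = ", "),
         " counting the header)")
  cleav <- if (!is.na(map[["cleavage"]]) &&
               map[["cleavage"]] %in% colnames(tab))
    suppressWarnings(as.integer(tab[[map[["cleavage"]]]]))
  else rep(NA_integer_, nrow(tab))
  call <- if (!is.na(map[["call"]]) && map[["call"]] %in% colnames(tab))
    tab[[map[["call"]]]] else rep(NA_character_, nrow(tab))
  data.frame(record_id = tab[[map[["id"]]]],
             predictor = dialect, score = score,
             cleavage_position = cleav, raw_call = call,
             stringsAsFactors = FALSE)
}

#' Collapse a prediction table into a score map
#'
#' @param predictions data.frame from \code{\link{parsePredictorTable}};
#'   must stem from a single predictor.
#' @param predictor the expected predictor name (checked).
#' @return a named numeric vector id -> score, suitable for
#'   \code{\link{sweepThresholds}}.
#' @export
toScoreTable <- function(predictions, predictor) {
  stopifnot(is.data.frame(predictions))
  if (nrow(predictions) == 0L) return(stats::setNames(numeric(0), character(0)))
  preds <- unique(predictions$predictor)
  if (length(preds) > 1L)
    stop("predictions mix multiple predictors: ",
         paste(preds, collapse = ", "))
  if (!identical(preds, predictor))
    stop("predictions are from '", preds, "', not '", predictor, "'")
  if (anyDuplicated(predictions$record_id))
    stop("duplicate record ids: ",
         paste(unique(predictions$record_id[
           duplicated(predictions$record_id)]), collapse = ", "))
  stats::setNames(predictions$score, predictions$record_id)
}

#' Extract external cleavage sites from a prediction table
#'
#' Helper to feed external predictor output into
#' \code{\link{consensusCleavage}}: rows with a cleavage position become
#' \linkS4class{CleavageSite} objects.
#'
#' @param predictions data.frame from \code{\link{parsePredictorTable}}.
#' @return a named list (by record id) of \linkS4class{CleavageSite}.
#' @export
externalCleavageSites <- function(predictions) {
  keep <- !is.na(predictions$cleavage_position)
  out <- lapply(which(keep), function(i)
    cleavageSite(predictions$record_id[i],
                 predictions$cleavage_position[i],
                 predictions$predictor[i], predictions$score[i]))
  stats::setNames(out, predictions$record_id[keep])
}
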