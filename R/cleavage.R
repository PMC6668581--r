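#' @include AllClasses.R
NULL

#' Construct a CleavageSite
#'
#' @param recordId protein id.
#' @param position 1-based index of the last signal-peptide residue (the
#'   mature protein starts at \code{position + 1}).
#' @param predictor predictor name.
#' @param score predictor score.
#' @return a validated \linkS4class{CleavageSite}.
#' @export
cleavageSite <- function(recordId, position, predictor, score = NA_real_) {
  new("CleavageSite", recordId = as.character(recordId),
      position = as.integer(position), predictor = as.character(predictor),
      score = as.numeric(score))
}

.residueCounts <- function(chars) {
  ## counts over the 20 standard residues; X (and anything else) ignored
  tab <- table(factor(chars, levels = AA20))
  as.numeric(tab)
}

#' Train a log-odds signal-peptide cleavage PWM
#'
#' Builds a position weight matrix over a window of offsets anchored at
#' known cleavage sites (offset 0 = last signal-peptide residue, offset +1
#' = first mature residue). Cell (o, a) is
#' \code{log2((count(a at o) + pseudocount) / (n_eff(o) + 20 * pseudocount)
#' / background(a))}, where \code{n_eff(o)} counts non-X residues at offset
#' o; X never contributes to counts. Entries whose sequence does not cover
#' the full offset window are skipped with a warning.
#'
#' @param refset a \linkS4class{ReferenceSet}; only non-excluded entries
#'   with a known cleavage position are used.
#' @param offsets contiguous window relative to the cleavage site; the
#'   default \code{-13:2} covers the classic signal-peptidase footprint.
#' @param pseudocount smoothing pseudocount (> 0, default 1).
#' @param background per-residue background frequency (default uniform
#'   0.05); an alternative background, e.g. estimated from cytosolic
#'   references, may be supplied.
#' @return a \linkS4class{SignalPWM}.
#' @export
trainSignalPWM <- function(refset, offsets = -13:2, pseudocount = 1,
                           background = NULL) {
  stopifnot(is(refset, "ReferenceSet"))
  if (is.null(background)) background <- .uniformBackground()
  background <- background[AA20]
  offsets <- as.integer(offsets)
  usable <- filterReferenceSet(refset, withCleavage = TRUE)
  info <- refInfo(usable)
  if (nrow(info) == 0L)
    stop("no usable training entries (need known cleavage positions)")
  seqs <- refSequences(usable)
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(info))) {
    pos <- info$knownCleavage[i]
    s <- as.character(seqs[[info$id[i]]])
    lo <- pos + offsets[1]
    hi <- pos + offsets[length(offsets)]
    if (lo < 1L || hi > nchar(s)) {
      skipped <- skipped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- strsplit(substr(s, lo, hi), "")[[1]]
  }
  if (skipped > 0L)
    warning(skipped, " training entr(y/ies) skipped: sequence does not ",
            "cover offsets ", offsets[1], "..", offsets[length(offsets)])
  if (length(rows) == 0L)
    stop("no usable training entries cover the offset window")
  if (length(rows) < 2L)
    stop("at least 2 usable training entries are required")
  mat <- do.call(rbind, rows)
  cellsM <- matrix(NA_real_, nrow = length(offsets), ncol = 20L,
                   dimnames = list(offsets, AA20))
  for (j in seq_along(offsets)) {
    cnt <- .residueCounts(mat[, j])
    nEff <- sum(cnt)
    freq <- (cnt + pseudocount) / (nEff + 20 * pseudocount)
    cellsM[j, ] <- log2(freq / background)
  }
  new("SignalPWM", offsets = offsets, cells = cellsM,
      background = background, pseudocount = as.numeric(pseudocount),
      nTrain = length(rows))
}

#' Predict a cleavage site with a PWM scan
#'
#' Scores every candidate cleavage position p in \code{searchRange} as the
#' sum of PWM cells over the window \code{p + offsets(pwm)} (X residues
#' contribute 0) and returns the maximal-scoring position if its score
#' reaches \code{minScore}, otherwise nothing. Ties break to the smallest
#' position. Candidate positions whose window would run past either
#' terminus are dropped; if none remain, nothing is returned.
#'
#' The default search range 10..45 reflects the length distribution of
#' N-terminal extensions observed on curated plastid references (about
#' 40-80 residues of bipartite signal upstream of the mature protein, with
#' the signal-peptide part occupying roughly its first half) and shorter
#' mitochondrial presequences.
#'
#' @param record a single-record \code{AAStringSet}.
#' @param pwm a \linkS4class{SignalPWM}.
#' @param searchRange candidate positions for the last signal-peptide
#'   residue (default \code{10:45}).
#' @param minScore minimal log-odds score to report a site (default 4, i.e.
#'   at least a 16-fold enrichment over background across the window).
#' @return a \linkS4class{CleavageSite}, or \code{NULL} when no candidate
#'   reaches \code{minScore}.
#' @export
predictCleavagePWM <- function(record, pwm, searchRange = 10:45,
                               minScore = 4) {
  stopifnot(is(record, "AAStringSet"), length(record) == 1L,
            is(pwm, "SignalPWM"))
  s <- as.character(record[[1]])
  n <- nchar(s)
  off <- pwm@offsets
  range <- as.integer(searchRange)
  range <- range[range + off[1] >= 1L & range + off[length(off)] <= n]
  if (length(range) == 0L) return(NULL)
  chars <- strsplit(s, "")[[1]]
  best <- -Inf
  bestPos <- NA_integer_
  for (p in range) {
    res <- chars[p + off]
    idx <- match(res, AA20)
    sc <- sum(pwm@cells[cbind(which(!is.na(idx)), idx[!is.na(idx)])])
    if (sc > best + 1e-12) {
      best <- sc
      bestPos <- p
    }
  }
  if (!is.finite(best) || best < minScore) return(NULL)
  cleavageSite(names(record), bestPos, "pwm", best)
}

#' Call a consensus cleavage site across predictors
#'
#' Implements majority agreement across independent signal-peptide
#' predictors: among the k predictors that returned any site, a position
#' wins if supported by more than k/2 of them (strict majority). Exact
#' position identity is required by default; \code{tolerance} allows
#' near-identical positions (within \code{tolerance} residues) to count as
#' agreement, in which case the supported position reported is the one
#' with maximal support (ties to the smallest position).
#'
#' @param sites a list of \linkS4class{CleavageSite} or \code{NULL}
#'   elements, at most one per predictor.
#' @param tolerance maximal position difference still counted as agreement
#'   (default 0 = exact identity).
#' @return a \linkS4class{CleavageSite} with \code{predictor = "consensus"}
#'   and \code{score} = number of supporting predictors, or \code{NULL}
#'   when no strict majority exists.
#' @export
consensusCleavage <- function(sites, tolerance = 0L) {
  stopifnot(is.list(sites))
  got <- Filter(Negate(is.null), sites)
  if (length(sites) == 0L)
    stop("at least one predictor output must be supplied")
  if (length(got) == 0L) return(NULL)
  ok <- vapply(got, function(x) is(x, "CleavageSite"), logical(1))
  if (!all(ok)) stop("sites must contain CleavageSite objects or NULL")
  preds <- vapply(got, function(x) x@predictor, character(1))
  if (anyDuplicated(preds))
    stop("multiple sites from the same predictor: ",
         paste(unique(preds[duplicated(preds)]), collapse = ", "))
  ids <- unique(vapply(got, function(x) x@recordId, character(1)))
  if (length(ids) > 1L)
    stop("sites refer to different records: ", paste(ids, collapse = ", "))
  pos <- vapply(got, function(x) x@position, integer(1))
  k <- length(pos)
  cand <- sort(unique(pos))
  support <- vapply(cand, function(p) sum(abs(pos - p) <= tolerance),
                    integer(1))
  winners <- cand[support > k / 2]
  if (length(winners) == 0L) return(NULL)
  best <- winners[which.max(support[match(winners, cand)])]
  cleavageSite(ids, best, "consensus",
               support[match(best, cand)])
}

#' Read and write per-predictor cleavage-site tables
#'
#' The on-disk format for cleavage predictions is a TSV with header
#' columns \code{id}, \code{position}, \code{score}; one file per
#' predictor.
#'
#' @param sites a list of \linkS4class{CleavageSite} objects.
#' @param path file path.
#' @param predictor predictor name assigned to the rows read.
#' @return \code{writeCleavageSites}: \code{path} invisibly;
#'   \code{readCleavageSites}: a list of \linkS4class{CleavageSite}.
#' @export
writeCleavageSites <- function(sites, path) {
  sites <- Filter(Negate(is.null), sites)
  df <- data.frame(
    id = vapply(sites, function(x) x@recordId, character(1)),
    position = vapply(sites, function(x) x@position, integer(1)),
    score = vapply(sites, function(x) x@score, numeric(1)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeCleavageSites
#' @export
readCleavageSites <- function(path, predictor) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("id", "position") %in% colnames(tab)))
    stop("cleavage table must have columns 'id' and 'position'")
  if (!"score" %in% colnames(tab)) tab$score <- NA_real_
  lapply(seq_len(nrow(tab)), function(i)
    cleavageSite(tab$id[i], tab$position[i], predictor, tab$score[i]))
}

#' Serialize a SignalPWM to TSV
#'
#' Rows are offsets, columns the 20 residues; a '#'-prefixed metadata
#' header records pseudocount, training size and background.
#'
#' @param pwm a \linkS4class{SignalPWM}.
#' @param path file path.
#' @return \code{path} (write) or a \linkS4class{SignalPWM} (read).
#' @export
writeSignalPWM <- function(pwm, path) {
  stopifnot(is(pwm, "SignalPWM"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# SignalPWM pseudocount=%.10g n_train=%d", pwm@pseudocount,
            pwm@nTrain),
    sprintf("# background=%s",
            paste(sprintf("%s:%.10g", AA20, pwm@background[AA20]),
                  collapse = ","))), con)
  df <- data.frame(offset = pwm@offsets, pwm@cells, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSignalPWM
#' @export
readSignalPWM <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  pc <- as.numeric(sub(".*pseudocount=([0-9.eE+-]+).*", "\\1",
                       meta[grepl("pseudocount=", meta)][1]))
  nTrain <- as.integer(sub(".*n_train=([0-9]+).*", "\\1",
                           meta[grepl("n_train=", meta)][1]))
  bgLine <- meta[grepl("background=", meta)][1]
  bgPairs <- strsplit(sub("^# background=", "", bgLine), ",")[[1]]
  bg <- vapply(strsplit(bgPairs, ":"), function(x) as.numeric(x[2]),
               numeric(1))
  names(bg) <- vapply(strsplit(bgPairs, ":"), `[`, character(1), 1)
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)], sep = "\t",
                           check.names = FALSE)
  cellsM <- as.matrix(tab[, AA20])
  rownames(cellsM) <- tab$offset
  new("SignalPWM", offsets = as.integer(tab$offset), cells = cellsM,
      background = bg[AA20], pseudocount = pc, nTrain = nTrain)
}
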