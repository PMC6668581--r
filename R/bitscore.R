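#' @include AllClasses.R
NULL

#' Build a stack of aligned cleavage-site windows
#'
#' Aligns training proteins on their consensus cleavage sites: for each
#' entry, the row holds the residues at positions \code{cleavage + o} for
#' every offset o, so offset 0 is the last signal-peptide residue and
#' offset +1 the first mature residue. Entries whose sequence does not
#' cover the full offset range are skipped with a warning and counted.
#'
#' @param sequences an \code{AAStringSet}.
#' @param sites list of \linkS4class{CleavageSite} (one per entry; entries
#'   with \code{NULL} are ignored).
#' @param offsets contiguous window anchored at the cleavage site; the
#'   default \code{-10:15} spans the signal-peptide C-region and the early
#'   transit peptide.
#' @return a \linkS4class{WindowStack}.
#' @export
buildWindowStack <- function(sequences, sites, offsets = -10:15) {
  stopifnot(is(sequences, "AAStringSet"))
  offsets <- as.integer(offsets)
  sites <- Filter(Negate(is.null), sites)
  if (length(sites) == 0L)
    stop("no cleavage sites supplied")
  rows <- list()
  ids <- character(0)
  skipped <- 0L
  for (site in sites) {
    id <- site@recordId
    if (!id %in% names(sequences))
      stop("no sequence for record '", id, "'")
    s <- as.character(sequences[[id]])
    lo <- site@position + offsets[1]
    hi <- site@position + offsets[length(offsets)]
    if (lo < 1L || hi > nchar(s)) {
      skipped <- skipped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- strsplit(substr(s, lo, hi), "")[[1]]
    ids <- c(ids, id)
  }
  if (skipped > 0L)
    warning(skipped, " entr(y/ies) skipped: sequence does not cover ",
            "offsets ", offsets[1], "..", offsets[length(offsets)])
  if (length(rows) == 0L)
    stop("all entries were skipped; no window covers the offset range")
  mat <- do.call(rbind, rows)
  colnames(mat) <- offsets
  new("WindowStack", offsets = offsets, rows = mat, ids = ids)
}

#' Compute a bit-score-weighted cleavage-site matrix
#'
#' The sequence-logo weighting: at each offset o, residue frequencies are
#' \code{freq(o, a) = (count + pseudocount) / (n_eff + 20 * pseudocount)}
#' with \code{n_eff} the number of non-X residues at o; the information
#' content is \code{info(o) = log2(20) - H(o) - e(n_eff)} with
#' \code{H(o) = -sum(freq * log2(freq))} and the small-sample correction
#' \code{e(n) = 19 / (2 * ln(2) * n)} (applied when
#' \code{smallSampleCorrection} is TRUE, otherwise 0); negative corrected
#' info is clamped to 0 so the downstream cumulative scorer never rewards
#' absence of signal. Cells are \code{freq * info} — the letter heights of
#' the corresponding sequence logo.
#'
#' @param stack a \linkS4class{WindowStack}.
#' @param pseudocount smoothing pseudocount (>= 0, default 0).
#' @param smallSampleCorrection apply the entropy-bias correction
#'   (default TRUE).
#' @param speciesTag free-text tag recorded with the matrix.
#' @return a \linkS4class{BitScoreMatrix}.
#' @export
computeBitScoreMatrix <- function(stack, pseudocount = 0,
                                  smallSampleCorrection = TRUE,
                                  speciesTag = "") {
  stopifnot(is(stack, "WindowStack"), pseudocount >= 0)
  no <- length(stack@offsets)
  freqM <- matrix(0, no, 20L, dimnames = list(stack@offsets, AA20))
  info <- numeric(no)
  for (j in seq_len(no)) {
    cnt <- .residueCounts(stack@rows[, j])
    nEff <- sum(cnt)
    if (nEff == 0L)
      stop("no countable residues at offset ", stack@offsets[j],
           " (all X)")
    freq <- (cnt + pseudocount) / (nEff + 20 * pseudocount)
    h <- -sum(ifelse(freq > 0, freq * log2(freq), 0))
    e <- if (smallSampleCorrection) 19 / (2 * log(2) * nEff) else 0
    info[j] <- max(0, log2(20) - h - e)
    freqM[j, ] <- freq
  }
  cellsM <- freqM * info
  new("BitScoreMatrix", offsets = stack@offsets, freq = freqM,
      info = info, cells = cellsM, nTrain = nrow(stack@rows),
      correctionApplied = isTRUE(smallSampleCorrection),
      speciesTag = as.character(speciesTag))
}

## colours follow a fixed chemistry scheme (hydrophobic black, polar green,
## basic blue, acidic red, aromatic purple-ish handled as hydrophobic)
.residueColour <- function() {
  col <- stats::setNames(rep("black", 20), AA20)
  col[c("S", "T", "N", "Q", "G", "C", "Y")] <- "forestgreen"
  col[c("K", "R", "H")] <- "blue3"
  col[c("D", "E")] <- "red3"
  col[c("F", "W")] <- "purple3"
  col
}

#' Export a sequence logo of a bit-score matrix
#'
#' Renders one letter stack per offset: in \code{bits} mode the stack
#' height is the offset's information content and letter heights are the
#' bit-score cells (sorted ascending bottom-up); in \code{frequency} mode
#' letter heights are residue frequencies. Letters are drawn as coloured
#' tiles with centred residue labels. The cleavage boundary (between the
#' last signal-peptide residue and the first mature residue, +1) is marked
#' with a dashed vertical line. The output format follows the file
#' extension: \code{.svg} or \code{.png}.
#'
#' @param matrix a \linkS4class{BitScoreMatrix}.
#' @param mode \code{"bits"} or \code{"frequency"}.
#' @param path output path ending in \code{.svg} or \code{.png}.
#' @param minHeight letters shorter than this fraction of the y-range are
#'   drawn without a label (default 0.02).
#' @return \code{path}, invisibly.
#' @export
exportLogo <- function(matrix, mode = c("bits", "frequency"), path,
                       minHeight = 0.02) {
  stopifnot(is(matrix, "BitScoreMatrix"))
  mode <- match.arg(mode)
  ext <- tolower(tools::file_ext(path))
  dev <- switch(ext,
    svg = function() grDevices::svg(path, width = 9, height = 3.2),
    png = function() grDevices::png(path, width = 1800, height = 640,
                                    res = 200, type = "cairo"),
    stop("unsupported logo format: .", ext, " (use .svg or .png)"))
  heights <- if (mode == "bits") matrix@cells else matrix@freq
  ymax <- if (mode == "bits") max(log2(20), max(matrix@info)) else 1
  col <- .residueColour()
  dev()
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(3.2, 3.6, 1.5, 0.6), mgp = c(2.1, 0.6, 0))
  graphics::plot(NA, xlim = c(0.5, length(matrix@offsets) + 0.5),
                 ylim = c(0, ymax), xaxt = "n", xaxs = "i",
                 xlab = "offset from cleavage site",
                 ylab = if (mode == "bits") "bits" else "frequency",
                 main = if (nzchar(matrix@speciesTag)) matrix@speciesTag
                        else "")
  graphics::axis(1, at = seq_along(matrix@offsets),
                 labels = sprintf("%+d", matrix@offsets), cex.axis = 0.6,
                 las = 2)
  boundary <- which(matrix@offsets == 1L)
  if (length(boundary) == 1L)
    graphics::abline(v = boundary - 0.5, lty = 2, col = "grey40")
  for (j in seq_along(matrix@offsets)) {
    h <- heights[j, ]
    ord <- order(h)          # ascending: tallest letter ends on top
    y <- 0
    for (a in ord) {
      if (h[a] <= 0) next
      graphics::rect(j - 0.42, y, j + 0.42, y + h[a],
                     col = grDevices::adjustcolor(col[AA20[a]], 0.25),
                     border = NA)
      if (h[a] >= minHeight * ymax)
        graphics::text(j, y + h[a] / 2, AA20[a], col = col[AA20[a]],
                       cex = min(1.1, 0.3 + 3 * h[a] / ymax),
                       font = 2)
      y <- y + h[a]
    }
  }
  invisible(path)
}

#' Serialize a BitScoreMatrix to TSV
#'
#' Rows are offsets; the 20 residue columns hold the bit-score cells, with
#' extra columns \code{freq_sum} and \code{info}; a '#'-prefixed metadata
#' header records n, pseudocount, correction flag and species tag. The
#' frequency matrix is recovered on read as \code{cells / info} (uniform
#' where info is 0).
#'
#' @param matrix a \linkS4class{BitScoreMatrix}.
#' @param path file path.
#' @return \code{path} (write) or a \linkS4class{BitScoreMatrix} (read).
#' @export
writeBitScoreMatrix <- function(matrix, path) {
  stopifnot(is(matrix, "BitScoreMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# BitScoreMatrix n=%d correction=%s species_tag=%s",
    matrix@nTrain, matrix@correctionApplied, matrix@speciesTag), con)
  df <- data.frame(offset = matrix@offsets, matrix@cells,
                   freq_sum = rowSums(matrix@freq), info = matrix@info,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeBitScoreMatrix
#' @export
readBitScoreMatrix <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)[1]
  n <- as.integer(sub(".* n=([0-9]+).*", "\\1", meta))
  corr <- as.logical(sub(".*correction=(TRUE|FALSE).*", "\\1", meta))
  tag <- sub(".*species_tag=", "", meta)
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)], sep = "\t",
                           check.names = FALSE)
  cellsM <- as.matrix(tab[, AA20])
  rownames(cellsM) <- tab$offset
  info <- tab$info
  freqM <- cellsM
  for (j in seq_len(nrow(freqM)))
    freqM[j, ] <- if (info[j] > 0) cellsM[j, ] / info[j] else rep(1 / 20, 20)
  new("BitScoreMatrix", offsets = as.integer(tab$offset), freq = freqM,
      info = info, cells = cellsM, nTrain = n,
      correctionApplied = corr, speciesTag = tag)
}
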