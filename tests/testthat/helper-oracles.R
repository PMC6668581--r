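# Independent brute-force oracles. These deliberately share no code with
# the implementation: plain double loops over characters and thresholds.

AA20_TEST <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# sliding-window scan: naive double loop over matrix offsets and shifts
oracleScan <- function(seqChars, sitePos, cellsM, offs, windowLen = 5L,
                       shifts = -5:5) {
  cellOf <- function(o, ch) {
    if (!ch %in% AA20_TEST) return(0)
    cellsM[which(offs == o), ch]
  }
  cum <- 0
  for (o in offs) cum <- cum + cellOf(o, seqChars[sitePos + o])
  ws <- c()
  for (d in shifts) {
    start <- sitePos + 1L + d
    if (start < 1L || start + windowLen - 1L > length(seqChars)) next
    sc <- 0
    for (j in 0:(windowLen - 1L))
      sc <- sc + cellOf(1L + j, seqChars[start + j])
    ws[as.character(d)] <- sc
  }
  dAll <- as.integer(names(ws))
  mx <- max(ws)
  cand <- dAll[ws >= mx - 1e-12]
  cand <- cand[order(abs(cand), cand)]
  list(cumulative = cum, windowScores = ws, best = cand[1])
}

# PWM site search: exhaustive scan over every full-coverage position
oraclePwmPredict <- function(seqChars, cellsM, offs, searchRange,
                             minScore) {
  best <- -Inf
  bestPos <- NA_integer_
  for (p in searchRange) {
    if (p + offs[1] < 1L || p + offs[length(offs)] > length(seqChars))
      next
    sc <- 0
    for (o in offs) {
      ch <- seqChars[p + o]
      if (ch %in% AA20_TEST) sc <- sc + cellsM[which(offs == o), ch]
    }
    if (sc > best + 1e-12) {
      best <- sc
      bestPos <- p
    }
  }
  if (!is.finite(best) || best < minScore) return(NULL)
  list(position = bestPos, score = best)
}

# confusion tally: one explicit pass per entry
oracleConfusion <- function(scores, truth, positiveClass, threshold) {
  tp <- fp <- fn <- tn <- 0L
  for (id in names(scores)) {
    pos <- truth[[id]] == positiveClass
    pass <- scores[[id]] >= threshold
    if (pos && pass) tp <- tp + 1L
    else if (pos) fn <- fn + 1L
    else if (pass) fp <- fp + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# per-column entropy/information, scripted independently of the package
oracleColumnInfo <- function(column, pseudocount = 0, correction = FALSE) {
  keep <- column[column %in% AA20_TEST]
  n <- length(keep)
  cnt <- sapply(AA20_TEST, function(a) sum(keep == a))
  freq <- (cnt + pseudocount) / (n + 20 * pseudocount)
  h <- 0
  for (f in freq) if (f > 0) h <- h - f * log2(f)
  e <- if (correction) 19 / (2 * log(2) * n) else 0
  list(freq = freq, info = max(0, log2(20) - h - e))
}

# log-odds PWM cell table by direct counting
oraclePwmCells <- function(windows, offs, pseudocount, background) {
  m <- matrix(NA_real_, length(offs), 20,
              dimnames = list(offs, AA20_TEST))
  for (j in seq_along(offs)) {
    col <- sapply(windows, function(w) w[j])
    keep <- col[col %in% AA20_TEST]
    n <- length(keep)
    for (a in AA20_TEST) {
      f <- (sum(keep == a) + pseudocount) / (n + 20 * pseudocount)
      m[j, a] <- log2(f / background[[a]])
    }
  }
  m
}

# -- fixture builders -------------------------------------------------

randomProtein <- function(len) {
  paste(sample(AA20_TEST, len, replace = TRUE), collapse = "")
}

aaSet <- function(seqs) {
  x <- Biostrings::AAStringSet(seqs)
  S4Vectors::mcols(x) <- S4Vectors::DataFrame(
    description = rep("", length(x)), chimeric = rep(FALSE, length(x)),
    source = rep("test", length(x)))
  x
}

# reference set embedding 16-residue training windows so that the
# offset-0 column (offsets -13..2) lands at cleavage position 32
refSetFromWindows <- function(windows, flank = 18L) {
  seqs <- vapply(windows, function(w)
    paste0(strrep("G", flank), paste(w, collapse = ""),
           strrep("G", flank)), character(1))
  names(seqs) <- sprintf("w%02d", seq_along(windows))
  referenceSet(aaSet(seqs), id = names(seqs), label = "plastid",
               knownCleavage = flank + 14L)
}

# random but valid BitScoreMatrix via a random window stack
randomBitScoreMatrix <- function(offs = -3:6, n = 25L) {
  rows <- matrix(sample(AA20_TEST, n * length(offs), replace = TRUE),
                 nrow = n)
  colnames(rows) <- offs
  stack <- new("WindowStack", offsets = as.integer(offs), rows = rows,
               ids = sprintf("r%02d", seq_len(n)))
  computeBitScoreMatrix(stack, smallSampleCorrection = FALSE)
}
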