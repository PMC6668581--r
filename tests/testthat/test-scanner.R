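zeroMatrix <- function(offs = -3:6) {
  n <- length(offs)
  new("BitScoreMatrix", offsets = as.integer(offs),
      freq = matrix(1 / 20, n, 20, dimnames = list(offs, AA20_TEST)),
      info = rep(0, n),
      cells = matrix(0, n, 20, dimnames = list(offs, AA20_TEST)),
      nTrain = 2L, correctionApplied = FALSE, speciesTag = "")
}

pheMatrix <- function(offs = -3:6, height = 2, height2 = 0) {
  # invariant-F columns at +1 (and optionally +2) with chosen info
  freq <- matrix(1 / 20, length(offs), 20,
                 dimnames = list(offs, AA20_TEST))
  inf <- rep(0, length(offs))
  cellsM <- matrix(0, length(offs), 20, dimnames = list(offs, AA20_TEST))
  freq["1", ] <- 0
  freq["1", "F"] <- 1
  inf[which(offs == 1L)] <- height
  cellsM["1", "F"] <- height
  if (height2 > 0) {
    freq["2", ] <- 0
    freq["2", "F"] <- 1
    inf[which(offs == 2L)] <- height2
    cellsM["2", "F"] <- height2
  }
  new("BitScoreMatrix", offsets = as.integer(offs), freq = freq,
      info = inf, cells = cellsM, nTrain = 2L,
      correctionApplied = FALSE, speciesTag = "")
}

test_that("window scans honour tie-breaks and single contributions", {
  rec <- aaSet(c(r = randomProtein(60)))
  site <- cleavageSite("r", 25L, "consensus", 4)
  res <- scanWindows(rec, site, zeroMatrix())
  expect_equal(res@cumulativeScore, 0)
  expect_true(all(res@windowScores == 0))
  expect_identical(res@bestWindowOffset, 0L)   # ties resolve to |d| = 0
  expect_true(res@agrees)
  # single positive cell at (+1, F) and F only at site + 1
  chars <- rep("A", 60)
  chars[26] <- "F"
  rec <- aaSet(c(r = paste(chars, collapse = "")))
  res <- scanWindows(rec, site, pheMatrix(height = 2))
  expect_identical(res@bestWindowOffset, 0L)
  expect_equal(res@cumulativeScore, 2)
  expect_equal(unname(res@windowScores[["0"]]), 2)
  expect_true(res@agrees)
  # the same Phe four residues downstream breaks agreement
  chars[26] <- "A"
  chars[30] <- "F"
  rec <- aaSet(c(r = paste(chars, collapse = "")))
  res <- scanWindows(rec, site, pheMatrix(height = 2))
  expect_identical(res@bestWindowOffset, 4L)
  expect_false(res@agrees)
})

test_that("window scans refuse sites hanging over a terminus", {
  rec <- aaSet(c(r = randomProtein(30)))
  expect_error(scanWindows(rec, cleavageSite("r", 2L, "x", 1),
                           zeroMatrix(-3:6)), "terminus")
  expect_error(scanWindows(rec, cleavageSite("r", 28L, "x", 1),
                           zeroMatrix(-3:6)), "terminus")
})

test_that("window scans equal the brute-force double loop", {
  set.seed(37)
  for (i in 1:40) {
    offs <- -sample(2:6, 1):sample(5:9, 1)
    bsm <- randomBitScoreMatrix(offs = offs, n = sample(4:30, 1))
    len <- sample(40:90, 1)
    seqChars <- sample(AA20_TEST, len, replace = TRUE)
    pos <- sample((1 - offs[1]):(len - offs[length(offs)] - 1), 1)
    rec <- aaSet(setNames(paste(seqChars, collapse = ""), "r"))
    site <- cleavageSite("r", pos, "consensus", 1)
    got <- scanWindows(rec, site, bsm, windowLen = 5L)
    want <- oracleScan(seqChars, pos, cells(bsm), offs, windowLen = 5L)
    expect_equal(got@cumulativeScore, want$cumulative, tolerance = 1e-9)
    expect_equal(got@windowScores, want$windowScores, tolerance = 1e-9)
    expect_identical(got@bestWindowOffset, want$best)
  }
})

test_that("the classification cascade orders its evidence correctly", {
  # cumulative score 6 (the top of the scanner's usual range) from two
  # invariant Phe columns: 4 bits at +1 plus 2 bits at +2
  bsm <- pheMatrix(height = 4, height2 = 2)
  chars <- rep("A", 80)
  chars[26:27] <- "F"
  rec <- aaSet(c(r = paste(chars, collapse = "")))
  site <- cleavageSite("r", 25L, "consensus", 4)
  # no site, no mito score: other
  res <- classifyProtein(rec, NULL, bsm)
  expect_identical(res@call, "other")
  # no site but convincing external mito score: mitochondrion
  res <- classifyProtein(rec, NULL, bsm, mitoScore = 0.9,
                         mitoThreshold = 0.5)
  expect_identical(res@call, "mitochondrion")
  # site + cumulative score 6 over threshold 1.4: plastid
  res <- classifyProtein(rec, site, bsm,
                         plastidThreshold = thresholdPreset("cvelia"))
  expect_identical(res@call, "plastid")
  expect_equal(res@score, 6)
  # site but score below threshold: secretory
  res <- classifyProtein(rec, site, bsm, plastidThreshold = 100)
  expect_identical(res@call, "secretory")
  # scan failure degrades to "other" with a warning, never an error
  edge <- cleavageSite("r", 2L, "consensus", 4)
  expect_warning(res <- classifyProtein(rec, edge, bsm), "scan failed")
  expect_identical(res@call, "other")
})

test_that("raising the plastid threshold never creates plastid calls", {
  set.seed(41)
  fx <- generateFixture(fixtureSpec(nPerClass = 30L, seed = 41L))
  rs <- fixtureReferenceSet(fx)
  pwm <- trainSignalPWM(filterReferenceSet(rs, label = c("plastid",
                                                         "secretory"),
                                           withCleavage = TRUE))
  pla <- filterReferenceSet(rs, label = "plastid", withCleavage = TRUE)
  info <- refInfo(pla)
  sites <- lapply(seq_len(nrow(info)), function(i)
    cleavageSite(info$id[i], info$knownCleavage[i], "consensus", 4))
  bsm <- computeBitScoreMatrix(buildWindowStack(refSequences(pla), sites))
  seqs <- fx$sequences[seq(1, length(fx$sequences), by = 4)]  # plastids
  lo <- predictLocalization(seqs, pwm, bsm, plastidThreshold = 1)
  hi <- predictLocalization(seqs, pwm, bsm, plastidThreshold = 3)
  expect_true(all(hi$call[lo$call != "plastid"] != "plastid"))
  expect_lte(sum(hi$call == "plastid"), sum(lo$call == "plastid"))
})

test_that("species presets carry the calibrated default thresholds", {
  expect_equal(thresholdPreset("cvelia"), 1.4)
  expect_equal(thresholdPreset("vbrassicaformis"), 1.0)
})
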