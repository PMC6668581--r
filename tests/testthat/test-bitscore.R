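stackFromRows <- function(rows, offs) {
  m <- do.call(rbind, rows)
  colnames(m) <- offs
  new("WindowStack", offsets = as.integer(offs), rows = m,
      ids = sprintf("s%02d", seq_along(rows)))
}

test_that("window stacks map offset +1 to the first post-cleavage residue", {
  # 5 hand-built entries: cleavage at 20, offsets -2..+2 pick residues
  # 18..22, so +1 is residue 21
  seqs <- c("CDEFG", "HIKLM", "NPQRS", "TVWYA", "FFFFF")
  full <- vapply(seqs, function(s)
    paste0(strrep("G", 17), s, strrep("G", 10)), character(1))
  names(full) <- sprintf("e%d", 1:5)
  sites <- lapply(names(full), function(id)
    cleavageSite(id, 20L, "consensus", 4))
  stack <- buildWindowStack(aaSet(full), sites, offsets = -2:2)
  expect_identical(unname(stack@rows[1, ]), strsplit("CDEFG", "")[[1]])
  expect_identical(unname(stack@rows[, "1"]),
                   c("F", "L", "R", "Y", "F"))
  expect_identical(trainingCount(stack), 5L)
})

test_that("window stacks skip entries that cannot cover the offsets", {
  seqs <- c(a = randomProtein(40), b = randomProtein(21),
            c = randomProtein(40))
  sites <- lapply(names(seqs), function(id)
    cleavageSite(id, 20L, "consensus", 3))
  expect_warning(stack <- buildWindowStack(aaSet(seqs), sites,
                                           offsets = -2:2),
                 "skipped")  # b has no +2 residue
  expect_identical(stack@ids, c("a", "c"))
  shortOnly <- lapply(c("b"), function(id) cleavageSite(id, 20L, "x", 1))
  expect_error(suppressWarnings(
    buildWindowStack(aaSet(seqs), shortOnly, offsets = -2:2)),
    "skipped")
})

test_that("information content hits its entropy extremes", {
  # uniform column: 0 bits; invariant column: log2(20) bits
  uniformRows <- lapply(AA20_TEST, function(a) c(a, "A"))
  stack <- stackFromRows(uniformRows, 0:1)
  bsm <- computeBitScoreMatrix(stack, smallSampleCorrection = FALSE)
  expect_equal(unname(infoContent(bsm)[["0"]]), 0)
  expect_equal(max(abs(cells(bsm)[1, ])), 0)
  expect_equal(unname(infoContent(bsm)[["1"]]), log2(20))
  expect_equal(unname(cells(bsm)["1", "A"]), log2(20))
  expect_equal(sum(cells(bsm)["1", colnames(cells(bsm)) != "A"]), 0)
})

test_that("bit scores agree with an independent entropy script", {
  set.seed(17)
  rows <- lapply(1:4, function(i) sample(AA20_TEST, 8, replace = TRUE))
  stack <- stackFromRows(rows, -3:4)
  for (corr in c(TRUE, FALSE)) {
    bsm <- computeBitScoreMatrix(stack, pseudocount = 0,
                                 smallSampleCorrection = corr)
    for (j in 1:8) {
      want <- oracleColumnInfo(stack@rows[, j], 0, corr)
      expect_equal(unname(infoContent(bsm)[[j]]), want$info,
                   tolerance = 1e-12)
      expect_equal(unname(freqMatrix(bsm)[j, ]), unname(want$freq),
                   tolerance = 1e-12)
      expect_equal(unname(cells(bsm)[j, ]),
                   unname(want$freq * want$info), tolerance = 1e-12)
    }
  }
})

test_that("cells conserve the column information at machine precision", {
  set.seed(23)
  for (i in 1:10) {
    bsm <- randomBitScoreMatrix(offs = -4:8, n = sample(5:40, 1))
    expect_lt(max(abs(rowSums(cells(bsm)) - unname(infoContent(bsm)))),
              1e-9)
    expect_true(all(cells(bsm) >= 0))
    expect_true(all(infoContent(bsm) <= log2(20) + 1e-12))
  }
})

test_that("two-residue columns match the closed-form information", {
  for (p in seq(0.05, 0.95, by = 0.05)) {
    n <- 100L
    k <- round(p * n)
    rows <- lapply(seq_len(n), function(i)
      c(if (i <= k) "F" else "L", "A"))
    stack <- stackFromRows(rows, 1:2)
    bsm <- computeBitScoreMatrix(stack, smallSampleCorrection = FALSE)
    q <- k / n
    want <- log2(20) + q * log2(q) + (1 - q) * log2(1 - q)
    expect_equal(unname(infoContent(bsm)[["1"]]), want, tolerance = 1e-12)
  }
})

test_that("reinforcing a dominant residue never loses information", {
  set.seed(29)
  for (i in 1:10) {
    rows <- lapply(1:15, function(j) sample(AA20_TEST, 3, replace = TRUE))
    stack <- stackFromRows(rows, 0:2)
    cnt <- table(factor(stack@rows[, 1], levels = AA20_TEST))
    dominant <- names(which.max(cnt))
    before <- infoContent(computeBitScoreMatrix(
      stack, smallSampleCorrection = FALSE))[["0"]]
    # duplicate rows carrying the dominant residue at offset 0
    extra <- rows[vapply(rows, function(r) r[1] == dominant, logical(1))]
    stack2 <- stackFromRows(c(rows, extra, extra), 0:2)
    after <- infoContent(computeBitScoreMatrix(
      stack2, smallSampleCorrection = FALSE))[["0"]]
    expect_gte(after, before - 1e-12)
  }
})

test_that("X residues are excluded per column, not per row", {
  rows <- list(c("F", "X"), c("F", "A"), c("X", "A"), c("F", "A"))
  stack <- stackFromRows(rows, 1:2)
  bsm <- computeBitScoreMatrix(stack, smallSampleCorrection = FALSE)
  # column 1: three F's among 3 countable -> invariant
  expect_equal(unname(infoContent(bsm)[["1"]]), log2(20))
  # an all-X column is a hard error naming the offset
  rows <- list(c("X", "A"), c("X", "A"))
  expect_error(computeBitScoreMatrix(stackFromRows(rows, 5:6),
                                     smallSampleCorrection = FALSE),
               "offset 5")
})

test_that("bit-score matrices survive a TSV round trip", {
  set.seed(31)
  bsm <- randomBitScoreMatrix(offs = -10:15, n = 30L)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeBitScoreMatrix(bsm, tsv)
  back <- readBitScoreMatrix(tsv)
  expect_equal(cells(back), cells(bsm), tolerance = 1e-9)
  expect_equal(unname(infoContent(back)), unname(infoContent(bsm)),
               tolerance = 1e-9)
  expect_identical(offsets(back), offsets(bsm))
  expect_identical(trainingCount(back), 30L)
})

test_that("logos render to SVG/PNG with the tallest +1 letter being Phe", {
  fx <- generateFixture(fixtureSpec(nPerClass = 60L, seed = 19L,
                                    speciesProfile = "cvelia_like"))
  rs <- filterReferenceSet(fixtureReferenceSet(fx), label = "plastid",
                           withCleavage = TRUE)
  info <- refInfo(rs)
  sites <- lapply(seq_len(nrow(info)), function(i)
    cleavageSite(info$id[i], info$knownCleavage[i], "consensus", 4))
  stack <- buildWindowStack(refSequences(rs), sites)
  bsm <- computeBitScoreMatrix(stack, speciesTag = "cvelia_like")
  expect_identical(names(which.max(cells(bsm)["1", ])), "F")
  svgPath <- withr::local_tempfile(fileext = ".svg")
  exportLogo(bsm, "bits", svgPath)
  expect_gt(file.size(svgPath), 1000)
  # an all-zero matrix still renders the axes
  zero <- computeBitScoreMatrix(
    stackFromRows(lapply(AA20_TEST, function(a) c(a, a)), 1:2),
    smallSampleCorrection = FALSE)
  expect_equal(max(abs(cells(zero))), 0)
  svg2 <- withr::local_tempfile(fileext = ".svg")
  exportLogo(zero, "bits", svg2)
  expect_gt(file.size(svg2), 500)
})
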