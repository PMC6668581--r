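cc <- function(tp, fp, fn, tn, thr = 1) {
  new("ConfusionCounts", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tn = as.integer(tn),
      positiveClass = "plastid", threshold = thr)
}

test_that("sensitivity and precision follow their defining ratios", {
  expect_equal(sensitivity(cc(3, 0, 1, 0)), 0.75)
  expect_equal(precision(cc(3, 1, 0, 0)), 0.75)
  expect_equal(sensitivity(cc(0, 0, 5, 0)), 0)
  expect_equal(precision(cc(5, 0, 0, 0)), 1)
  # undefined ratios surface as markers, never numbers
  expect_true(is.na(sensitivity(cc(0, 3, 0, 7))))
  expect_true(is.na(precision(cc(0, 0, 3, 7))))
})

test_that("confusion counting is inclusive at the threshold", {
  scores <- c(a = 2, b = 2, c = 2, d = 0.5)
  truth <- c(a = "plastid", b = "plastid", c = "plastid", d = "plastid")
  k <- confusionCounts(scores, truth, "plastid", 1)
  expect_identical(c(k@tp, k@fn), c(3L, 1L))
  # exactly-at-threshold scores count as passing
  k <- confusionCounts(scores, truth, "plastid", 2)
  expect_identical(k@tp, 3L)
  # empty maps give zero counts, not an error
  k <- confusionCounts(setNames(numeric(0), character(0)),
                       setNames(character(0), character(0)),
                       "plastid", 1)
  expect_identical(k@tp + k@fp + k@fn + k@tn, 0L)
  # id mismatches are reported with the symmetric difference
  expect_error(confusionCounts(c(a = 1), c(b = "plastid"), "plastid", 1),
               "only in scores.*a.*only in truth.*b")
})

test_that("confusion counting matches an independent tally", {
  set.seed(43)
  for (i in 1:30) {
    n <- 50L
    ids <- sprintf("q%02d", 1:n)
    scores <- setNames(round(runif(n, 0, 5), 2), ids)
    truth <- setNames(sample(c("plastid", "cytosol", "secretory"), n,
                             replace = TRUE), ids)
    thr <- runif(1, 0, 5)
    k <- confusionCounts(scores, truth, "plastid", thr)
    want <- oracleConfusion(scores, truth, "plastid", thr)
    expect_identical(c(k@tp, k@fp, k@fn, k@tn), unname(want))
    expect_identical(k@tp + k@fp + k@fn + k@tn, n)
  }
})

test_that("threshold sweeps trace the full curve and keep undefined points", {
  # perfectly separated scores reach a point with sens = prec = 1
  scores <- c(p1 = 5, p2 = 6, n1 = 1, n2 = 0)
  truth <- c(p1 = "plastid", p2 = "plastid", n1 = "cytosol",
             n2 = "cytosol")
  curve <- sweepThresholds(scores, truth, "plastid")
  pts <- curve@points
  expect_true(any(pts$sensitivity == 1 & !is.na(pts$precision) &
                  pts$precision == 1))
  # all-positive truth: precision 1 wherever defined
  truth2 <- setNames(rep("plastid", 4), names(scores))
  pts2 <- sweepThresholds(scores, truth2, "plastid")@points
  expect_true(all(pts2$precision[!is.na(pts2$precision)] == 1))
  # sensitivity weakly decreasing along the sweep
  expect_true(all(diff(pts$sensitivity) <= 1e-12))
})

test_that("sweeps agree pointwise with per-threshold brute force", {
  set.seed(47)
  n <- 50L
  ids <- sprintf("r%02d", 1:n)
  scores <- setNames(sample(seq(0, 3, by = 0.25), n, replace = TRUE), ids)
  truth <- setNames(sample(c("plastid", "cytosol"), n, replace = TRUE),
                    ids)
  curve <- sweepThresholds(scores, truth, "plastid")
  for (i in seq_len(nrow(curve@points))) {
    row <- curve@points[i, ]
    want <- oracleConfusion(scores, truth, "plastid", row$threshold)
    expect_identical(c(row$tp, row$fp, row$fn, row$tn), unname(want))
    sens <- if (want[["tp"]] + want[["fn"]] > 0)
      want[["tp"]] / (want[["tp"]] + want[["fn"]]) else NA_real_
    expect_equal(row$sensitivity, sens)
  }
})

test_that("threshold selection maximizes the free metric at each floor", {
  # constructed curve: 1.4 is the largest threshold with sens >= 0.75
  scores <- c(setNames(c(1.4, 1.5, 1.6, 1.8, 2.0, 0.9), sprintf("p%d", 1:6)),
              setNames(c(0.5, 0.6, 1.0, 1.2), sprintf("n%d", 1:4)))
  truth <- setNames(c(rep("plastid", 6), rep("cytosol", 4)),
                    names(scores))
  curve <- sweepThresholds(scores, truth, "plastid")
  sel <- selectThreshold(curve, "sensitivity_level", 0.75)
  expect_equal(sel$threshold, 1.4)
  expect_equal(sel$sensitivity, 5 / 6)
  expect_true(sel$attained)
  # linear-scan oracle over the same curve
  pts <- curve@points
  wantThr <- max(pts$threshold[pts$sensitivity >= 0.75])
  expect_equal(sel$threshold, wantThr)
  # precision mode: smallest threshold reaching the precision floor
  sel <- selectThreshold(curve, "precision_level", 0.85)
  ok <- which(!is.na(pts$precision) & pts$precision >= 0.85)
  expect_equal(sel$threshold, pts$threshold[min(ok)])
  # unattainable level: closest point, flagged; selection stays on curve
  lowPrec <- sweepThresholds(
    c(a = 2, b = 1, c = 3, d = 2.5, e = 1.5),
    c(a = "plastid", b = "plastid", c = "cytosol", d = "cytosol",
      e = "cytosol"), "plastid")
  expect_lt(max(lowPrec@points$precision, na.rm = TRUE), 0.85)
  sel <- selectThreshold(lowPrec, "precision_level", 0.85)
  expect_false(sel$attained)
  expect_true(sel$threshold %in% lowPrec@points$threshold)
  # single-point curve returns that point in both modes
  one <- suppressWarnings(sweepThresholds(c(a = 1, b = 1),
                                          c(a = "plastid", b = "cytosol"),
                                          "plastid"))
  expect_equal(selectThreshold(one, "sensitivity_level", 0.75)$threshold, 1)
  expect_equal(selectThreshold(one, "precision_level", 0.85)$threshold, 1)
})

test_that("predictor comparison reports both operating points per tool", {
  ids <- sprintf("x%02d", 1:40)
  truth <- setNames(rep(c("plastid", "cytosol"), each = 20), ids)
  perfect <- setNames(c(rep(2, 20), rep(0, 20)), ids)
  # dominated predictor: same ranking but positives shifted down
  set.seed(53)
  noisy <- setNames(runif(40, 0, 2), ids)
  rep <- comparePredictors(list(perfect = perfect, noisy = noisy), truth,
                           "plastid")
  prow <- rep[rep$predictor == "perfect", ]
  expect_equal(prow$sensitivity_s, 1)
  expect_equal(prow$precision_s, 1)
  expect_equal(prow$threshold_s, prow$threshold_p)
  nrow_ <- rep[rep$predictor == "noisy", ]
  expect_lte(nrow_$precision_s, prow$precision_s)
  expect_lte(nrow_$sensitivity_p, prow$sensitivity_p)
})
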