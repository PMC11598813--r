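test_that("per-class counts decompose the published matrix correctly", {
  cm <- published_confusion()
  ct <- per_class_counts(cm, "N")
  expect_equal(unname(ct), c(12718, 3682, 232, 283))  # TP TN FP FN
  expect_equal(sum(ct), sum(cm))
  # identity matrix: no confusions
  ident <- diag(5L)
  dimnames(ident) <- dimnames(cm)
  for (cls in beat_classes()) {
    ct <- per_class_counts(ident, cls)
    expect_equal(unname(ct[c("FP", "FN")]), c(0, 0))
  }
  # conservation holds for arbitrary matrices
  set.seed(14)
  for (rep in 1:20) {
    m <- matrix(rpois(25, 40), 5, 5, dimnames = dimnames(cm))
    for (cls in beat_classes()) {
      expect_equal(sum(per_class_counts(m, cls)), sum(m))
    }
  }
})

test_that("the published metric block is reproduced exactly", {
  r <- metric_report(published_confusion())
  expect_equal(r$accuracy_pct, 96.61)
  expect_equal(r$macro_f1_pct, 89.08)
  want <- data.frame(
    class = c("N", "S", "V", "F", "Q"),
    Sen  = c(97.82, 80.45, 95.40, 79.62, 95.46),
    Ppv  = c(98.21, 77.14, 90.56, 77.64, 98.78),
    Spec = c(94.07, 99.15, 99.05, 99.79, 99.87),
    Acc2 = c(96.96, 98.50, 98.73, 99.60, 99.43))
  expect_equal(r$table[, names(want)], want)
  expect_equal(r$table$F1[1], 98.02)
  # the binary (V vs non-V) F1 at one-decimal precision
  expect_equal(round(r$table$F1[3], 1), 92.9)
})

test_that("a fully symmetric two-class toy gives 50% everywhere defined", {
  cm <- matrix(0L, 5, 5, dimnames = list(predicted = beat_classes(),
                                         original = beat_classes()))
  cm["N", "N"] <- 1L; cm["S", "S"] <- 1L
  cm["N", "S"] <- 1L; cm["S", "N"] <- 1L
  r <- suppressWarnings(metric_report(cm))
  expect_equal(r$per_class$F1[1], 0.5)
  expect_equal(r$per_class$F1[2], 0.5)
  expect_equal(r$per_class$Acc2[1], 0.5)
  expect_equal(r$accuracy, 0.5)
})

test_that("class permutations leave the overall metrics unchanged", {
  cm <- published_confusion()
  set.seed(2)
  for (rep in 1:5) {
    perm <- sample(5)
    pm <- cm[perm, perm]
    r <- metric_report(pm)
    expect_equal(r$accuracy, metric_report(cm)$accuracy)
    expect_equal(r$macro_f1, metric_report(cm)$macro_f1)
    expect_equal(r$per_class$F1, metric_report(cm)$per_class$F1[perm])
  }
})

test_that("matrix-aggregated metrics agree with per-sample counting", {
  set.seed(6)
  for (rep in 1:30) {
    n <- 200
    truth <- sample(beat_classes(), n, replace = TRUE)
    pred <- ifelse(runif(n) < 0.7, truth,
                   sample(beat_classes(), n, replace = TRUE))
    r <- suppressWarnings(metric_report(confusion_matrix5(pred, truth)))
    expect_equal(r$accuracy, mean(pred == truth))
    for (k in seq_along(beat_classes())) {
      cls <- beat_classes()[k]
      tp <- sum(pred == cls & truth == cls)
      fp <- sum(pred == cls & truth != cls)
      fn <- sum(pred != cls & truth == cls)
      sen <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
      f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn)
            else NA_real_
      expect_equal(r$per_class$Sen[k], sen)
      expect_equal(r$per_class$F1[k], f1)
    }
  }
})

test_that("degenerate denominators warn and report NA, not zero", {
  cm <- matrix(0L, 5, 5, dimnames = list(predicted = beat_classes(),
                                         original = beat_classes()))
  cm["N", "N"] <- 10L
  warns <- testthat::capture_warnings(r <- metric_report(cm))
  expect_true(any(grepl("undefined", warns)))
  expect_true(is.na(r$per_class$Ppv[2]))
  expect_equal(r$accuracy, 1)
  expect_error(metric_report(cm * 0L), "empty")
  expect_error(confusion_matrix5(c("N", "X"), c("N", "N")), "labels")
  expect_error(confusion_matrix5("N", c("N", "S")), "lengths")
})

test_that("all defined rates stay inside the unit interval", {
  set.seed(10)
  for (rep in 1:20) {
    m <- matrix(rpois(25, 15), 5, 5,
                dimnames = list(predicted = beat_classes(),
                                original = beat_classes()))
    r <- metric_report(m)
    vals <- unlist(r$per_class[, -1])
    expect_true(all(vals[!is.na(vals)] >= 0 & vals[!is.na(vals)] <= 1))
  }
})
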