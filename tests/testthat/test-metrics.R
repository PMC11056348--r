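# Classification metrics: confusion matrix conventions, the
# precision/recall/F1 arithmetic, aggregation, and agreement with an
# independent reference implementation.

test_that("confusion matrix follows the truth-rows / prediction-columns convention", {
  classes <- c("a", "b", "c")
  truth <- c("a", "a", "b", "c", "c", "c")
  pred  <- c("a", "b", "b", "c", "a", "c")
  cm <- confusion_matrix(truth, pred, classes)
  expect_equal(unname(rowSums(cm)), c(2, 1, 3))         # supports
  expect_equal(sum(cm), 6)
  expect_equal(cm["a", "b"], 1L)
  expect_equal(cm["c", "a"], 1L)
  # perfect predictions give a diagonal matrix
  cmp <- confusion_matrix(truth, truth, classes)
  expect_true(all(cmp[upper.tri(cmp) | lower.tri(cmp)] == 0))
  expect_equal(unname(diag(cmp)), c(2, 1, 3))
  expect_error(confusion_matrix(c("a", "z"), c("a", "a"), classes), "z")
})

test_that("swapping two predicted labels moves exactly two counts (or none)", {
  # exhaustive check: a swap relocates two counts iff the two records
  # disagree in both truth and prediction; otherwise the matrix is invariant
  classes <- c("a", "b", "c")
  set.seed(20)
  truth <- sample(classes, 8, replace = TRUE)
  pred <- sample(classes, 8, replace = TRUE)
  cm1 <- confusion_matrix(truth, pred, classes)
  for (i in 1:7) {
    for (j in (i + 1):8) {
      pred2 <- pred
      pred2[c(i, j)] <- pred[c(j, i)]
      moved <- sum(abs(cm1 - confusion_matrix(truth, pred2, classes))) / 2
      expected <- if (pred[i] != pred[j] && truth[i] != truth[j]) 2 else 0
      expect_equal(moved, expected, info = sprintf("swap %d,%d", i, j))
    }
  }
})

test_that("accuracy is 100 * trace / total with sane extremes", {
  cm <- diag(c(5L, 7L, 9L))
  expect_equal(accuracy(cm), 100)
  off <- matrix(1L, 3, 3) - diag(1L, 3)
  expect_equal(accuracy(off), 0)
  expect_error(accuracy(matrix(0L, 2, 2)), "no observations")
})

test_that("degenerate denominators yield flagged zeros", {
  # class "b" never predicted, class "c" has no true members
  cm <- matrix(c(3L, 0L, 0L,
                 2L, 0L, 1L,
                 0L, 0L, 0L), 3, 3, byrow = TRUE,
               dimnames = list(truth = c("a", "b", "c"),
                               predicted = c("a", "b", "c")))
  pr <- precision_recall(cm)
  expect_equal(pr$precision[2], 0)
  expect_true(pr$degenerate_precision[2])
  expect_false(pr$degenerate_recall[2])
  expect_gt(pr$recall[1], 0)
  expect_true(pr$degenerate_recall[3])
  expect_equal(f1_score(0, 0), 0)
})

test_that("F1 is the harmonic mean with its fixed point", {
  expect_equal(f1_score(50, 50), 50)
  x <- c(10, 85.3, 99)
  expect_equal(f1_score(x, x), x)
  expect_equal(f1_score(60, 30), 2 * 60 * 30 / 90)
})

test_that("macro and weighted aggregates coincide under equal supports", {
  set.seed(14)
  pc <- data.frame(class = letters[1:4],
                   precision = runif(4, 50, 100),
                   recall = runif(4, 50, 100),
                   support = rep(25L, 4))
  rep_ <- aggregate_report(pc)
  expect_equal(rep_$macro, rep_$weighted)
  # unequal supports weight the larger class more
  pc$support <- c(10L, 10L, 10L, 70L)
  rep2 <- aggregate_report(pc)
  expect_equal(unname(rep2$weighted["precision"]),
               sum(pc$support * pc$precision) / 100)
})

test_that("micro-averaged recall equals overall accuracy for any matrix", {
  set.seed(15)
  for (rep in 1:10) {
    C <- sample(2:6, 1)
    cm <- matrix(rpois(C * C, 5), C, C,
                 dimnames = list(truth = letters[1:C],
                                 predicted = letters[1:C]))
    if (sum(cm) == 0) next
    micro_re <- 100 * sum(diag(cm)) / sum(cm)
    expect_equal(accuracy(cm), micro_re)
  }
})

test_that("report agrees with the caret reference on random label vectors", {
  skip_if_not_installed("caret")
  set.seed(16)
  classes <- c("w", "x", "y", "z")
  for (rep in 1:100) {
    n <- 60L
    truth <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    cm <- confusion_matrix(truth, pred, classes)
    ours <- precision_recall(cm)
    ours$f1 <- f1_score(ours$precision, ours$recall)
    ref <- caret::confusionMatrix(factor(pred, classes), factor(truth, classes))
    by_class <- ref$byClass
    for (ci in seq_along(classes)) {
      ref_pr <- 100 * by_class[ci, "Precision"]
      ref_re <- 100 * by_class[ci, "Recall"]
      ref_f1 <- 100 * by_class[ci, "F1"]
      if (!is.na(ref_pr)) {
        expect_equal(ours$precision[ci], unname(ref_pr), tolerance = 1e-10)
      }
      if (!is.na(ref_re)) {
        expect_equal(ours$recall[ci], unname(ref_re), tolerance = 1e-10)
      }
      if (!is.na(ref_f1)) {
        expect_equal(ours$f1[ci], unname(ref_f1), tolerance = 1e-10)
      }
    }
    expect_equal(accuracy(cm), unname(100 * ref$overall["Accuracy"]),
                 tolerance = 1e-10)
  }
})

test_that("reports serialize to JSON and CSV", {
  cm <- confusion_matrix(c("a", "b", "b"), c("a", "b", "a"), c("a", "b"))
  rep_ <- classification_report(cm)
  jp <- tempfile(fileext = ".json")
  cp <- tempfile(fileext = ".csv")
  write_report(rep_, jp)
  write_report(rep_, cp)
  back <- jsonlite::read_json(jp)
  expect_equal(back$accuracy, rep_$accuracy)
  expect_equal(nrow(utils::read.csv(cp)), 2 + 3)
  mp <- tempfile(fileext = ".csv")
  write_confusion_csv(cm, mp)
  expect_equal(utils::read.csv(mp)$a, c(1L, 1L))
})
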