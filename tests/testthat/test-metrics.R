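test_that("confusion counts satisfy the defining identities", {
  m <- random_mask(8, 2, 1)
  expect_equal(unname(confusion_counts(m, m, 1)[c("FP", "FN")]), c(0L, 0L))
  comp <- 1L - m
  cc <- confusion_counts(comp, m, 1)
  expect_equal(unname(cc[c("TP", "TN")]), c(0L, 0L))
  expect_equal(sum(cc), 64L)
  expect_error(confusion_counts(m, random_mask(9, 2, 1), 1), "shape")
})

test_that("counts and scores match an exhaustive pixel-by-pixel tally", {
  for (seed in 1:25) {
    pred <- random_mask(8, 4, seed)
    truth <- random_mask(8, 4, seed + 1000)
    for (cl in 0:3) {
      fast <- confusion_counts(pred, truth, cl)
      slow <- oracle_confusion(pred, truth, cl)
      expect_identical(fast, slow)
      sc <- seg_scores(fast)
      expect_equal(sc[["accuracy"]], (slow[["TP"]] + slow[["TN"]]) / 64)
      # Dice/Jaccard identity
      expect_equal(sc[["dice"]], 2 * sc[["jaccard"]] / (1 + sc[["jaccard"]]))
      expect_lte(sc[["jaccard"]], sc[["dice"]])
      expect_lte(sc[["dice"]], 1)
    }
  }
})

test_that("hand-computable count sets give the textbook values", {
  expect_equal(seg_scores(c(TP = 50, FP = 25, FN = 25, TN = 0)),
               c(accuracy = 0.5, jaccard = 0.5, dice = 2 / 3))
  expect_equal(seg_scores(c(TP = 10, FP = 0, FN = 0, TN = 90)),
               c(accuracy = 1, jaccard = 1, dice = 1))
  # class absent from both masks: perfect agreement on absence
  expect_equal(seg_scores(c(TP = 0, FP = 0, FN = 0, TN = 64)),
               c(accuracy = 1, jaccard = 1, dice = 1))
})

test_that("metrics are invariant to pixel ordering", {
  pred <- random_mask(8, 3, 3)
  truth <- random_mask(8, 3, 4)
  set.seed(5)
  perm <- sample(64)
  pp <- matrix(pred[perm], 8, 8)
  tp <- matrix(truth[perm], 8, 8)
  for (cl in 0:2) {
    expect_identical(confusion_counts(pred, truth, cl),
                     confusion_counts(pp, tp, cl))
  }
})

test_that("micro aggregation sums counts; macro averages per-image scores", {
  p1 <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  t1 <- matrix(c(1L, 0L, 0L, 0L), 2, 2)
  p2 <- matrix(1L, 2, 2)
  t2 <- matrix(1L, 2, 2)
  micro <- class_metrics(list(p1, p2), list(t1, t2), classes = 1)
  macro <- class_metrics(list(p1, p2), list(t1, t2), classes = 1,
                         aggregate = "macro")
  expect_equal(micro$jaccard, 5 / 6)        # (1+4)/(1+4+1)
  expect_equal(macro$jaccard, (0.5 + 1) / 2)
})

test_that("two-fold averaging is the per-class arithmetic mean", {
  f1 <- class_metrics(random_mask(8, 3, 6), random_mask(8, 3, 7), 0:2)
  f2 <- class_metrics(random_mask(8, 3, 8), random_mask(8, 3, 9), 0:2)
  avg <- two_fold_average(f1, f2)
  expect_equal(avg$jaccard, (f1$jaccard + f2$jaccard) / 2)
  expect_identical(two_fold_average(f1, f1), f1)
  expect_true(all(avg$dice >= pmin(f1$dice, f2$dice) &
                    avg$dice <= pmax(f1$dice, f2$dice)))
  f3 <- f2[f2$class != 2, ]
  expect_error(two_fold_average(f1, f3), "classes")
})

test_that("the CSV report prints percentages to two decimals per fold", {
  f1 <- class_metrics(random_mask(8, 2, 10), random_mask(8, 2, 11), 0:1)
  f2 <- class_metrics(random_mask(8, 2, 12), random_mask(8, 2, 13), 0:1)
  path <- tempfile(fileext = ".csv")
  write_metrics_report(f1, f2, path, class_names = c("background", "lung"))
  rep <- utils::read.csv(path, colClasses = "character")
  expect_equal(nrow(rep), 6)
  expect_setequal(unique(rep$fold), c("fold1", "fold2", "average"))
  expect_true(all(grepl("^\\d+\\.\\d{2}$", rep$jaccard)))
  j_avg <- as.numeric(rep$jaccard[rep$fold == "average" & rep$class == "lung"])
  expect_equal(j_avg, round(100 * (f1$jaccard[2] + f2$jaccard[2]) / 2, 2))
  unlink(path)
})
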