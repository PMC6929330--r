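test_that("confusion counts match a loop-and-count oracle", {
  set.seed(40)
  for (rep in 1:20) {
    n <- sample(5:60, 1L)
    p <- runif(n)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2L) next
    thr <- runif(1)
    cc <- confusion_counts(p, y, thr)
    tp <- fp <- tn <- fn <- 0L
    for (i in seq_len(n)) {
      pred <- p[i] >= thr
      if (pred && y[i] == 1) tp <- tp + 1L
      if (pred && y[i] == 0) fp <- fp + 1L
      if (!pred && y[i] == 0) tn <- tn + 1L
      if (!pred && y[i] == 1) fn <- fn + 1L
    }
    expect_identical(unlist(unclass(cc)),
                     c(TP = tp, FP = fp, TN = tn, FN = fn))
    expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, n)
  }
})

test_that("a probability exactly at the threshold counts as positive", {
  cc <- confusion_counts(c(0.5, 0.5), c(1, 0), threshold = 0.5)
  expect_equal(cc$TP, 1L)
  expect_equal(cc$FP, 1L)
  expect_error(confusion_counts(numeric(0), character(0)), "no predictions")
})

test_that("metrics evaluate the worked confusion example exactly", {
  m <- classification_metrics(list(TP = 3, FP = 1, TN = 5, FN = 1))
  expect_equal(unname(m["sensitivity"]), 0.75)
  expect_equal(unname(m["specificity"]), 5 / 6)
  expect_equal(unname(m["accuracy"]), 0.8)
  expect_equal(unname(m["mcc"]), 14 / 24)
})

test_that("metric conventions cover degenerate counts", {
  perfect <- classification_metrics(list(TP = 4, FP = 0, TN = 6, FN = 0))
  expect_equal(unname(perfect), c(1, 1, 1, 1))
  # only positives observed, half predicted: specificity and MCC fall back
  m <- classification_metrics(list(TP = 2, FP = 0, TN = 0, FN = 2))
  expect_equal(unname(m["sensitivity"]), 0.5)
  expect_equal(unname(m["specificity"]), 0)
  expect_equal(unname(m["mcc"]), 0)
})

test_that("MCC is symmetric under swapping classes and predictions", {
  set.seed(41)
  for (rep in 1:20) {
    cc <- as.list(sample(0:10, 4L, replace = TRUE))
    names(cc) <- c("TP", "FP", "TN", "FN")
    if (sum(unlist(cc)) == 0) next
    swapped <- list(TP = cc$TN, FP = cc$FN, TN = cc$TP, FN = cc$FP)
    expect_equal(classification_metrics(cc)["mcc"],
                 classification_metrics(swapped)["mcc"],
                 ignore_attr = TRUE)
  }
})

test_that("trapezoidal AUC equals the U-statistic oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.4, 6L), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(6:40, 1L)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2L) next
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    expect_equal(roc_auc(s, y)$auc, u_statistic_auc(s, y),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(runif(4), c(1, 1, 1, 1)), "both classes")
})

test_that("AUC agrees with an established implementation", {
  set.seed(43)
  y <- rbinom(60, 1, 0.4)
  s <- runif(60) + 0.4 * y
  expect_equal(roc_auc(s, y)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(44)
  y <- rbinom(40, 1, 0.5)
  y[1:2] <- c(0, 1)
  s <- rnorm(40)
  a <- roc_auc(s, y)$auc
  expect_equal(roc_auc(exp(2 * s), y)$auc, a, tolerance = 1e-12)
  expect_equal(roc_auc(plogis(s - 3), y)$auc, a, tolerance = 1e-12)
})

test_that("the ROC curve runs from (0,0) to (1,1)", {
  set.seed(45)
  rep <- evaluate_predictions(runif(30), rbinom(30, 1, 0.5))
  expect_equal(unlist(rep$roc[1L, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(rep$roc[nrow(rep$roc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(rep$roc$fpr) >= 0))
  expect_true(all(diff(rep$roc$tpr) >= 0))
})

test_that("evaluation report recomputes from its own counts", {
  set.seed(46)
  p <- runif(50)
  y <- rbinom(50, 1, 0.3)
  y[1:2] <- c(0, 1)
  rep <- evaluate_predictions(p, y, threshold = 0.35)
  m <- classification_metrics(rep$counts)
  expect_equal(rep$accuracy, unname(m["accuracy"]))
  expect_equal(rep$mcc, unname(m["mcc"]))
  expect_equal(sum(rep$support), 50L)
})
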