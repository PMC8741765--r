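# Confusion matrices, the six diagnostic metrics, ROC curves.

test_that("confusion tallies match direct counting", {
  cm <- confusion_matrix(rep(c("DM", "non_DM"), each = 4),
                         rep(c("DM", "non_DM"), each = 4))
  expect_equal(c(cm$TP, cm$TN, cm$FP, cm$FN), c(4, 4, 0, 0))

  lab <- rep(c("DM", "non_DM"), each = 5)
  cm <- confusion_matrix(rep("DM", 10), lab)
  expect_equal(cm$FP, 5)

  withr::with_seed(21, {
    pred <- sample(c("DM", "non_DM"), 100, replace = TRUE)
    lab <- sample(c("DM", "non_DM"), 100, replace = TRUE)
  })
  cm <- confusion_matrix(pred, lab)
  oc <- oracle_confusion(pred, lab)
  expect_equal(list(TP = cm$TP, FP = cm$FP, TN = cm$TN, FN = cm$FN), oc)
  expect_error(confusion_matrix("DM", c("DM", "DM")),
               class = "tonguenet_contract_error")
})

test_that("metrics follow their defining formulas", {
  m <- classification_metrics(list(TP = 50, FP = 10, TN = 30, FN = 10))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 5 / 6)
  expect_equal(m$sensitivity, 5 / 6)
  expect_equal(m$specificity, 0.75)
  expect_equal(m$error_rate, 0.2)
  expect_equal(m$f1, 5 / 6) # precision == recall

  perfect <- classification_metrics(list(TP = 50, FP = 0, TN = 50, FN = 0))
  expect_equal(unlist(perfect[c("accuracy", "precision", "sensitivity",
                                "specificity", "f1")]),
               rep(1, 5), ignore_attr = TRUE)
  expect_equal(perfect$error_rate, 0)
})

test_that("metric identities hold on random confusion matrices", {
  withr::with_seed(31, {
    for (i in 1:25) {
      counts <- as.list(rmultinom(1, 200, c(0.4, 0.2, 0.3, 0.1))[, 1])
      names(counts) <- c("TP", "FP", "TN", "FN")
      m <- classification_metrics(counts)
      total <- sum(unlist(counts))
      expect_equal(m$accuracy + m$error_rate, 1)
      expect_equal(m$accuracy * total, counts$TP + counts$TN)
      if (!is.na(m$f1)) {
        expect_gte(m$f1 + 1e-12, min(m$precision, m$sensitivity))
        expect_lte(m$f1 - 1e-12, max(m$precision, m$sensitivity))
      }
    }
  })
})

test_that("metrics are invariant under joint permutation of predictions and labels", {
  withr::with_seed(41, {
    pred <- sample(c("DM", "non_DM"), 60, replace = TRUE)
    lab <- sample(c("DM", "non_DM"), 60, replace = TRUE)
    perm <- sample(60)
  })
  m1 <- classification_metrics(confusion_matrix(pred, lab))
  m2 <- classification_metrics(confusion_matrix(pred[perm], lab[perm]))
  expect_equal(m1, m2)
})

test_that("zero denominators are flagged as undefined, never reported as 0", {
  m <- classification_metrics(list(TP = 0, FP = 0, TN = 10, FN = 5))
  expect_true(is.na(m$precision))
  expect_true("precision" %in% attr(m, "undefined"))
  expect_false(is.na(m$specificity))
  expect_error(classification_metrics(list(TP = 0, FP = 0, TN = 0, FN = 0)),
               class = "tonguenet_argument_error")
})

test_that("ROC endpoints, degenerate cases, and the trapezoid AUC are correct", {
  lab <- rep(c("non_DM", "DM"), each = 5)
  sep <- roc_curve(c(rep(0.1, 5), rep(0.9, 5)), lab)
  expect_equal(sep$auc, 1)
  flat <- roc_curve(rep(0.5, 10), lab)
  expect_equal(flat$auc, 0.5)
  expect_equal(flat$points$fpr, flat$points$tpr)

  pts <- sep$points
  expect_equal(c(pts$fpr[1], pts$tpr[1]), c(0, 0))
  expect_equal(c(pts$fpr[nrow(pts)], pts$tpr[nrow(pts)]), c(1, 1))
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))

  expect_error(roc_curve(runif(4), rep("DM", 4)),
               class = "tonguenet_argument_error")
})

test_that("AUC matches the pairwise Mann-Whitney oracle and pROC", {
  withr::with_seed(51, {
    for (i in 1:10) {
      scores <- round(runif(20), 2) # rounding forces ties
      labels <- sample(c("DM", "non_DM"), 20, replace = TRUE)
      if (length(unique(labels)) < 2) next
      r <- roc_curve(scores, labels)
      expect_equal(r$auc, oracle_auc(scores, labels), tolerance = 1e-12)
    }
  })
  scores <- withr::with_seed(52, runif(50))
  labels <- rep(c("DM", "non_DM"), 25)
  ours <- roc_curve(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                        levels = c("non_DM", "DM"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("metric reports serialize to JSON and a comparison-style table", {
  m <- classification_metrics(list(TP = 40, FP = 5, TN = 45, FN = 10))
  pj <- withr::local_tempfile(fileext = ".json")
  pt <- withr::local_tempfile(fileext = ".tsv")
  df <- write_metric_report(list(deep_rbfnn = m), pj, pt)
  expect_equal(df$accuracy, m$accuracy)
  back <- utils::read.delim(pt)
  expect_equal(back$f1, m$f1, tolerance = 1e-12)
  expect_equal(jsonlite::read_json(pj, simplifyVector = TRUE)$accuracy,
               m$accuracy)
})
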