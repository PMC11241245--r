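test_that("the confusion matrix tallies true rows against predicted columns", {
  cm <- confusion_matrix(c("A", "A", "DC"), c("A", "DC", "DC"),
                         labels = c("A", "DC"))
  expect_equal(cm["A", "A"], 1L, ignore_attr = TRUE)
  expect_equal(cm["A", "DC"], 1L, ignore_attr = TRUE)
  expect_equal(cm["DC", "DC"], 1L, ignore_attr = TRUE)
  expect_equal(cm["DC", "A"], 0L, ignore_attr = TRUE)

  y <- rep(breakhis_classes, 3)
  perfect <- confusion_matrix(y, y)
  expect_true(all(perfect[row(perfect) != col(perfect)] == 0))

  expect_error(confusion_matrix("A", "ZZ", labels = "A"),
               class = "ecsanet_invalid_input")
})

test_that("the confusion matrix matches a brute-force tally on random labels", {
  withr::with_seed(5, {
    yt <- sample(breakhis_classes, 200, TRUE)
    yp <- sample(breakhis_classes, 200, TRUE)
  })
  cm <- confusion_matrix(yt, yp, breakhis_classes)
  for (i in breakhis_classes) for (j in breakhis_classes)
    expect_equal(unname(cm[i, j]), sum(yt == i & yp == j))
  expect_equal(sum(cm), 200)
  # one-vs-rest counts always partition the total
  for (cls in breakhis_classes)
    expect_equal(sum(ecsanet:::ovr_counts(cm, cls)), 200)
})

test_that("per-class rates follow their defining ratios", {
  y <- rep(c("A", "B"), c(6, 4))
  p <- c(rep("A", 5), "B", rep("B", 3), "A")
  cm <- confusion_matrix(y, p, c("A", "B"))
  m <- class_metrics(cm, "A")
  expect_equal(m$precision, 100 * 5 / 6)
  expect_equal(m$sensitivity, 100 * 5 / 6)
  expect_equal(m$specificity, 100 * 3 / 4)
  expect_equal(m$f1, 100 * 2 * (5 / 6) * (5 / 6) / (5 / 6 + 5 / 6))
  expect_equal(m$support, 6)

  diagm <- confusion_matrix(y, y, c("A", "B"))
  dm <- class_metrics(diagm)
  expect_true(all(dm$precision == 100 & dm$sensitivity == 100 &
                    dm$specificity == 100 & dm$f1 == 100))
})

test_that("F1 reproduces reported cells from precision/sensitivity pairs", {
  expect_equal(round(f1_score(71, 94)), 81)
  expect_equal(round(f1_score(94, 100)), 97)
  expect_equal(f1_score(0, 0), 0)
})

test_that("macro and weighted aggregation have the documented degeneracies", {
  pc <- tibble::tibble(label = c("A", "B"), precision = c(80, 80),
                       sensitivity = c(70, 70), specificity = c(90, 90),
                       f1 = c(74.7, 74.7), support = c(10, 30))
  agg <- aggregate_metrics(pc)
  expect_equal(agg$precision, c(80, 80))      # identical metrics: macro == weighted
  pc2 <- pc; pc2$precision <- c(60, 100)
  agg2 <- aggregate_metrics(pc2)
  expect_equal(agg2$precision[agg2$label == "macro"], 80)
  expect_equal(agg2$precision[agg2$label == "weighted"], 0.25 * 60 + 0.75 * 100)
})

test_that("multiclass Jaccard is the macro one-vs-rest intersection over union", {
  y <- c("A", "A", "B", "B")
  expect_equal(jaccard_index(y, y), 100)
  p <- c("A", "B", "B", "A")                  # half right in each class
  # per class: TP 1, FP 1, FN 1 -> 1/3
  expect_equal(jaccard_index(y, p), 100 / 3)
  expect_equal(jaccard_index(c("A", "B"), c("B", "A")), 0)
})

test_that("ROC-AUC matches the all-pairs concordance oracle and pROC", {
  withr::with_seed(7, {
    y <- sample(c("u", "v"), 20, TRUE)
    s <- matrix(runif(40), 20, 2, dimnames = list(NULL, c("u", "v")))
  })
  s <- s / rowSums(s)
  got <- roc_auc(s, y)
  # brute force: mean over classes of P(pos > neg) + 0.5 P(tie)
  brute <- function(scores, pos) {
    sp <- scores[pos]; sn <- scores[!pos]
    tot <- 0
    for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(sp) * length(sn))
  }
  want <- 100 * mean(c(brute(s[, "u"], y == "u"), brute(s[, "v"], y == "v")))
  expect_equal(got, want, tolerance = 1e-12)

  skip_if_not_installed("pROC")
  pr <- mean(vapply(c("u", "v"), function(cl)
    as.numeric(pROC::auc(pROC::roc(y == cl, s[, cl], quiet = TRUE))),
    numeric(1)))
  expect_equal(got, 100 * pr, tolerance = 1e-9)
})

test_that("ROC-AUC hits its closed-form anchors", {
  y <- rep(c("a", "b"), each = 5)
  perfect <- cbind(a = rep(c(0.9, 0.1), each = 5),
                   b = rep(c(0.1, 0.9), each = 5))
  expect_equal(roc_auc(perfect, y), 100)
  flat <- cbind(a = rep(0.5, 10), b = rep(0.5, 10))
  expect_equal(roc_auc(flat, y), 50)
  expect_warning(roc_auc(cbind(a = runif(4), b = runif(4), c = runif(4)),
                         rep(c("a", "b"), 2)), "absent")
})

test_that("metric functions agree with tally oracles on random inputs", {
  withr::with_seed(11, {
    for (trial in 1:25) {
      k <- sample(2:5, 1)
      labels <- LETTERS[1:k]
      n <- sample(20:60, 1)
      yt <- sample(labels, n, TRUE)
      yp <- sample(labels, n, TRUE)
      cm <- confusion_matrix(yt, yp, labels)
      pc <- suppressWarnings(class_metrics(cm))
      for (cls in labels) {
        tp <- sum(yt == cls & yp == cls); fp <- sum(yt != cls & yp == cls)
        fn <- sum(yt == cls & yp != cls)
        row <- pc[pc$label == cls, ]
        if (tp + fp > 0) expect_equal(row$precision, 100 * tp / (tp + fp))
        if (tp + fn > 0) expect_equal(row$sensitivity, 100 * tp / (tp + fn))
      }
      # micro identity: sum of TPs over N is the accuracy
      acc <- 100 * sum(yt == yp) / n
      expect_equal(100 * sum(diag(cm)) / sum(cm), acc)
      # weighted sensitivity equals accuracy
      agg <- aggregate_metrics(pc)
      expect_equal(agg$sensitivity[agg$label == "weighted"], acc,
                   tolerance = 1e-9)
    }
  })
})

test_that("the full report wires everything together", {
  withr::with_seed(12, {
    yt <- sample(c("A", "B", "C"), 60, TRUE)
    yp <- ifelse(runif(60) < 0.8, yt, sample(c("A", "B", "C"), 60, TRUE))
    s <- matrix(runif(180), 60, 3, dimnames = list(NULL, c("A", "B", "C")))
  })
  s <- s / rowSums(s)
  out <- withr::local_tempdir()
  rep <- suppressWarnings(metrics_report(yt, yp, scores = s, out_dir = out))
  expect_equal(sum(rep$per_class$support), 60)
  expect_equal(rep$weighted$sensitivity, rep$accuracy, tolerance = 1e-9)
  expect_true(file.exists(file.path(out, "per_class.csv")))
  expect_true(file.exists(file.path(out, "report.json")))
  td <- tidy(rep)
  expect_equal(nrow(td), 5L)                  # 3 classes + macro + weighted
  expect_s3_class(autoplot(rep), "ggplot")
})
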