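brute_counts <- function(labels, scores, thr = 0.5) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(labels)) {
    pos <- scores[i] >= thr
    if (pos && labels[i] == 1) tp <- tp + 1
    if (pos && labels[i] == 0) fp <- fp + 1
    if (!pos && labels[i] == 1) fn <- fn + 1
    if (!pos && labels[i] == 0) tn <- tn + 1
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

mann_whitney_auoc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  100 * total / (length(pos) * length(neg))
}

test_that("confusion counts enumerate the four outcomes", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(0.9, 0.2, 0.8, 0.1))
  expect_equal(unclass(cc)[c("TP", "FN", "FP", "TN")],
               list(TP = 1L, FN = 1L, FP = 1L, TN = 1L), ignore_attr = TRUE)
  cc0 <- confusion_counts(rep(0, 7), rep(0, 7))
  expect_equal(cc0$TN, 7)
  expect_equal(cc0$TP + cc0$FP + cc0$FN, 0)
  expect_error(confusion_counts(c(0, 1), 0.5), "length")
  expect_error(confusion_counts(c(0, 2), c(0.1, 0.2)), "labels")
})

test_that("accuracy and SE/SP follow their closed forms", {
  cc <- structure(list(TP = 50, TN = 42, FP = 5, FN = 3),
                  class = "confusion_counts")
  expect_equal(accuracy(cc), 92)
  expect_equal(unname(sensitivity_specificity(
    structure(list(TP = 9, FN = 1, TN = 1, FP = 0),
              class = "confusion_counts"))["SE"]), 90)
  expect_equal(unname(sensitivity_specificity(
    structure(list(TP = 1, FN = 0, TN = 0, FP = 10),
              class = "confusion_counts"))["SP"]), 0)
  all_right <- confusion_counts(c(0, 1), c(0.1, 0.9))
  expect_equal(accuracy(all_right), 100)
  expect_error(accuracy(confusion_counts(numeric(0), numeric(0))),
               "undefined")
  expect_error(sensitivity_specificity(confusion_counts(c(0, 0), c(0, 1))),
               "sensitivity undefined")
  expect_error(sensitivity_specificity(confusion_counts(c(1, 1), c(0, 1))),
               "specificity undefined")
})

test_that("metrics agree with a per-case brute-force recount", {
  withr::with_seed(41, {
    for (rep in 1:25) {
      n <- sample(20:200, 1)
      labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
      if (length(unique(labels)) < 2) next
      scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
      cc <- confusion_counts(labels, scores)
      bf <- brute_counts(labels, scores)
      expect_equal(unclass(cc), bf, ignore_attr = TRUE)
      expect_equal(accuracy(cc), 100 * (bf$TP + bf$TN) / n)
      sesp <- sensitivity_specificity(cc)
      expect_equal(unname(sesp["SE"]), 100 * bf$TP / (bf$TP + bf$FN))
      expect_equal(unname(sesp["SP"]), 100 * bf$TN / (bf$TN + bf$FP))
    }
  })
})

test_that("trapezoidal AUOC equals the Mann-Whitney statistic", {
  expect_equal(roc_auoc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auoc, 100)
  expect_equal(roc_auoc(c(0, 1, 0, 1), rep(0.4, 4))$auoc, 50)
  expect_error(roc_auoc(c(1, 1), c(0.2, 0.3)), "both classes")
  withr::with_seed(42, {
    for (rep in 1:20) {
      n <- sample(10:100, 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
      scores <- round(runif(n), sample(c(1, 3), 1))
      expect_equal(roc_auoc(labels, scores)$auoc,
                   mann_whitney_auoc(labels, scores))
    }
  })
})

test_that("AUOC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(7, {
    labels <- rbinom(60, 1, 0.4)
    scores <- runif(60)
  })
  ours <- roc_auoc(labels, scores)$auoc
  ref <- 100 * as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<",
                                              levels = c(0, 1))))
  expect_equal(ours, ref)
})

test_that("ROC invariants hold: monotone transforms, curve shape, AC identity", {
  withr::with_seed(11, {
    labels <- rbinom(80, 1, 0.5)
    scores <- runif(80)
  })
  base <- roc_auoc(labels, scores)
  expect_equal(roc_auoc(labels, exp(3 * scores))$auoc, base$auoc)
  expect_equal(roc_auoc(labels, rank(scores))$auoc, base$auoc)
  expect_true(all(diff(base$curve$fpr) >= 0))
  expect_true(all(diff(base$curve$tpr) >= 0))
  # accuracy is the prevalence-weighted mean of SE and SP
  cc <- confusion_counts(labels, scores)
  sesp <- sensitivity_specificity(cc)
  prev <- mean(labels == 1)
  expect_equal(accuracy(cc),
               prev * sesp[["SE"]] + (1 - prev) * sesp[["SP"]])
  m <- run_metrics(labels, scores)
  expect_named(m, c("AC", "SE", "SP", "AUOC"))
  expect_true(all(m >= 0 & m <= 100))
})
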