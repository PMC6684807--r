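# Confusion counts, SEN/PPV/F1 arithmetic, ROC and PRC curves against
# independent oracles.

test_that("confusion counts are exact and reject malformed input", {
  truth <- c("physiological", "pathological", "artifact")
  expect_identical(diag(confusion_counts(truth, truth)), c(physiological = 1L,
                                                           pathological = 1L,
                                                           artifact = 1L))
  # every item misclassified one class forward
  pred <- c("pathological", "artifact", "physiological")
  cm <- confusion_counts(truth, pred)
  expect_identical(sum(diag(cm)), 0L)
  expect_identical(cm["physiological", "pathological"], 1L)
  expect_identical(cm["pathological", "artifact"], 1L)
  expect_identical(cm["artifact", "physiological"], 1L)

  expect_error(confusion_counts(character(0), character(0)), "non-empty")
  expect_error(confusion_counts(truth, truth[1:2]), "length")
  expect_error(confusion_counts(truth, c("a", "b", "c")), "class set")
})

test_that("per-class metrics reproduce the published F1 arithmetic", {
  # Conv-LSTM rows of the published comparison: F1 from printed PPV/SEN
  expect_equal(round(f1_score(0.85, 0.87), 2), 0.86)   # physiological
  expect_equal(round(f1_score(0.66, 0.82), 2), 0.73)   # pathological
  expect_equal(round(f1_score(0.85, 0.76), 2), 0.80)   # artifacts
  f1s <- c(f1_score(0.85, 0.87), f1_score(0.66, 0.82), f1_score(0.85, 0.76))
  expect_equal(round(mean(f1s), 2), 0.80)              # macro average row
  expect_identical(f1_score(1, 1), 1)

  # a confusion matrix with known metrics
  cm <- matrix(c(8, 1, 1,
                 2, 6, 2,
                 0, 1, 9), 3, 3, byrow = TRUE,
               dimnames = list(ieeg_classes(), ieeg_classes()))
  rep <- per_class_metrics(cm)
  expect_equal(rep$per_class$sen, c(0.8, 0.6, 0.9))
  expect_equal(rep$per_class$ppv, c(8 / 10, 6 / 8, 9 / 12))
  expect_equal(rep$n, 30)
  expect_error(per_class_metrics(matrix(c(-1, 0, 0, 1), 2)), "non-negative")
})

test_that("undefined metrics are reported missing and excluded from macro averages", {
  cm <- matrix(c(5, 0, 0,
                 0, 0, 0,
                 0, 0, 5), 3, 3, byrow = TRUE,
               dimnames = list(ieeg_classes(), ieeg_classes()))
  expect_warning(rep <- per_class_metrics(cm), "undefined")
  expect_true(is.na(rep$per_class$sen[2]))
  expect_equal(rep$macro$f1, 1)                        # mean of the defined classes
})

test_that("F1 stays within the harmonic-mean bounds on random confusion matrices", {
  set.seed(99)
  for (i in 1:1000) {
    cm <- matrix(rpois(9, 5) + (diag(3) * rpois(3, 10)), 3)
    rep <- suppressWarnings(per_class_metrics(cm))
    ok <- !is.na(rep$per_class$f1)
    expect_true(all(rep$per_class$f1[ok] >=
                      pmin(rep$per_class$sen[ok], rep$per_class$ppv[ok]) - 1e-12))
    expect_true(all(rep$per_class$f1[ok] <=
                      pmax(rep$per_class$sen[ok], rep$per_class$ppv[ok]) + 1e-12))
  }
})

# Exhaustive pair-counting oracle: P(random positive outscores random
# negative), ties counted one half — the Mann-Whitney statistic.
auc_by_pairs <- function(scores, truth) {
  pos <- scores[truth]; neg <- scores[!truth]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

test_that("ROC AUC equals the exhaustive pair statistic, including ties", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    truth <- runif(n) < 0.5
    if (!any(truth) || all(truth)) next
    cv <- roc_curve(scores, truth)
    expect_equal(cv$auc, auc_by_pairs(scores, truth), tolerance = 1e-12)
    expect_identical(cv$points$x[1], 0)
    expect_identical(cv$points$y[1], 0)
    expect_identical(utils::tail(cv$points$x, 1), 1)
    expect_identical(utils::tail(cv$points$y, 1), 1)
  }
  expect_equal(roc_curve(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_error(roc_curve(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("ROC AUC agrees with pROC on larger instances", {
  skip_if_not_installed("pROC")
  set.seed(11)
  scores <- rnorm(200)
  truth <- runif(200) < plogis(scores)
  mine <- roc_curve(scores, truth)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("PRC AUC matches hand-enumerated step sums on toy fixtures", {
  # 6 items, scores descending, truth: + - + + - -
  # thresholds at each item: recall 1/3,1/3,2/3,1,1,1; precision 1,1/2,2/3,3/4,3/5,1/2
  # step AUC = (1/3)*1 + 0 + (1/3)*(2/3) + (1/3)*(3/4) = 0.8055556
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  truth <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
  cv <- prc_curve(scores, truth)
  expect_equal(cv$auc, 1 / 3 + (1 / 3) * (2 / 3) + (1 / 3) * (3 / 4),
               tolerance = 1e-12)
  # first point anchored at recall 0 with the top-threshold precision
  expect_identical(cv$points$x[1], 0)
  expect_identical(cv$points$y[1], 1)

  # all-positive truth: precision 1 everywhere, AUC 1
  expect_equal(prc_curve(c(0.3, 0.2, 0.9), c(TRUE, TRUE, TRUE))$auc, 1)
  expect_error(prc_curve(1:3, c(FALSE, FALSE, FALSE)), "positive")

  # average-precision identity: sum over positives of precision at their rank
  set.seed(13)
  for (i in 1:10) {
    n <- 15
    scores <- runif(n)                              # distinct almost surely
    truth <- runif(n) < 0.4
    if (!any(truth)) truth[1] <- TRUE
    o <- order(scores, decreasing = TRUE)
    y <- truth[o]
    ap <- sum((cumsum(y) / seq_len(n))[y]) / sum(y)
    expect_equal(prc_curve(scores, truth)$auc, ap, tolerance = 1e-12)
  }
})

test_that("uninformative scores give AUC near 0.5 (ROC) and prevalence (PRC)", {
  set.seed(17)
  scores <- runif(4000)
  truth <- runif(4000) < 0.25
  expect_equal(roc_curve(scores, truth)$auc, 0.5, tolerance = 0.05)
  expect_equal(prc_curve(scores, truth)$auc, 0.25, tolerance = 0.05)
})

test_that("metrics are invariant under joint permutation of (truth, pred)", {
  set.seed(23)
  truth <- sample(ieeg_classes(), 60, replace = TRUE)
  pred <- sample(ieeg_classes(), 60, replace = TRUE)
  r1 <- suppressWarnings(per_class_metrics(confusion_counts(truth, pred)))
  p <- sample(60)
  r2 <- suppressWarnings(per_class_metrics(confusion_counts(truth[p], pred[p])))
  expect_identical(r1$per_class, r2$per_class)
})
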