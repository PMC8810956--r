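test_that("confusion counts follow the >= threshold rule", {
  cc <- confusion_at_threshold(c(0.9, 0.2), c("positive", "negative"), 0.5)
  expect_equal(unlist(cc[c("tp", "fp", "tn", "fn")]),
               c(tp = 1L, fp = 0L, tn = 1L, fn = 0L))
  # threshold 0: everything predicted positive
  cc0 <- confusion_at_threshold(c(0.9, 0.2, 0), c(TRUE, FALSE, FALSE), 0)
  expect_equal(cc0$fn, 0L)
  expect_equal(cc0$tn, 0L)
  expect_equal(cc0$fp, 2L)
  # a probability equal to the threshold is predicted positive
  ccq <- confusion_at_threshold(c(0.5), c(TRUE), 0.5)
  expect_equal(ccq$tp, 1L)
  expect_error(confusion_at_threshold(numeric(0), logical(0), 0.5), "empty")
})

test_that("metric formulas reproduce the reference confusion arithmetic", {
  # the unique counts on a 160/640 test split consistent with the printed
  # sensitivity and PPV
  m <- metrics_from_confusion(confusion_counts(tp = 155, fp = 15,
                                               tn = 625, fn = 5))
  expect_equal(round(100 * m$sensitivity, 2), 96.88)
  expect_equal(round(100 * m$ppv, 2), 91.18)
  expect_equal(m$sensitivity, 155 / 160)
  expect_equal(m$ppv, 155 / 170)
  expect_equal(m$specificity, 625 / 640)
  expect_equal(m$accuracy, 780 / 800)

  perfect <- metrics_from_confusion(confusion_counts(1, 0, 1, 0))
  expect_true(all(unlist(perfect) == 1))

  undef <- metrics_from_confusion(confusion_counts(tp = 0, fp = 0,
                                                   tn = 3, fn = 2))
  expect_true(is.na(undef$ppv))
  expect_true("ppv" %in% attr(undef, "undefined"))
  expect_false("sensitivity" %in% attr(undef, "undefined"))
})

test_that("ROC AUC equals the exhaustive pair-counting oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), c(TRUE, FALSE, TRUE, FALSE)),
               0.75)
  # perfectly separated scores
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  # random score/label pairs, including ties
  set.seed(44)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    probs <- round(runif(n), sample(c(1, 2, 3), 1))
    labels <- runif(n) < 0.4
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(probs, labels), pair_count_auc(probs, labels))
  }
  expect_error(roc_auc(c(0.1, 0.9), c(TRUE, TRUE)), "both classes")
})

test_that("uninformative scores give AUC near one half", {
  set.seed(9)
  probs <- runif(4000)
  labels <- runif(4000) < 0.5
  expect_lt(abs(roc_auc(probs, labels) - 0.5), 0.05)
})

test_that("average precision is 1 for separation and matches a hand oracle", {
  pr <- pr_curve(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(pr$average_precision, 1)
  # hand-computed step-wise AP: scores .9(+) .8(-) .7(+) .6(-)
  # ranked: P at ranks 1..4 = 1, 1/2, 2/3, 1/2; recall steps at ranks 1, 3
  pr2 <- pr_curve(c(0.9, 0.8, 0.7, 0.6), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(pr2$average_precision, 0.5 * 1 + 0.5 * (2 / 3))
  # curve endpoints: recall reaches 1
  expect_equal(max(pr2$curve$recall), 1)
})

test_that("threshold selection maximises balanced accuracy with tie rules", {
  # separable validation set: midpoint of the gap is returned
  t1 <- select_threshold(c(0.9, 0.8, 0.3, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(t1, (0.8 + 0.3) / 2)
  # documented worked case: optimum lies in (0.7, 0.8]
  t2 <- select_threshold(c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2),
                         c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_gt(t2, 0.7)
  expect_lte(t2, 0.8)
  # all probabilities equal: degenerate, returned with a warning
  expect_warning(t3 <- select_threshold(c(0.4, 0.4, 0.4),
                                        c(TRUE, FALSE, TRUE)), "identical")
  expect_equal(t3, 0.4)
  expect_error(select_threshold(c(0.2, 0.4), c(TRUE, TRUE)), "both classes")
})

test_that("threshold selection matches brute force over all cuts", {
  balanced_acc <- function(probs, labels, t) {
    sens <- mean(probs[labels] >= t)
    spec <- mean(probs[!labels] < t)
    (sens + spec) / 2
  }
  set.seed(77)
  for (i in 1:25) {
    n <- sample(8:60, 1)
    probs <- round(runif(n), 2)
    labels <- runif(n) < 0.5
    if (length(unique(labels)) < 2 || length(unique(probs)) < 2) next
    t_star <- select_threshold(probs, labels)
    best_brute <- max(vapply(unique(probs), function(t)
      balanced_acc(probs, labels, t), 0))
    expect_equal(balanced_acc(probs, labels, t_star), best_brute)
  }
})

test_that("exact proportion intervals match direct beta quantiles", {
  expect_equal(proportion_ci(5, 5)[2], 1)
  expect_equal(proportion_ci(0, 8)[1], 0)
  ci <- proportion_ci(155, 160)
  expect_equal(ci[1], qbeta(0.025, 155, 160 - 155 + 1))
  expect_equal(ci[2], qbeta(0.975, 155 + 1, 160 - 155))
  expect_error(proportion_ci(6, 5), "k must lie")
  expect_error(proportion_ci(1, 0), "positive")
})

test_that("the DeLong AUC interval brackets the point estimate", {
  set.seed(3)
  probs <- c(runif(60, 0.4, 1), runif(60, 0, 0.6))
  labels <- rep(c(TRUE, FALSE), each = 60)
  ci <- auc_ci(probs, labels)
  a <- roc_auc(probs, labels)
  expect_lt(ci[1], a)
  expect_gt(ci[2], a)
  expect_true(ci[1] >= 0 && ci[2] <= 1)
})

test_that("the full report is internally consistent and exportable", {
  set.seed(21)
  probs <- c(runif(40, 0.35, 1), runif(80, 0, 0.65))  # overlapping classes
  labels <- rep(c("positive", "negative"), c(40, 80))
  rep_ <- evaluate_model(probs, labels, threshold = 0.5)
  cc <- rep_$confusion
  expect_equal(cc$tp + cc$fn, 40L)
  expect_equal(cc$tn + cc$fp, 80L)
  expect_equal(rep_$metrics$accuracy, (cc$tp + cc$tn) / 120)
  dir <- withr::local_tempdir()
  paths <- write_metrics_report(rep_, dir)
  expect_true(all(file.exists(paths)))
  got <- utils::read.csv(paths[1])
  expect_equal(got$value[got$metric == "auc"], rep_$auc)
})
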