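test_that("perfect separation gives AUC = 1 and J = 1", {
  r <- roc_with_youden(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T))
  expect_equal(r$auc, 1)
  expect_equal(r$youden_j, 1)
  expect_equal(r$sensitivity, 1); expect_equal(r$specificity, 1)
  expect_identical(r$direction, "higher_is_positive")
  expect_true(r$threshold > 3 && r$threshold <= 10)
})

test_that("AUC matches exhaustive pair counting", {
  scores <- c(3, 5, 1, 4); labels <- c(TRUE, TRUE, FALSE, FALSE)
  r <- roc_with_youden(scores, labels)
  expect_equal(r$auc, 0.75)                       # 3 concordant of 4 pairs
  expect_equal(r$auc, enum_auc(scores, labels))
  # with ties
  set.seed(6)
  s2 <- sample(1:8, 30, replace = TRUE); l2 <- rep(c(TRUE, FALSE), 15)
  if (mean(s2[l2]) >= mean(s2[!l2])) {
    expect_equal(roc_with_youden(s2, l2)$auc, enum_auc(s2, l2))
  } else {
    expect_equal(roc_with_youden(s2, l2)$auc, enum_auc(-s2, l2))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(10)
  scores <- c(rnorm(40, 1), rnorm(40))
  labels <- rep(c(TRUE, FALSE), each = 40)
  r <- roc_with_youden(scores, labels)
  ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                              direction = "<", quiet = TRUE)))
  expect_equal(r$auc, as.numeric(ref))
})

test_that("the Youden identity holds exactly at the reported threshold", {
  set.seed(3)
  for (i in 1:10) {
    scores <- rnorm(30); labels <- rep(c(TRUE, FALSE), 15)
    r <- roc_with_youden(scores + labels * runif(1, 0, 2), labels)
    expect_identical(r$youden_j, r$sensitivity + r$specificity - 1)
  }
  r <- roc_with_youden(c(2, 4, 6, 1, 3, 5), c(T, T, T, F, F, F))
  pos_called <- c(2, 4, 6) >= r$threshold
  neg_called <- c(1, 3, 5) >= r$threshold
  expect_equal(mean(pos_called), r$sensitivity)
  expect_equal(mean(!neg_called), r$specificity)
})

test_that("direction flips for markers where low scores mark the positives", {
  r <- roc_with_youden(c(1, 2, 8, 9), c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(r$direction, "lower_is_positive")
  expect_equal(r$auc, 1)                   # oriented AUC
  expect_true(r$threshold >= 2 && r$threshold < 8)
  # positives are called by score <= threshold
  expect_equal(mean(c(1, 2) <= r$threshold), r$sensitivity)
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(21)
  scores <- rexp(60); labels <- rep(c(TRUE, FALSE), 30)
  scores[labels] <- scores[labels] + 0.3
  a0 <- roc_with_youden(scores, labels)$auc
  for (f in list(function(x) 3 * x + 2, exp, function(x) x^3,
                 function(x) rank(x)))
    expect_equal(roc_with_youden(f(scores), labels)$auc, a0)
})

test_that("label-independent scores give a near-chance AUC at n = 2000/class", {
  set.seed(14)
  scores <- rnorm(4000); labels <- rep(c(TRUE, FALSE), 2000)
  a <- roc_with_youden(scores, labels)$auc
  expect_gte(a, 0.45); expect_lte(a, 0.55)
})

test_that("ties in J are broken toward higher specificity", {
  # two cuts reach J = 0.5: sens 1 / spec 0.5 and sens 0.5 / spec 1
  r <- roc_with_youden(c(1, 3, 2, 4), c(F, F, T, T))
  expect_equal(r$youden_j, 0.5)
  expect_equal(r$specificity, 1)
})

test_that("single-class labels are rejected", {
  expect_error(roc_with_youden(1:4, rep(TRUE, 4)), "both classes")
})
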