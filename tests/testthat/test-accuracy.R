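test_that("confusion matrices are built by direct pairwise counting", {
  cm <- build_confusion(rep("m", 10), rep("m", 10), c("m", "w"))
  expect_equal(unname(diag(cm$counts)), c(10, 0))
  expect_equal(sum(cm$counts), 10)

  cm2 <- build_confusion(c("m", "m", "m", "w"), c("m", "m", "m", "m"),
                         c("m", "w"))
  expect_equal(cm2$counts[["m", "m"]], 3L)
  expect_equal(cm2$counts[["m", "w"]], 1L)

  expect_error(build_confusion(character(0), character(0), c("m", "w")),
               "empty")
  expect_error(build_confusion(c("m", "x"), c("m", "m"), c("m", "w")),
               "x")
  expect_error(build_confusion("m", c("m", "w"), c("m", "w")), "length")
})

test_that("accuracy statistics of the 2009 epoch matrix match the record", {
  cm <- epoch1_error_matrix()
  expect_equal(round(overall_accuracy(cm), 1), 99.6)
  expect_equal(overall_accuracy(cm), 100 * 1698 / 1705)
  acc <- class_accuracies(cm)
  expect_equal(acc$users_accuracy[acc$class == "bare_builtup"],
               100 * 26 / 32)
  expect_equal(round_half_up(
    acc$users_accuracy[acc$class == "bare_builtup"], 1), 81.3)
  expect_equal(round(acc$producers_accuracy[acc$class == "mangrove"], 1),
               99.7)
  expect_equal(acc$users_accuracy[acc$class == "water"], 100)
})

test_that("accuracy statistics of the 2019 epoch matrix match the record", {
  cm <- epoch2_error_matrix()
  expect_equal(overall_accuracy(cm), 100 * 1691 / 1705)
  expect_gte(overall_accuracy(cm), 99.1)
  expect_lte(overall_accuracy(cm), 99.2)
  acc <- class_accuracies(cm)
  expect_equal(round(acc$users_accuracy[acc$class == "mangrove"], 1), 99.2)
  expect_equal(round(acc$producers_accuracy[acc$class == "mangrove"], 1),
               98.6)
})

test_that("identity matrices give perfect scores", {
  cm <- confusion_matrix(diag(5, 3), letters[1:3])
  expect_equal(overall_accuracy(cm), 100)
  acc <- class_accuracies(cm)
  expect_true(all(acc$users_accuracy == 100))
  expect_true(all(acc$producers_accuracy == 100))
  expect_equal(unname(disagreement(cm)), c(0, 0, 0))
  expect_equal(qadi(cm)$qadi, 0)
  expect_equal(qadi(cm)$confidence, "Very high confidence")
})

test_that("quantity/allocation decomposition matches hand oracles", {
  # all-quantity case: both reference columns land in one classified row
  cm <- confusion_matrix(rbind(c(2, 0), c(2, 0)), c("a", "b"))
  qa <- disagreement(cm)
  expect_equal(qa[["D"]], 2)
  expect_equal(qa[["Q"]], 2)
  expect_equal(qa[["A"]], 0)

  qa4 <- disagreement(epoch2_error_matrix())
  expect_equal(qa4[["D"]], 14)
  expect_equal(qa4[["Q"]], 5)
  expect_equal(qa4[["A"]], 9)
  expect_equal(qa4, oracle_disagreement(epoch2_error_matrix()$counts))
})

test_that("Q + A = N - trace on fuzzed matrices, and QADI bounds hold", {
  set.seed(101)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    counts <- matrix(rpois(k * k, lambda = sample(1:30, 1)), k)
    if (sum(counts) == 0) counts[1, 1] <- 1
    cm <- confusion_matrix(counts)
    qa <- disagreement(cm)
    expect_equal(qa[["Q"]] + qa[["A"]], cm$N - sum(diag(counts)))
    expect_equal(qa, oracle_disagreement(counts))
    q <- qadi(cm)$qadi
    expect_gte(q + 1e-12, max(qa[["Q"]], qa[["A"]]) / cm$N)
    expect_lte(q, (qa[["Q"]] + qa[["A"]]) / cm$N + 1e-12)
    # QADI = 0 exactly when the matrix is diagonal
    expect_equal(q == 0, sum(diag(counts)) == sum(counts))
  }
})

test_that("QADI is invariant to simultaneous class permutation", {
  cm <- epoch2_error_matrix()
  set.seed(3)
  for (i in 1:5) {
    p <- sample(4)
    cmp <- confusion_matrix(cm$counts[p, p], cm$labels[p])
    expect_equal(qadi(cmp)$qadi, qadi(cm)$qadi)
    expect_equal(overall_accuracy(cmp), overall_accuracy(cm))
  }
})

test_that("QADI value and confidence banding follow the five-step scale", {
  cm <- epoch2_error_matrix()
  q <- qadi(cm)
  expect_equal(q$qadi, sqrt((9 / 1705)^2 + (5 / 1705)^2))
  expect_equal(q$confidence, "Very high confidence")

  # A = 0, Q = N/2 -> QADI 0.5, bottom band
  cmq <- confusion_matrix(rbind(c(0, 0), c(2, 2)), c("a", "b"))
  qq <- qadi(cmq)
  expect_equal(qq$qadi, 0.5)
  expect_equal(qq$confidence, "Very low confidence")

  expect_equal(qadi_confidence(c(0, 0.069, 0.07, 0.119, 0.12, 0.199,
                                 0.2, 0.299, 0.3, 1)),
               rep(c("Very high confidence", "High confidence",
                     "Moderate confidence", "Low confidence",
                     "Very low confidence"), each = 2))
})

test_that("accuracy_report assembles consistent components", {
  rep1 <- accuracy_report(epoch1_error_matrix())
  expect_equal(rep1$total_disagreement,
               rep1$quantity_disagreement + rep1$allocation_disagreement)
  expect_equal(rep1$N, 1705)
  expect_equal(rep1$confidence, "Very high confidence")
  expect_output(print(rep1), "Overall accuracy: 99.6%")
})
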