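test_that("confusion counts enumerate the four outcomes", {
  cc <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_identical(unclass(cc)[c("TP", "FP", "FN", "TN")],
                   list(TP = 1L, FP = 1L, FN = 1L, TN = 1L))
  agree <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_identical(agree$FP + agree$FN, 0L)
  flip <- confusion(c(1, 0), c(0, 1))
  expect_identical(flip$TP + flip$TN, 0L)
  expect_error(confusion(c(1, 0), c(1)), class = "ecgfb_parameter_error")
})

test_that("precision/recall/F1 match the defining formulas", {
  m <- prf1(structure(list(TP = 8L, FP = 2L, FN = 2L, TN = 0L),
                      class = "confusion_counts"))
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.8)
  expect_equal(m$f1, 0.8)
  expect_false(m$degenerate)
  deg <- prf1(structure(list(TP = 0L, FP = 0L, FN = 5L, TN = 10L),
                        class = "confusion_counts"))
  expect_identical(c(deg$precision, deg$recall, deg$f1), c(0, 0, 0))
  expect_true(deg$degenerate)
  # F1 is the harmonic mean of precision and recall
  for (i in 1:200) {
    cnt <- ecgfb:::with_seed(i, as.list(sample(0:30, 4, replace = TRUE)))
    names(cnt) <- c("TP", "FP", "FN", "TN")
    m <- prf1(structure(cnt, class = "confusion_counts"))
    if (m$precision + m$recall > 0)
      expect_equal(m$f1, 2 / (1 / max(m$precision, 1e-300) +
                                1 / max(m$recall, 1e-300)),
                   tolerance = 1e-9)
  }
  # swapping FP and FN swaps precision and recall
  a <- prf1(structure(list(TP = 5L, FP = 3L, FN = 7L, TN = 1L),
                      class = "confusion_counts"))
  b <- prf1(structure(list(TP = 5L, FP = 7L, FN = 3L, TN = 1L),
                      class = "confusion_counts"))
  expect_equal(a$precision, b$recall)
  expect_equal(a$recall, b$precision)
})

test_that("trapezoidal AUC equals the exhaustive pairwise-ranking oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  for (i in 1:300) {
    n <- ecgfb:::with_seed(i, sample(4:12, 1))
    truth <- ecgfb:::with_seed(i * 2 + 1,
                               c(0, 1, sample(0:1, n - 2, replace = TRUE)))
    scores <- ecgfb:::with_seed(i * 3 + 1,
                                round(stats::runif(n), 1))  # force ties
    expect_equal(roc_auc(scores, truth)$auc,
                 auc_pairwise_oracle(scores, truth), tolerance = 1e-12)
  }
  expect_error(roc_auc(runif(5), rep(1, 5)),
               class = "ecgfb_undefined_auc_error")
})

test_that("ROC points are monotone with exact endpoints and AUC is rank-invariant", {
  scores <- ecgfb:::with_seed(8, stats::runif(50))
  truth <- ecgfb:::with_seed(9, sample(0:1, 50, replace = TRUE))
  ra <- roc_auc(scores, truth)
  expect_identical(unlist(ra$roc[1, ]), c(fpr = 0, tpr = 0))
  expect_identical(unlist(ra$roc[nrow(ra$roc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(ra$roc$fpr) >= 0))
  expect_true(all(diff(ra$roc$tpr) >= 0))
  for (f in list(function(x) 2 * x + 3, exp, function(x) x^3))
    expect_equal(roc_auc(f(scores), truth)$auc, ra$auc, tolerance = 1e-12)
})

test_that("random scores give chance-level AUC", {
  scores <- ecgfb:::with_seed(31, stats::runif(2000))
  truth <- ecgfb:::with_seed(32, sample(0:1, 2000, replace = TRUE))
  expect_equal(roc_auc(scores, truth)$auc, 0.5, tolerance = 0.05)
})

test_that("AUC agrees with an established ROC implementation", {
  library(pROC)
  scores <- ecgfb:::with_seed(21, stats::runif(80))
  truth <- ecgfb:::with_seed(22, sample(0:1, 80, replace = TRUE))
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, truth)$auc, ref, tolerance = 1e-9)
})

test_that("exact Wilcoxon p-values match sign-pattern enumeration", {
  # uniform positive shift, n = 9: the most extreme one-sided pattern
  b <- c(0.85, 0.87, 0.90, 0.84, 0.88, 0.91, 0.86, 0.89, 0.83)
  a <- b + 0.02
  res <- paired_wilcoxon(a, b)
  expect_equal(res$p_value, 2 / 2^9)
  expect_equal(res$p_value, 0.00390625)
  expect_identical(res$method, "exact")
  # one opposing rank and tied |differences|, n = 5..10
  for (i in 1:40) {
    n <- ecgfb:::with_seed(i, sample(5:10, 1))
    d <- ecgfb:::with_seed(i + 50,
                           sample(c(-3, -2, -1, 1, 1, 2, 2, 3), n,
                                  replace = TRUE)) / 10
    aa <- seq(0.5, 0.9, length.out = n)
    bb <- aa - d
    expect_equal(paired_wilcoxon(aa, bb)$p_value,
                 wilcoxon_enum_oracle(aa, bb), tolerance = 1e-12,
                 label = sprintf("case %d", i))
  }
})

test_that("exact no-ties p-values agree with the standard implementation", {
  for (i in 1:20) {
    n <- ecgfb:::with_seed(i, sample(6:15, 1))
    aa <- ecgfb:::with_seed(i + 30, stats::rnorm(n))
    bb <- ecgfb:::with_seed(i + 60, stats::rnorm(n))
    if (anyDuplicated(abs(aa - bb)) || any(aa == bb)) next
    ref <- stats::wilcox.test(aa, bb, paired = TRUE, exact = TRUE)$p.value
    expect_equal(paired_wilcoxon(aa, bb)$p_value, ref, tolerance = 1e-12)
  }
  # symmetric differences: no evidence, large p
  aa <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  bb <- c(0.2, 0.1, 0.4, 0.3, 0.6, 0.5)
  expect_gte(paired_wilcoxon(aa, bb)$p_value, 0.5)
  expect_error(paired_wilcoxon(aa, aa),
               class = "ecgfb_degenerate_input_error")
})

test_that("large-n Wilcoxon switches to the normal approximation", {
  a <- ecgfb:::with_seed(77, stats::rnorm(40))
  b <- a + ecgfb:::with_seed(78, stats::rnorm(40, 0.4))
  res <- paired_wilcoxon(a, b)
  expect_identical(res$method, "normal approximation")
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                            correct = TRUE)$p.value
  expect_equal(res$p_value, ref, tolerance = 1e-9)
})

test_that("eval_report aggregates per-class metrics and macro averages", {
  per_class <- list(
    AF = list(truth = c(1, 1, 0, 0), calls = c(1, 1, 0, 0),
              scores = c(0.9, 0.8, 0.2, 0.1)),
    PVC = list(truth = c(1, 0, 1, 0), calls = c(1, 0, 0, 0),
               scores = c(0.9, 0.4, 0.3, 0.2)))
  rep <- eval_report(per_class)
  expect_equal(rep$classes$AF$f1, 1)
  expect_equal(rep$classes$PVC$recall, 0.5)
  expect_equal(rep$macro_f1,
               mean(c(rep$classes$AF$f1, rep$classes$PVC$f1)))
  expect_equal(rep$macro_auc,
               mean(c(rep$classes$AF$auc, rep$classes$PVC$auc)))
})
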