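test_that("confusion counts match a brute-force per-element tally", {
  expect_equal(unclass(confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0), 1)),
               list(TP = 2L, TN = 2L, FP = 0L, FN = 0L))
  cc <- confusion_counts(c(1, 1, 0, 0), c(0, 0, 1, 1), 1)
  expect_equal(cc$TP + cc$TN, 0L)
  set.seed(42)
  y_true <- sample(0:3, 50, replace = TRUE)
  y_pred <- sample(0:3, 50, replace = TRUE)
  for (pos in 0:3) {
    cc <- confusion_counts(y_true, y_pred, pos)
    tp <- tn <- fp <- fn <- 0L
    for (i in seq_along(y_true)) {
      t <- y_true[i] == pos; p <- y_pred[i] == pos
      if (t && p) tp <- tp + 1L else if (!t && !p) tn <- tn + 1L
      else if (!t && p) fp <- fp + 1L else fn <- fn + 1L
    }
    expect_equal(unclass(cc), list(TP = tp, TN = tn, FP = fp, FN = fn))
  }
  expect_error(confusion_counts(1:3, 1:4, 1), "lengths differ")
})

test_that("binary metrics reproduce the printed formulas on fixed counts", {
  cc <- structure(list(TP = 50L, TN = 40L, FP = 5L, FN = 5L),
                  class = "confusion_counts")
  m <- compute_metrics(cc)
  expect_equal(m$accuracy, 0.90)
  expect_equal(m$error, 0.10)
  expect_equal(m$mcc, 1975 / 2475)
  expect_equal(m$recall, 50 / 55)
  expect_equal(m$specificity, 40 / 45)
  expect_equal(m$precision, 50 / 55)
  expect_equal(m$fpr, 5 / 45)
  expect_equal(m$f1, 2 * (50 / 55) * (50 / 55) / ((50 / 55) + (50 / 55)))
  # kappa by the printed Po/Pe formulas
  po <- 0.9; pe <- (55 * 55 + 45 * 45) / 100^2
  expect_equal(m$kappa, (po - pe) / (1 - pe))
})

test_that("degenerate confusion tables behave as specified", {
  perfect <- compute_metrics(structure(list(TP = 7L, TN = 9L, FP = 0L, FN = 0L),
                                       class = "confusion_counts"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$error, 0)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$fpr, 0)
  # all-positive predictions on balanced truth: Po = Pe, kappa = 0
  allpos <- compute_metrics(structure(list(TP = 10L, TN = 0L, FP = 10L, FN = 0L),
                                      class = "confusion_counts"))
  expect_equal(allpos$kappa, 0)
  # zero denominators yield NA, never an error
  nopos <- compute_metrics(structure(list(TP = 0L, TN = 10L, FP = 0L, FN = 0L),
                                     class = "confusion_counts"))
  expect_true(is.na(nopos$recall))
  expect_true(is.na(nopos$precision))
})

test_that("accuracy + error = 1 and MCC is symmetric under TP<->TN, FP<->FN", {
  set.seed(7)
  for (rep in 1:20) {
    cts <- as.list(rmultinom(1, 60, c(0.4, 0.3, 0.15, 0.15))[, 1])
    names(cts) <- c("TP", "TN", "FP", "FN")
    cc <- structure(cts, class = "confusion_counts")
    sw <- structure(list(TP = cts$TN, TN = cts$TP, FP = cts$FN, FN = cts$FP),
                    class = "confusion_counts")
    m <- compute_metrics(cc); ms <- compute_metrics(sw)
    expect_equal(m$accuracy + m$error, 1)
    if (!is.na(m$mcc) && !is.na(ms$mcc)) expect_equal(abs(m$mcc), abs(ms$mcc))
  }
})

test_that("macro metrics: perfect prediction, balanced identity, permutation", {
  y <- rep(0:7, each = 5)
  perfect <- macro_metrics(y, y)
  for (f in c("accuracy", "recall", "specificity", "precision", "f1", "mcc", "kappa"))
    expect_equal(perfect[[f]], 1)
  expect_equal(perfect$error, 0)
  expect_equal(perfect$fpr, 0)

  # 2 balanced classes: macro recall equals balanced accuracy
  set.seed(11)
  y2 <- rep(0:1, each = 20)
  p2 <- ifelse(runif(40) < 0.8, y2, 1 - y2)
  m2 <- macro_metrics(y2, p2)
  bal_acc <- mean(c(mean(p2[y2 == 0] == 0), mean(p2[y2 == 1] == 1)))
  expect_equal(m2$recall, bal_acc)

  perm <- sample(40)
  m2p <- macro_metrics(y2[perm], p2[perm])
  expect_equal(m2[names(m2) != "per_class"], m2p[names(m2p) != "per_class"])

  expect_warning(macro_metrics(c(0, 0, 1, 1), c(0, 0, 1, 1), classes = 0:2),
                 "absent")
})

test_that("one-sample t test matches the closed form and quadrature", {
  v <- c(1.1, 0.9, 1.3, 0.7, 1.0, 1.2)
  res <- one_sample_t_test(v, 1.0)
  expect_equal(res$df, 5L)
  expect_equal(res$t, (mean(v) - 1) / (sd(v) / sqrt(6)))
  # symmetric values about mu0 -> t = 0, p = 1
  sym <- one_sample_t_test(c(0.9, 1.1, 0.8, 1.2), 1.0)
  expect_equal(sym$t, 0)
  expect_equal(sym$p_two_tailed, 1)
  expect_error(one_sample_t_test(c(1, 1, 1), 0), "variance")
  # p-value kernel vs numerical integration of the t density
  tval <- 0.712; df <- 5
  dens <- function(x) dt(x, df)
  central <- integrate(dens, -abs(tval), abs(tval))$value
  expect_equal(t_test_p_value(tval, df), 1 - central, tolerance = 1e-8)
})

test_that("mean confidence intervals: degenerate, nesting, closed form", {
  expect_equal(mean_confidence_interval(rep(0.99, 5)),
               c(lo = 0.99, hi = 0.99))
  v <- c(0.989, 0.992, 0.987, 0.995, 0.991, 0.993)
  ci95 <- mean_confidence_interval(v, 0.95)
  ci99 <- mean_confidence_interval(v, 0.99)
  expect_lte(ci99[["lo"]], ci95[["lo"]])
  expect_gte(ci99[["hi"]], ci95[["hi"]])
  expect_equal(ci95[["hi"]] - ci95[["lo"]],
               2 * qt(0.975, 5) * sd(v) / sqrt(6))
})
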